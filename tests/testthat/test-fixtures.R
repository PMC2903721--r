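schema <- load_schema()

test_that("duplex generation matches its stated counts and ground truth", {
  d <- make_duplex("GGCGCC", n_models = 1)
  expect_equal(sum(vapply(d$structure$models[[1]]$chains, length, 1L)), 12)
  expect_equal(nrow(d$truth$pairs), 6)
  expect_equal(nrow(d$truth$stacks), 10)
  expect_equal(d$structure$pdb_id, "SYN1")
  # strand B is the reverse complement
  seqB <- vapply(d$structure$models[[1]]$chains$B, `[[`, "", "res_name")
  expect_equal(paste(seqB, collapse = ""), "GGCGCC")  # palindromic here
  d2 <- make_duplex("GAAC", n_models = 1)
  seqB2 <- vapply(d2$structure$models[[1]]$chains$B, `[[`, "", "res_name")
  expect_equal(paste(seqB2, collapse = ""), "GUUC")
})

test_that("multi-model duplexes share a skeleton and seeds fix the noise", {
  d8 <- make_duplex("GC", n_models = 8)
  expect_length(d8$structure$models, 8)
  skel <- lapply(d8$structure$models, rnakb:::model_skeleton)
  for (k in 2:8) expect_identical(skel[[k]], skel[[1]])

  s1 <- make_duplex(duplex_spec("GC", n_models = 2, noise_sigma = 0.05,
                                seed = 42))
  s2 <- make_duplex(duplex_spec("GC", n_models = 2, noise_sigma = 0.05,
                                seed = 42))
  expect_identical(write_pdb(s1$structure), write_pdb(s2$structure))
  s3 <- make_duplex(duplex_spec("GC", n_models = 2, noise_sigma = 0.05,
                                seed = 43))
  expect_false(identical(write_pdb(s1$structure), write_pdb(s3$structure)))

  expect_error(make_duplex("GATC"), "A, C, G, U")
  expect_error(duplex_spec("G"), "length")
})

test_that("the annotator recovers the generator ground truth exactly at sigma 0", {
  for (sq in c("GGCGCC", "GACUGU", "AUAUGC")) {
    d <- make_duplex(sq, n_models = 1)
    ann <- annotate_model(d$structure$models[[1]])
    got_pairs <- sort(vapply(ann$pairs, function(p)
      paste0(p$res_i$chain, p$res_i$seq_num, "-", p$res_j$chain,
             p$res_j$seq_num), ""))
    want_pairs <- sort(paste0(d$truth$pairs$chain_i, d$truth$pairs$seq_i,
                              "-", d$truth$pairs$chain_j,
                              d$truth$pairs$seq_j))
    expect_equal(got_pairs, want_pairs)
    got_stacks <- sort(vapply(ann$stacks, function(s)
      paste0(s$res_i$chain, s$res_i$seq_num, "-", s$res_j$chain,
             s$res_j$seq_num), ""))
    want_stacks <- sort(paste0(d$truth$stacks$chain_i,
                               d$truth$stacks$seq_i, "-",
                               d$truth$stacks$chain_j,
                               d$truth$stacks$seq_j))
    expect_equal(got_stacks, want_stacks)
    expect_true(all(vapply(ann$glycosidics, `[[`, "",
                           "conformation") == "anti"))
    for (pk in ann$puckers) {
      expect_equal(pk$mode, "envelope")
      expect_equal(pk$apex_atoms, "C3'")
      expect_equal(pk$apex_sides, "endo")
    }
  }
})

test_that("complementary pair counts are stable across sizes and thresholds", {
  for (n in c(2, 5, 9, 12)) {
    sq <- paste(rep(c("G", "A", "C", "U"), length.out = n), collapse = "")
    d <- make_duplex(sq, n_models = 1)
    for (f in c(0.9, 1, 1.1)) {
      p <- annotation_params(
        hbond_max_da = 3.5 * f, hbond_min_da = 2.4 * f,
        hbond_max_angle_dev = 45 * f, stack_max_centroid_dist = 5.5 * f,
        stack_max_normal_angle = 35 * f, stack_min_vertical = 2.0 * f)
      ann <- annotate_model(d$structure$models[[1]], p)
      expect_length(ann$pairs, n)
    }
  }
})

test_that("noisy duplexes keep high annotator agreement", {
  agreement <- function(sigma, seeds = 1:20) {
    tp <- fp <- fn <- 0
    for (s in seeds) {
      d <- make_duplex(duplex_spec("GGCGCC", n_models = 1,
                                   noise_sigma = sigma, seed = s))
      ann <- suppressWarnings(annotate_model(d$structure$models[[1]]))
      det <- vapply(ann$pairs, function(p)
        paste0(p$res_i$chain, p$res_i$seq_num, "-", p$res_j$chain,
               p$res_j$seq_num), "")
      want <- paste0("A", 1:6, "-B", 6:1)
      dst <- vapply(ann$stacks, function(s)
        paste0(s$res_i$chain, s$res_i$seq_num, "-", s$res_j$chain,
               s$res_j$seq_num), "")
      wst <- c(paste0("A", 1:5, "-A", 2:6), paste0("B", 1:5, "-B", 2:6))
      tp <- tp + length(intersect(det, want)) + length(intersect(dst, wst))
      fp <- fp + length(setdiff(det, want)) + length(setdiff(dst, wst))
      fn <- fn + length(setdiff(want, det)) + length(setdiff(wst, dst))
    }
    2 * tp / (2 * tp + fp + fn)
  }
  expect_gte(agreement(0.05), 0.95)
  expect_gte(agreement(0.1), 0.95)
})

test_that("constructed pucker rings carry their parameters", {
  r <- make_pucker_ring("C2'", "endo", 0.5)
  pk <- classify_pucker(r)
  expect_equal(list(pk$mode, pk$apex_atoms, pk$apex_sides),
               list("envelope", "C2'", "endo"))
  quad <- rnakb:::atom_coords(r, setdiff(rnakb:::RIBOSE_RING, "C2'"))
  expect_equal(fit_plane(quad)$rms_deviation, 0, tolerance = 1e-12)
  expect_error(make_pucker_ring("C5'"), "apex")
  expect_error(make_pucker_ring("C3'", "endo", -1), "amplitude")
})

test_that("planned fixtures validate their plans", {
  expect_error(make_kb_fixture(kb_fixture_spec(
    n_models = 1, n_chains = 1, residues_per_chain = 2,
    pair_plan = list(list(model = 1, chain_i = "A", seq_i = 1,
                          chain_j = "B", seq_j = 1,
                          subedges = list(c("Ww", "Ww")))))),
    "nonexistent")
  expect_error(make_kb_fixture(kb_fixture_spec(
    n_models = 1, n_chains = 1, residues_per_chain = 3,
    pair_plan = list(list(model = 1, chain_i = "A", seq_i = 1,
                          chain_j = "A", seq_j = 2,
                          subedges = list(c("Ww", "Qq")))))))
})

test_that("an empty plan leaves only the model queries non-empty", {
  fx <- make_kb_fixture(kb_fixture_spec(n_models = 4, pdb_id = "1EMP"),
                        schema)
  expect_length(fx$truth$A, 4)
  expect_identical(fx$truth$A, fx$truth$F)
  for (q in c("B", "C", "D", "E")) expect_length(fx$truth[[q]], 0)
  g <- saturate(fx$graph, schema)
  for (q in c("A", "B", "C", "D", "E", "F")) {
    expect_identical(run_stored_query(q, g, schema, "1EMP")$individuals,
                     fx$truth[[q]])
  }
})

test_that("a planned Hh/Ww interaction drives queries B through E", {
  fx <- make_kb_fixture(kb_fixture_spec(
    n_models = 3, n_chains = 2, residues_per_chain = 2,
    pair_plan = list(list(model = 2, chain_i = "A", seq_i = 1,
                          chain_j = "B", seq_j = 1,
                          subedges = list(c("Hh", "Ww")))),
    pdb_id = "1PLN"), schema)
  g <- saturate(fx$graph, schema)
  expect_length(fx$truth$B, 1)
  expect_identical(fx$truth$D, fx$truth$B)
  for (q in c("B", "C", "D", "E")) {
    got <- run_stored_query(q, g, schema, "1PLN")$individuals
    expect_identical(got, fx$truth[[q]], label = paste("query", q))
  }
  # residue A:1 is a G under the default sequence, so C matches too
  expect_length(fx$truth$C, 1)
})
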