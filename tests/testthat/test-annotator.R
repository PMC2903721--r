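test_that("ideal Watson-Crick G:C geometry yields the three canonical bonds", {
  d <- make_duplex("GC", n_models = 1)
  m <- d$structure$models[[1]]
  g <- m$chains$A[[1]]; c <- m$chains$B[[2]]
  hb <- detect_hydrogen_bonds(g, c)
  key <- paste(hb$donor_atom, hb$acceptor_atom)
  expect_setequal(key, c("N1 N3", "N2 O2", "N4 O6"))
  expect_true(all(hb$distance > 2.4 & hb$distance < 3.5))

  # scanning order must not matter, roles preserved
  hb2 <- detect_hydrogen_bonds(c, g)
  expect_equal(hb2[order(hb2$donor_atom), c("donor_atom", "acceptor_atom")],
               hb[order(hb$donor_atom), c("donor_atom", "acceptor_atom")],
               ignore_attr = TRUE)
})

test_that("distant residues give no hydrogen bonds", {
  d <- make_duplex("GC", n_models = 1)
  m <- d$structure$models[[1]]
  g <- m$chains$A[[1]]; c <- m$chains$B[[2]]
  c$atoms$x <- c$atoms$x + 20
  expect_equal(nrow(detect_hydrogen_bonds(g, c)), 0)
})

test_that("hydrogen-bond detection matches the brute-force oracle", {
  for (sq in c("GGCGCC", "AUAUGC")) {
    d <- make_duplex(sq, n_models = 1)
    entries <- rnakb:::model_residues(d$structure$models[[1]])
    n <- length(entries)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        got <- detect_hydrogen_bonds(entries[[i]]$res, entries[[j]]$res)
        want <- oracle_hbonds(entries[[i]]$res, entries[[j]]$res)
        expect_equal(got, want, ignore_attr = TRUE)
      }
    }
  }
})

test_that("face lookup follows the bundled LW+ table", {
  expect_equal(subedge_of_atom("G", "O2'"), "O2p")
  expect_equal(subedge_of_atom("A", "C8"), "C8")
  expect_true(is.na(subedge_of_atom("C", "P")))
  expect_equal(subedge_of_atom("C", "N3"), "Ww")
  expect_equal(subedge_of_atom("U", "N1"), "Sw")
  expect_error(subedge_of_atom("HOH", "O"), "unknown residue class")
})

test_that("every sub-edge agglomerates to exactly one edge", {
  edges <- edge_of_subedge(rnakb:::SUBEDGE_KINDS)
  expect_length(edges, 12)
  expect_setequal(unique(edges), c("WatsonCrick", "Hoogsteen", "Sugar"))
  expect_equal(sum(edges == "Hoogsteen"), 4)
  expect_equal(edge_of_subedge(c("C8", "Hh", "Hw", "Bh")),
               rep("Hoogsteen", 4))
  expect_error(edge_of_subedge("Xx"), "unknown sub-edge")
})

test_that("a complementary duplex yields exactly its Watson-Crick pairs", {
  for (sq in c("GGCGCC", "GACUGU")) {
    n <- nchar(sq)
    d <- make_duplex(sq, n_models = 1)
    pairs <- detect_base_pairs(d$structure$models[[1]])
    expect_length(pairs, n)
    for (p in pairs) {
      expect_equal(p$res_i$chain, "A")
      expect_equal(p$res_j$chain, "B")
      expect_equal(p$res_i$seq_num + p$res_j$seq_num, n + 1)
      expect_equal(p$lw_edge_i, "WatsonCrick")
      expect_equal(p$lw_edge_j, "WatsonCrick")
      expect_equal(p$orientation, "cis")
      expect_true(any(vapply(p$interactions, function(it)
        it$subedge_i == "Ww" && it$subedge_j == "Ww", TRUE)))
    }
  }
})

test_that("pair detection is empty for well-separated chains", {
  d <- make_duplex("GGC", n_models = 1)
  m <- d$structure$models[[1]]
  for (k in seq_along(m$chains$B)) {
    m$chains$B[[k]]$atoms$x <- m$chains$B[[k]]$atoms$x + 50
  }
  # strand A alone has no intra-strand hydrogen-bonded pairs either
  expect_length(detect_base_pairs(m), 0)
})

test_that("stack normal-orientation follows the stated sign convention", {
  r1 <- flat_ring_residue("A", 1, c(0, 0, 0))
  r2_up <- flat_ring_residue("A", 3, c(0, 0, 3.4))
  m <- list(model_num = 1L,
            chains = list(A = list(r1, guanine_residue("A", 2, jitter = 50),
                                   r2_up)))
  st <- detect_base_stacks(m)
  expect_length(st, 1)
  expect_equal(st[[1]]$normal_orientation, "upward")
  expect_equal(st[[1]]$adjacency, "non_adjacent")

  r2_in <- flat_ring_residue("A", 3, c(0, 0, 3.4), flip = TRUE)
  m2 <- list(model_num = 1L,
             chains = list(A = list(r1, guanine_residue("A", 2, jitter = 50),
                                    r2_in)))
  st2 <- detect_base_stacks(m2)
  expect_length(st2, 1)
  expect_equal(st2[[1]]$normal_orientation, "inward")
})

test_that("duplex stacking is exactly the adjacent intra-strand set", {
  d <- make_duplex("GGCGCC", n_models = 1)
  st <- detect_base_stacks(d$structure$models[[1]])
  expect_length(st, 10)
  expect_true(all(vapply(st, function(s) s$adjacency == "adjacent", TRUE)))
  got <- vapply(st, function(s)
    paste0(s$res_i$chain, s$res_i$seq_num, "-", s$res_j$chain,
           s$res_j$seq_num), "")
  expect_setequal(got, c(paste0("A", 1:5, "-A", 2:6),
                         paste0("B", 1:5, "-B", 2:6)))
})

test_that("pucker classification recovers constructed envelopes", {
  for (apex in c("C1'", "C2'", "C3'", "C4'", "O4'")) {
    for (side in c("endo", "exo")) {
      r <- make_pucker_ring(apex, side, 0.5)
      pk <- classify_pucker(r)
      expect_equal(pk$mode, "envelope")
      expect_equal(pk$apex_atoms, apex)
      expect_equal(pk$apex_sides, side)
    }
  }
  expect_equal(classify_pucker(make_pucker_ring("C3'", "endo", 0))$mode,
               "planar")
})

test_that("twist geometries report two apexes on opposite sides", {
  # adjacent ring atoms displaced to opposite sides: a classic twist; the
  # apex pair itself is ambiguous on a symmetric ring, but the contract
  # (two apexes, opposite endo/exo sides) must hold
  ang <- 90 - 72 * (0:4)
  m <- cbind(1.26 * cos(ang * pi / 180), 1.26 * sin(ang * pi / 180), 0)
  rownames(m) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  m["C2'", 3] <- 0.6
  m["C3'", 3] <- -0.6
  atoms <- do.call(rbind, c(lapply(rownames(m), function(nm)
    atom_record(nm, m[nm, ])),
    list(atom_record("C5'", c(0, -1.2, 1.2)))))
  r <- new_residue("A", 1, "RIB", atoms)
  pk <- classify_pucker(r)
  expect_equal(pk$mode, "twist")
  expect_length(pk$apex_atoms, 2)
  expect_setequal(pk$apex_sides, c("endo", "exo"))
  r2 <- r
  r2$atoms <- r2$atoms[r2$atoms$name != "O4'", ]
  expect_error(classify_pucker(r2), "missing")
})

test_that("glycosidic conformation follows the chi range rule", {
  d <- make_duplex("GACU", n_models = 1)
  for (e in rnakb:::model_residues(d$structure$models[[1]])) {
    gl <- classify_glycosidic(e$res)
    expect_equal(gl$conformation, "anti")
    expect_true(gl$chi < -90 || gl$chi > 90)
  }
  # constructed chi = 0 (syn): put the chi reference atom eclipsing O4'
  r <- make_pucker_ring("C3'", "endo", 0.3)
  xyz <- rnakb:::atom_xyz
  c1 <- xyz(r, "C1'")
  nv <- c1 + c(0, 1.4, 0.4)
  r$atoms <- rbind(r$atoms, atom_record("N9", nv),
                   atom_record("C4", nv + (xyz(r, "O4'") - c1)))
  gl <- classify_glycosidic(r)
  expect_equal(gl$conformation, "syn")
})

test_that("annotation aggregates all detectors deterministically", {
  expect_length(annotate_model(list(model_num = 1L, chains = list()))$pairs,
                0)
  d <- make_duplex("GGCGCC", n_models = 2)
  a1 <- annotate_model(d$structure$models[[1]])
  a2 <- annotate_model(d$structure$models[[2]])
  a1$model_num <- a2$model_num
  expect_equal(a1, a2)
  expect_length(a1$pairs, 6)
  expect_length(a1$stacks, 10)
  expect_equal(unique(vapply(a1$glycosidics, `[[`, "", "conformation")),
               "anti")
  pk <- a1$puckers[["A:1"]]
  expect_equal(pk$mode, "envelope")
  expect_equal(pk$apex_atoms, "C3'")
  expect_equal(pk$apex_sides, "endo")
})

test_that("a degraded residue drops out of features with a warning", {
  d <- make_duplex("GGCGCC", n_models = 1)
  m <- d$structure$models[[1]]
  r <- m$chains$A[[3]]
  r$atoms <- r$atoms[grepl("'", r$atoms$name), ]  # base atoms deleted
  r$residue_class <- classify_residue(r)
  m$chains$A[[3]] <- r
  expect_warning(ann <- annotate_model(m), "A:3")
  involved <- function(feats) any(vapply(feats, function(p)
    (p$res_i$chain == "A" && p$res_i$seq_num == 3) ||
      (p$res_j$chain == "A" && p$res_j$seq_num == 3), TRUE))
  expect_false(involved(ann$pairs))
  expect_false(involved(ann$stacks))
})

test_that("pair and stack detection are order-independent", {
  d <- make_duplex("GCGC", n_models = 1)
  m <- d$structure$models[[1]]
  m2 <- m
  m2$chains <- rev(m2$chains)
  m2$chains$A <- rev(m2$chains$A)
  key <- function(feats) sort(vapply(feats, function(p)
    paste0(p$res_i$chain, p$res_i$seq_num, "-", p$res_j$chain,
           p$res_j$seq_num), ""))
  expect_equal(key(detect_base_pairs(m2)), key(detect_base_pairs(m)))
  expect_equal(key(detect_base_stacks(m2)), key(detect_base_stacks(m)))
})

test_that("annotation parameters validate and read from YAML", {
  expect_error(annotation_params(hbond_min_da = 4), "hbond_min_da")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("hbond_max_da: 3.3", "pair_min_interactions: 2"), path)
  p <- read_annotation_params(path)
  expect_equal(p$hbond_max_da, 3.3)
  expect_equal(p$pair_min_interactions, 2L)
  expect_equal(p$pucker_tol, 0.10)
})
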