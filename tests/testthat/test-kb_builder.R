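schema <- load_schema()

test_that("URIs follow the naming scheme with prime sanitization", {
  ns <- rnakb:::RNAKB_DATA_NS
  expect_equal(mint_uri(list(kind = "residue", pdb_id = "1aju",
                             chain = "A", seq_num = 34)),
               paste0(ns, "1AJU_cA_r34"))
  expect_equal(mint_uri(list(kind = "quality", pdb_id = "1AM0",
                             model_num = 7, chain = "A", seq_num = 5,
                             quality_token = "anti")),
               paste0(ns, "1AM0_m7_cA_r5_anti"))
  expect_equal(mint_uri(list(kind = "atom", pdb_id = "1AJU", chain = "A",
                             seq_num = 36, atom_name = "O2'")),
               paste0(ns, "1AJU_cA_r36_aO2p"))
  expect_equal(mint_uri(list(kind = "structure_model", pdb_id = "1AM0",
                             model_num = 5)),
               paste0(ns, "1AM0_m5"))
  expect_equal(mint_uri(list(kind = "base_pair", pdb_id = "1AJU",
                             model_num = 5, chain = "A", seq_num = 34,
                             chain2 = "A", seq_num2 = 36)),
               paste0(ns, "1AJU_m5_cA_r34_cA_r36_bp"))
  expect_equal(mint_uri(list(kind = "subedge", pdb_id = "1AJU",
                             model_num = 5, chain = "A", seq_num = 36,
                             subedge = "O2p")),
               paste0(ns, "1AJU_m5_cA_r36_seO2p"))
  expect_equal(mint_uri(list(kind = "nucleoside", pdb_id = "1AJU",
                             chain = "A", seq_num = 34)),
               paste0(ns, "1AJU_cA_r34_ns"))
  expect_error(mint_uri(list(kind = "residue", pdb_id = "1AJU",
                             chain = "A")), "seq_num")
  expect_error(mint_uri(list(kind = "unknown_kind")), "unknown")
})

test_that("distinct descriptors mint distinct URIs", {
  descs <- list()
  for (kind in c("residue", "nucleoside", "ribose", "nucleobase")) {
    for (chain in c("A", "B")) {
      for (seq in 1:3) {
        descs[[length(descs) + 1]] <-
          list(kind = kind, pdb_id = "1ABC", chain = chain, seq_num = seq)
      }
    }
  }
  for (m in 1:2) {
    descs[[length(descs) + 1]] <- list(kind = "structure_model",
                                       pdb_id = "1ABC", model_num = m)
    for (tok in c("anti", "envelope", "C3p_endo")) {
      descs[[length(descs) + 1]] <-
        list(kind = "quality", pdb_id = "1ABC", model_num = m, chain = "A",
             seq_num = 1, quality_token = tok)
    }
  }
  uris <- vapply(descs, mint_uri, "")
  expect_false(anyDuplicated(uris) > 0)
})

test_that("a featureless fixture yields one model individual and its file link", {
  fx <- make_kb_fixture(kb_fixture_spec(n_models = 1, n_chains = 1,
                                        residues_per_chain = 2,
                                        pdb_id = "1FIX"), schema)
  g <- fx$graph
  expect_length(instances_of(g, "structure_model"), 1)
  file_uri <- unname(g$label_index["Molecular Structure File PDB:1fix"])
  rep_triples <- g$triples[g$triples$p == "is_represented_by", ]
  expect_equal(nrow(rep_triples), 1)
  expect_equal(rep_triples$o, file_uri)
  expect_length(instances_of(g, "molecular_structure_file"), 1)
})

test_that("duplex population conserves counts from the annotations", {
  d <- make_duplex("GGCGCC", n_models = 2)
  g <- build_graph(d$structure, schema = schema)
  expect_length(instances_of(g, "structure_model"), 2)
  bp <- instances_of(g, "nucleotide_base_pair")
  expect_length(bp, 12)
  hpp <- g$triples[g$triples$p == "has_proper_part", ]
  for (u in bp) {
    fillers <- hpp$o[hpp$s == u]
    expect_length(fillers, 2)
    expect_true(all(grepl("_r[0-9]+$", fillers)))
  }
  # sequence chaining: n-1 isImmediatelyBefore links per chain per... the
  # relation is model-independent, so 5 per chain
  ib <- g$triples[g$triples$p == "isImmediatelyBefore", ]
  expect_equal(nrow(ib), 2 * 5)
  # stacks and their qualities
  st <- instances_of(g, "nucleotide_base_stack")
  expect_length(st, 20)
  hq <- g$triples[g$triples$p == "has_quality", ]
  for (u in st) expect_length(hq$o[hq$s == u], 2)
  # every quality individual bears exactly one bearer link
  qo <- g$triples[g$triples$p == "quality_of", ]
  expect_false(anyDuplicated(qo$s) > 0)
  # pair participants are typed sub-edges, externally connected pairwise
  ect <- g$triples[g$triples$p == "externally_connected_to", ]
  expect_true(all(grepl("_se", ect$s) & grepl("_se", ect$o)))
  expect_gte(nrow(ect), 12)
})

test_that("pucker and glycosidic qualities attach to the right bearers", {
  d <- make_duplex("GC", n_models = 1)
  g <- build_graph(d$structure, schema = schema)
  anti <- instances_of(g, "anti_conformation")
  expect_length(anti, 4)
  qo <- g$triples[g$triples$p == "quality_of", ]
  expect_true(all(grepl("_ns$", qo$o[qo$s %in% anti])))
  env <- instances_of(g, "envelope_conformation")
  expect_length(env, 4)
  expect_true(all(grepl("_rib$", qo$o[qo$s %in% env])))
  endo <- instances_of(g, "endo")
  expect_length(endo, 4)
  expect_true(all(grepl("_aC3p$", qo$o[qo$s %in% endo])))
})

test_that("annotations naming absent residues abort the build", {
  d <- make_duplex("GC", n_models = 1)
  anns <- annotate_structure(d$structure)
  anns[[1]]$pairs[[1]]$res_i$seq_num <- 99L
  expect_error(build_graph(d$structure, anns, schema), "absent")
})

test_that("serialization round-trips and is deterministic", {
  fx <- make_kb_fixture(kb_fixture_spec(
    n_models = 2, n_chains = 2, residues_per_chain = 3,
    pair_plan = list(list(model = 1, chain_i = "A", seq_i = 1,
                          chain_j = "B", seq_j = 2,
                          subedges = list(c("Ww", "Ww"), c("Hh", "O2p")))),
    stack_plan = list(list(model = 2, chain_i = "A", seq_i = 1,
                           chain_j = "A", seq_j = 2)),
    pdb_id = "1RTT"), schema)
  g <- fx$graph
  for (fmt in c("ntriples", "turtle")) {
    txt <- serialize_graph(g, fmt)
    expect_identical(serialize_graph(g, fmt), txt)  # byte-identical
    g2 <- parse_graph(txt, fmt)
    expect_setequal(rnakb:::triple_keys(g2$triples),
                    rnakb:::triple_keys(g$triples))
    expect_equal(sort(names(g2$label_index)), sort(names(g$label_index)))
  }
  expect_error(serialize_graph(g, "rdfxml"))
})

test_that("parsing applies set semantics and flags syntax errors", {
  doc <- c('<http://x.org/a> <http://x.org/p> <http://x.org/b> .',
           '<http://x.org/a> <http://x.org/p> <http://x.org/b> .',
           '<http://x.org/a> <http://x.org/q> "a label" .')
  g <- parse_graph(doc, "ntriples")
  expect_equal(graph_size(g), 2)
  expect_error(parse_graph('<http://x.org/a> <http://x.org/p> .',
                           "ntriples"), "3 terms")
  expect_error(parse_graph('<http://x.org/a> <p> <q>', "ntriples"),
               "line 1")
  g0 <- parse_graph(character(0), "ntriples")
  expect_equal(graph_size(g0), 0)
  expect_length(serialize_graph(kb_graph(), "ntriples"), 0)
})
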