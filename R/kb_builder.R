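# Knowledge-graph population: URI minting per the naming scheme and triple
# emission relating information content entities (file, structure models),
# material entities (molecules, residues, atoms, base pairs, base stacks,
# sub-edge participants) and their qualities.
#
# Naming scheme (local names, prefixed with the data namespace):
#   file                PDBID
#   structure model     PDBID_mMODEL
#   molecule (chain)    PDBID_cCHAIN
#   residue             PDBID_cCHAIN_rRESIDUE
#   atom                PDBID_cCHAIN_rRESIDUE_aATOM
#   nucleoside/ribose/nucleobase   residue + _ns / _rib / _nb
#   quality             PDBID_mMODEL_cCHAIN_rRESIDUE_QUALITY
#   base pair / stack   PDBID_mMODEL_cC1_rR1_cC2_rR2_bp | _stk
#   sub-edge participant PDBID_mMODEL_cCHAIN_rRESIDUE_seFACE
# Prime characters are replaced by "p" (O2' -> O2p); local names are
# URI-safe. Residues, atoms and molecules are model-independent material
# entities; features and qualities are minted per model.

uri_token <- function(x) {
  x <- gsub("'", "p", x, fixed = TRUE)
  gsub("[^A-Za-z0-9]+", "_", x)
}

residue_token <- function(seq_num, icode = "") {
  paste0("r", seq_num, uri_token(icode))
}

#' Mint a URI for a knowledge-base entity
#'
#' @param d Entity descriptor: list with `kind` (one of `file`,
#'   `structure_model`, `molecule`, `residue`, `atom`, `nucleoside`,
#'   `ribose`, `nucleobase`, `base_pair`, `base_stack`, `subedge`,
#'   `quality`) and the fields that kind requires (`pdb_id`, `model_num`,
#'   `chain`, `seq_num`, `icode`, `atom_name`, `quality_token`,
#'   `subedge`, `chain2`, `seq_num2`, `icode2`).
#' @param ns Namespace prefix.
#' @return Full URI string.
#' @export
mint_uri <- function(d, ns = RNAKB_DATA_NS) {
  need <- function(...) {
    fields <- c(...)
    miss <- fields[!vapply(fields, function(f)
      !is.null(d[[f]]) && !is.na(d[[f]]), TRUE)]
    if (length(miss)) {
      stop("descriptor of kind '", d$kind, "' is missing field(s): ",
           paste(miss, collapse = ", "))
    }
  }
  ic <- function(f = "icode") if (is.null(d[[f]])) "" else d[[f]]
  pid <- function() { need("pdb_id"); toupper(d$pdb_id) }
  res_local <- function() {
    need("pdb_id", "chain", "seq_num")
    paste0(pid(), "_c", uri_token(d$chain), "_",
           residue_token(d$seq_num, ic()))
  }
  model_res_local <- function() {
    need("model_num")
    paste0(pid(), "_m", d$model_num, "_c", uri_token(d$chain), "_",
           residue_token(d$seq_num, ic()))
  }
  feature_local <- function(suffix) {
    need("pdb_id", "model_num", "chain", "seq_num", "chain2", "seq_num2")
    paste0(pid(), "_m", d$model_num,
           "_c", uri_token(d$chain), "_", residue_token(d$seq_num, ic()),
           "_c", uri_token(d$chain2), "_",
           residue_token(d$seq_num2, ic("icode2")), "_", suffix)
  }
  local <- switch(
    d$kind,
    file = pid(),
    structure_model = { need("pdb_id", "model_num")
                        paste0(pid(), "_m", d$model_num) },
    molecule = { need("pdb_id", "chain")
                 paste0(pid(), "_c", uri_token(d$chain)) },
    residue = res_local(),
    atom = { need("atom_name")
             paste0(res_local(), "_a", uri_token(d$atom_name)) },
    nucleoside = paste0(res_local(), "_ns"),
    ribose = paste0(res_local(), "_rib"),
    nucleobase = paste0(res_local(), "_nb"),
    quality = { need("model_num", "quality_token")
                paste0(model_res_local(), "_", uri_token(d$quality_token)) },
    subedge = { need("model_num", "subedge")
                paste0(model_res_local(), "_se", uri_token(d$subedge)) },
    base_pair = feature_local("bp"),
    base_stack = feature_local("stk"),
    stop("unknown descriptor kind: ", d$kind)
  )
  paste0(ns, local)
}

#' Populate a knowledge graph from a structure and its annotations
#'
#' Emits the full entity web: the file individual (typed
#' 'molecular structure file', labeled `Molecular Structure File
#' PDB:<id>`); one 'structure model' individual per model, represented by
#' the file and about the model's molecules, base pairs and base stacks;
#' per-chain molecule individuals holding residues via 'has proper part';
#' residues typed by species with nucleoside/ribose/nucleobase parts, their
#' atoms, and 'isImmediatelyBefore' chaining; base-pair individuals with
#' their residues, sub-edge participant individuals (typed by sub-edge
#' class, part of their residue, pairwise 'externally connected to');
#' base-stack individuals with adjacency and normal-orientation qualities;
#' and per-model glycosidic (nucleoside), pucker (ribose) and endo/exo
#' (apex atom) quality individuals. Residues classified `non_nucleic`
#' (waters, ions) are not emitted.
#'
#' @param f A `molecular_structure_file`.
#' @param anns List of `model_annotation`, one per model (default: run
#'   [annotate_structure()]).
#' @param schema A `schema_catalog`.
#' @param ns Data namespace for minted URIs.
#' @param about_atoms Also assert 'is about' from models to residues and
#'   atoms (default: molecules, pairs and stacks only).
#' @param emit_orientation Emit cis/trans pair-orientation qualities.
#' @return A `kb_graph`.
#' @export
build_graph <- function(f, anns = NULL, schema = load_schema(),
                        ns = RNAKB_DATA_NS, about_atoms = FALSE,
                        emit_orientation = FALSE) {
  stopifnot(inherits(f, "molecular_structure_file"))
  if (is.null(anns)) anns <- annotate_structure(f)
  if (length(anns) != length(f$models)) {
    stop("need one model annotation per model (", length(f$models),
         " models, ", length(anns), " annotations)")
  }
  pdb <- f$pdb_id
  rows <- new.env(parent = emptyenv())
  rows$acc <- vector("list", 4096); rows$n <- 0L
  emit <- function(s, p, o, lit = FALSE) {
    rows$n <- rows$n + 1L
    if (rows$n > length(rows$acc)) length(rows$acc) <- 2L * length(rows$acc)
    rows$acc[[rows$n]] <- c(s, p, o, if (lit) "1" else "0")
  }
  cls <- function(label) schema_id(label)

  file_uri <- mint_uri(list(kind = "file", pdb_id = pdb), ns)
  emit(file_uri, "rdf:type", cls("molecular structure file"))
  emit(file_uri, "rdfs:label",
       paste0("Molecular Structure File PDB:", tolower(pdb)), lit = TRUE)

  for (mi in seq_along(f$models)) {
    model <- f$models[[mi]]
    ann <- anns[[mi]]
    mnum <- model$model_num
    model_uri <- mint_uri(list(kind = "structure_model", pdb_id = pdb,
                               model_num = mnum), ns)
    emit(model_uri, "rdf:type", cls("structure model"))
    emit(model_uri, "rdfs:label",
         paste0("Structure Model ", mnum, " PDB:", tolower(pdb)), lit = TRUE)
    emit(model_uri, "is_represented_by", file_uri)

    entries <- Filter(function(e) is_nucleotide(e$res),
                      model_residues(model))
    res_index <- stats::setNames(entries, vapply(entries, `[[`, "", "key"))
    res_uri_of <- function(key) {
      e <- res_index[[key]]
      if (is.null(e)) {
        stop("annotation refers to residue ", key,
             " absent from model ", mnum)
      }
      r <- e$res
      mint_uri(list(kind = "residue", pdb_id = pdb, chain = r$chain_id,
                    seq_num = r$seq_num, icode = r$icode), ns)
    }

    for (ck in names(model$chains)) {
      keep <- Filter(is_nucleotide, model$chains[[ck]])
      if (length(keep) == 0) next
      mol_uri <- mint_uri(list(kind = "molecule", pdb_id = pdb, chain = ck),
                          ns)
      emit(mol_uri, "rdf:type", cls("molecule"))
      emit(model_uri, "is_about", mol_uri)
      prev_uri <- NULL
      for (r in keep) {
        base <- list(pdb_id = pdb, chain = ck, seq_num = r$seq_num,
                     icode = r$icode)
        r_uri <- mint_uri(c(base, kind = "residue"), ns)
        emit(r_uri, "rdf:type", cls(RESIDUE_CLASS_LABEL[[r$residue_class]]))
        emit(mol_uri, "has_proper_part", r_uri)
        if (!is.null(prev_uri)) emit(prev_uri, "isImmediatelyBefore", r_uri)
        prev_uri <- r_uri
        ns_uri <- mint_uri(c(base, kind = "nucleoside"), ns)
        rib_uri <- mint_uri(c(base, kind = "ribose"), ns)
        nb_uri <- mint_uri(c(base, kind = "nucleobase"), ns)
        emit(ns_uri, "rdf:type", cls("nucleoside"))
        emit(rib_uri, "rdf:type", cls("ribose"))
        emit(nb_uri, "rdf:type", cls("nucleobase"))
        emit(r_uri, "has_proper_part", ns_uri)
        emit(ns_uri, "has_proper_part", rib_uri)
        emit(ns_uri, "has_proper_part", nb_uri)
        if (about_atoms) emit(model_uri, "is_about", r_uri)
        for (an in r$atoms$name) {
          a_uri <- mint_uri(c(base, kind = "atom", atom_name = an), ns)
          emit(a_uri, "rdf:type", cls("atom"))
          emit(r_uri, "has_proper_part", a_uri)
          if (about_atoms) emit(model_uri, "is_about", a_uri)
        }
      }
    }

    ref_key <- function(ref) paste0(ref$chain, ":", ref$seq_num, ref$icode)
    for (bp in ann$pairs) {
      ki <- ref_key(bp$res_i); kj <- ref_key(bp$res_j)
      ri_uri <- res_uri_of(ki); rj_uri <- res_uri_of(kj)
      bp_uri <- mint_uri(list(
        kind = "base_pair", pdb_id = pdb, model_num = mnum,
        chain = bp$res_i$chain, seq_num = bp$res_i$seq_num,
        icode = bp$res_i$icode, chain2 = bp$res_j$chain,
        seq_num2 = bp$res_j$seq_num, icode2 = bp$res_j$icode), ns)
      emit(bp_uri, "rdf:type", cls("nucleotide base pair"))
      emit(bp_uri, "has_proper_part", ri_uri)
      emit(bp_uri, "has_proper_part", rj_uri)
      emit(model_uri, "is_about", bp_uri)
      for (it in bp$interactions) {
        pi_uri <- mint_uri(list(
          kind = "subedge", pdb_id = pdb, model_num = mnum,
          chain = bp$res_i$chain, seq_num = bp$res_i$seq_num,
          icode = bp$res_i$icode, subedge = it$subedge_i), ns)
        pj_uri <- mint_uri(list(
          kind = "subedge", pdb_id = pdb, model_num = mnum,
          chain = bp$res_j$chain, seq_num = bp$res_j$seq_num,
          icode = bp$res_j$icode, subedge = it$subedge_j), ns)
        emit(pi_uri, "rdf:type", cls(SUBEDGE_CLASS_LABEL[[it$subedge_i]]))
        emit(pj_uri, "rdf:type", cls(SUBEDGE_CLASS_LABEL[[it$subedge_j]]))
        emit(bp_uri, "has_part", pi_uri)
        emit(bp_uri, "has_part", pj_uri)
        emit(pi_uri, "part_of", ri_uri)
        emit(pj_uri, "part_of", rj_uri)
        emit(pi_uri, "externally_connected_to", pj_uri)
      }
      if (emit_orientation && !is.na(bp$orientation)) {
        q_uri <- paste0(bp_uri, "_", bp$orientation)
        emit(q_uri, "rdf:type", cls(paste0(bp$orientation, " orientation")))
        emit(bp_uri, "has_quality", q_uri)
      }
    }

    for (st in ann$stacks) {
      ki <- ref_key(st$res_i); kj <- ref_key(st$res_j)
      ri_uri <- res_uri_of(ki); rj_uri <- res_uri_of(kj)
      st_uri <- mint_uri(list(
        kind = "base_stack", pdb_id = pdb, model_num = mnum,
        chain = st$res_i$chain, seq_num = st$res_i$seq_num,
        icode = st$res_i$icode, chain2 = st$res_j$chain,
        seq_num2 = st$res_j$seq_num, icode2 = st$res_j$icode), ns)
      emit(st_uri, "rdf:type", cls("nucleotide base stack"))
      emit(st_uri, "has_proper_part", ri_uri)
      emit(st_uri, "has_proper_part", rj_uri)
      emit(model_uri, "is_about", st_uri)
      adj_uri <- paste0(st_uri, "_adj")
      emit(adj_uri, "rdf:type",
           cls(if (st$adjacency == "adjacent") "adjacent stack quality"
               else "non-adjacent stack quality"))
      emit(st_uri, "has_quality", adj_uri)
      or_uri <- paste0(st_uri, "_orient")
      emit(or_uri, "rdf:type", cls(st$normal_orientation))
      emit(st_uri, "has_quality", or_uri)
    }

    emit_res_quality <- function(key, token, class_label, target_uri) {
      e <- res_index[[key]]
      if (is.null(e)) {
        stop("annotation refers to residue ", key,
             " absent from model ", mnum)
      }
      r <- e$res
      q_uri <- mint_uri(list(kind = "quality", pdb_id = pdb,
                             model_num = mnum, chain = r$chain_id,
                             seq_num = r$seq_num, icode = r$icode,
                             quality_token = token), ns)
      emit(q_uri, "rdf:type", cls(class_label))
      emit(q_uri, "quality_of", target_uri)
    }

    for (key in names(ann$glycosidics)) {
      conf <- ann$glycosidics[[key]]$conformation
      e <- res_index[[key]]
      if (is.null(e)) stop("annotation refers to residue ", key,
                           " absent from model ", mnum)
      r <- e$res
      ns_uri <- mint_uri(list(kind = "nucleoside", pdb_id = pdb,
                              chain = r$chain_id, seq_num = r$seq_num,
                              icode = r$icode), ns)
      emit_res_quality(key, conf, paste0(conf, " conformation"), ns_uri)
    }
    for (key in names(ann$puckers)) {
      pk <- ann$puckers[[key]]
      if (pk$mode == "planar") next
      e <- res_index[[key]]
      if (is.null(e)) stop("annotation refers to residue ", key,
                           " absent from model ", mnum)
      r <- e$res
      base <- list(pdb_id = pdb, chain = r$chain_id, seq_num = r$seq_num,
                   icode = r$icode)
      rib_uri <- mint_uri(c(base, kind = "ribose"), ns)
      emit_res_quality(key, pk$mode, paste0(pk$mode, " conformation"),
                       rib_uri)
      for (ai in seq_along(pk$apex_atoms)) {
        a_uri <- mint_uri(c(base, kind = "atom",
                            atom_name = pk$apex_atoms[ai]), ns)
        emit_res_quality(key,
                         paste0(uri_token(pk$apex_atoms[ai]), "_",
                                pk$apex_sides[ai]),
                         pk$apex_sides[ai], a_uri)
      }
    }
  }

  m <- do.call(rbind, rows$acc[seq_len(rows$n)])
  triples <- data.frame(s = m[, 1], p = m[, 2], o = m[, 3],
                        lit = m[, 4] == "1", stringsAsFactors = FALSE)
  kb_graph(triples, ns = ns)
}
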