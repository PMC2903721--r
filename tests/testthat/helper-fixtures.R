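# Shared fixture builders and independent oracles used across the suite.

# -- tiny structure builders -------------------------------------------------

# guanine base ring + O2' (enough for classification and framing)
guanine_residue <- function(chain = "A", seq = 1, jitter = 0) {
  tpl <- rnakb:::base_template("G")
  atoms <- do.call(rbind, lapply(rownames(tpl), function(nm)
    atom_record(nm, tpl[nm, ] + jitter)))
  atoms <- rbind(atoms, atom_record("O2'", c(3, 3, 1)))
  new_residue(chain, seq, "G", atoms)
}

water_residue <- function(chain = "A", seq = 99) {
  new_residue(chain, seq, "HOH", atom_record("O", c(0, 0, 0)))
}

# a 1-methyladenosine-like residue: adenine ring atoms, nonstandard name
modified_residue <- function(chain = "A", seq = 1) {
  tpl <- rnakb:::base_template("A")
  atoms <- do.call(rbind, lapply(rownames(tpl), function(nm)
    atom_record(nm, tpl[nm, ])))
  atoms <- rbind(atoms, atom_record("CM1", c(2.5, 2.5, 0)),
                 atom_record("O2'", c(3, 3, 1)))
  new_residue(chain, seq, "1MA", atoms)
}

one_model_file <- function(residues, pdb_id = "TST1") {
  chains <- split(residues, vapply(residues, function(r) r$chain_id, ""))
  chains <- lapply(chains, function(rs)
    rs[order(vapply(rs, function(r) r$seq_num, 1L))])
  new_structure_file(pdb_id, list(list(model_num = 1L, chains = chains)))
}

# planar base-ring-only residue for stack geometry cases: a pyrimidine-like
# hexagon traversed counterclockwise (table normal +z), placed with a given
# centroid; flip = TRUE turns the base over (normal -z)
flat_ring_residue <- function(chain, seq, centroid, flip = FALSE) {
  ang <- 90 + 60 * (0:5)
  m <- cbind(1.38 * cos(ang * pi / 180), 1.38 * sin(ang * pi / 180), 0)
  rownames(m) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  if (flip) m[, 3] <- -m[, 3]
  if (flip) m[, 2] <- -m[, 2]  # proper rotation: flip about x-axis
  m <- sweep(m, 2, centroid, FUN = "+")
  atoms <- do.call(rbind, lapply(rownames(m), function(nm)
    atom_record(nm, m[nm, ])))
  atoms <- rbind(atoms, atom_record("O2'", centroid + c(2.5, 0, 0.5)))
  new_residue(chain, seq, "C", atoms)
}

# -- independent hydrogen-bond oracle ---------------------------------------

# brute-force all-atom donor/acceptor scan re-implementing the stated
# criteria with its own vector arithmetic
oracle_hbonds <- function(r1, r2, params = annotation_params()) {
  norm2 <- function(v) sqrt(sum(v^2))
  ang3 <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(max(-1, min(1, sum(u * v) / (norm2(u) * norm2(v))))) * 180 / pi
  }
  get_xyz <- function(r, nm) {
    i <- match(nm, r$atoms$name)
    if (is.na(i)) NULL else as.numeric(r$atoms[i, c("x", "y", "z")])
  }
  ring_normal <- function(r) {
    tabs <- list(c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
                 c("N1", "C2", "N3", "C4", "C5", "C6"))
    for (tb in tabs) {
      if (all(tb %in% r$atoms$name)) {
        pts <- t(vapply(tb, function(nm) get_xyz(r, nm), numeric(3)))
        ctr <- colMeans(pts)
        sv <- svd(sweep(pts, 2, ctr))
        return(sv$v[, 3])
      }
    }
    NULL
  }
  out <- NULL
  for (pair in list(list(r1, r2), list(r2, r1))) {
    rd <- pair[[1]]; ra <- pair[[2]]
    dons <- rnakb:::residue_donors(rd$residue_class)
    accs <- intersect(rnakb:::residue_acceptors(ra$residue_class),
                      ra$atoms$name)
    nrm <- ring_normal(rd)
    for (dn in intersect(names(dons), rd$atoms$name)) {
      dp <- get_xyz(rd, dn)
      antes <- Filter(Negate(is.null),
                      lapply(dons[[dn]], function(a) get_xyz(rd, a)))
      hd <- NULL
      if (length(antes)) {
        s <- Reduce(`+`, lapply(antes, function(a) {
          v <- a - dp; v / norm2(v)
        }))
        if (norm2(s) > 1e-9) hd <- -s / norm2(s)
      }
      for (an in accs) {
        ap <- get_xyz(ra, an)
        d <- norm2(ap - dp)
        if (d < params$hbond_min_da || d > params$hbond_max_da) next
        if (length(antes)) {
          if (any(vapply(antes, function(a) ang3(a, dp, ap), 1) < 90)) next
          if (!is.null(hd)) {
            dev <- ang3(dp + hd, dp, ap)
            if (length(antes) == 1) {
              if (dn == "O2'" || is.null(nrm)) {
                dev <- abs(dev - 60)
              } else {
                rot <- function(v, axis, th) {
                  th <- th * pi / 180
                  axis <- axis / norm2(axis)
                  v * cos(th) + rnakb:::cross3(axis, v) * sin(th) +
                    axis * sum(axis * v) * (1 - cos(th))
                }
                dev <- min(ang3(dp + rot(hd, nrm, 60), dp, ap),
                           ang3(dp + rot(hd, nrm, -60), dp, ap))
              }
            }
            if (dev > params$hbond_max_angle_dev) next
          }
        }
        out <- rbind(out, data.frame(
          donor_res = rnakb:::residue_key(rd), donor_atom = dn,
          acceptor_res = rnakb:::residue_key(ra), acceptor_atom = an,
          distance = d, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(donor_res = character(0), donor_atom = character(0),
                      acceptor_res = character(0),
                      acceptor_atom = character(0), distance = numeric(0))
  }
  out[order(out$donor_res, out$donor_atom, out$acceptor_atom), ,
      drop = FALSE]
}

# -- independent class-expression interpreter --------------------------------

# recursive set interpreter over the raw triple table; written with plain
# loops and vector scans, independent of the package evaluator
naive_eval <- function(node, g, schema) {
  tr <- g$triples
  inds <- unique(tr$s[tr$p == "rdf:type" & !tr$lit])
  sup_of <- function(cid) {
    seen <- character(0); stack <- cid
    while (length(stack)) {
      c0 <- stack[1]; stack <- stack[-1]
      if (c0 %in% seen) next
      seen <- c(seen, c0)
      stack <- c(stack, schema$classes[[c0]]$parents)
      for (aid in names(schema$classes)) {
        eu <- schema$classes[[aid]]$equivalent_union
        if (!is.null(eu) && c0 %in% eu) stack <- c(stack, aid)
      }
    }
    seen
  }
  rec <- function(node) {
    k <- node$kind
    if (k == "named") {
      id <- schema$label_to_id[node$label]
      if (is.na(id)) {
        uri <- g$label_index[node$label]
        if (is.na(uri)) stop("naive: unresolved ", node$label)
        return(unname(uri))
      }
      hit <- character(0)
      for (x in inds) {
        types <- tr$o[tr$p == "rdf:type" & tr$s == x]
        if (id %in% types) hit <- c(hit, x)
      }
      return(hit)
    }
    if (k == "and") return(Reduce(intersect, lapply(node$args, rec)))
    if (k == "or") return(Reduce(union, lapply(node$args, rec)))
    if (k == "nominal") {
      return(unname(vapply(node$labels, function(l) {
        uri <- g$label_index[l]
        if (is.na(uri)) stop("naive: unresolved nominal ", l)
        uri
      }, "")))
    }
    pid <- schema$label_to_id[node$property]
    if (is.na(pid)) pid <- schema$label_to_id[gsub("_", " ", node$property)]
    pid <- unname(pid)
    fillset <- rec(node$filler)
    role <- tr[tr$p == pid & !tr$lit, , drop = FALSE]
    if (node$inverse) role <- data.frame(s = role$o, o = role$s,
                                         stringsAsFactors = FALSE)
    if (k == "some") {
      hit <- unique(role$s[role$o %in% fillset])
      ax <- schema$existential_axioms
      ax <- ax[ax$prop == pid & !node$inverse, , drop = FALSE]
      if (nrow(ax)) {
        named <- if (node$filler$kind == "named") node$filler$label
          else if (node$filler$kind == "or")
            unlist(lapply(node$filler$args,
                          function(a) if (a$kind == "named") a$label))
        nd_ids <- unname(schema$label_to_id[named])
        nd_ids <- nd_ids[!is.na(nd_ids)]
        for (r in seq_len(nrow(ax))) {
          if (any(nd_ids %in% sup_of(ax$filler[r]))) {
            for (x in inds) {
              types <- tr$o[tr$p == "rdf:type" & tr$s == x]
              if (ax$subclass[r] %in% types) hit <- union(hit, x)
            }
          }
        }
      }
      return(hit)
    }
    # exactly
    hit <- character(0)
    for (x in inds) {
      cnt <- sum(role$s == x & role$o %in% fillset)
      if (cnt == node$n) hit <- c(hit, x)
    }
    hit
  }
  sort(unique(rec(node)))
}

# random class expression of bounded depth over schema labels present in a
# fixture graph
random_expression <- function(schema, g, depth = 3) {
  class_labels <- c("nucleotide base pair", "structure model",
                    "nucleotide residue", "GMP residue [chebi:50324]",
                    "hoogsteen edge", "nucleotide edge",
                    "hoogsteen sub-edge", "watson watson sub edge",
                    "hoogsteen hoogsteen sub edge", "molecule", "quality",
                    "nucleotide base stack", "material entity")
  prop_labels <- c("has part", "part of", "has proper part",
                   "externally connected to", "is about",
                   "is represented by", "has quality", "quality of")
  gen <- function(d) {
    if (d <= 0 || stats::runif(1) < 0.35) {
      if (stats::runif(1) < 0.15 && length(g$label_index)) {
        return(list(kind = "nominal",
                    labels = sample(names(g$label_index), 1)))
      }
      return(list(kind = "named", label = sample(class_labels, 1)))
    }
    pick <- sample(c("and", "or", "some", "exactly"), 1)
    if (pick %in% c("and", "or")) {
      return(list(kind = pick, args = list(gen(d - 1), gen(d - 1))))
    }
    prop <- sample(prop_labels, 1)
    filler <- gen(d - 1)
    # the TBox shortcut is defined for named/union fillers only; keep
    # random expressions inside the supported fragment for 'part of'
    if (prop %in% c("part of", "has part") &&
        !filler$kind %in% c("named")) {
      filler <- list(kind = "named", label = sample(class_labels, 1))
    }
    if (pick == "some") {
      return(list(kind = "some", property = prop,
                  inverse = stats::runif(1) < 0.2, filler = filler))
    }
    list(kind = "exactly", n = sample(0:3, 1), property = prop,
         inverse = FALSE, filler = filler)
  }
  gen(depth)
}
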