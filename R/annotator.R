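# Structural feature detection: hydrogen bonds, base pairs with LW/LW+
# classification, base stacks with adjacency and normal-orientation
# qualities, ribose pucker and glycosidic conformation.

#' Annotation parameters
#'
#' Geometric thresholds for feature detection. Defaults (Angstrom, degrees):
#' donor-acceptor distance within \[2.4, 3.5\]; implied-hydrogen deviation
#' from linearity at most 45 degrees; stacked base centroids within 5.5 with
#' normals within 35 degrees (or the supplement) and at least 2.0 vertical
#' separation; ring atoms within 0.10 of a plane count as coplanar for
#' pucker classification; one sub-edge interaction suffices for a pair.
#'
#' @param hbond_max_da,hbond_min_da Donor-acceptor distance window, Angstrom.
#' @param hbond_max_angle_dev Maximum deviation of the donor-acceptor
#'   direction from the implied hydrogen direction, degrees.
#' @param stack_max_centroid_dist Maximum base-centroid distance, Angstrom.
#' @param stack_max_normal_angle Maximum angle between base normals (or its
#'   supplement), degrees.
#' @param stack_min_vertical Minimum centroid offset along the mean normal,
#'   Angstrom.
#' @param pucker_tol Coplanarity/deviation tolerance for pucker calls,
#'   Angstrom.
#' @param pair_min_interactions Minimum sub-edge interactions per base pair.
#' @return An `annotation_params` list.
#' @export
annotation_params <- function(hbond_max_da = 3.5, hbond_min_da = 2.4,
                              hbond_max_angle_dev = 45,
                              stack_max_centroid_dist = 5.5,
                              stack_max_normal_angle = 35,
                              stack_min_vertical = 2.0,
                              pucker_tol = 0.10,
                              pair_min_interactions = 1L) {
  p <- list(hbond_max_da = hbond_max_da, hbond_min_da = hbond_min_da,
            hbond_max_angle_dev = hbond_max_angle_dev,
            stack_max_centroid_dist = stack_max_centroid_dist,
            stack_max_normal_angle = stack_max_normal_angle,
            stack_min_vertical = stack_min_vertical,
            pucker_tol = pucker_tol,
            pair_min_interactions = as.integer(pair_min_interactions))
  stopifnot(all(unlist(p) > 0), p$hbond_min_da < p$hbond_max_da)
  structure(p, class = "annotation_params")
}

#' Read annotation parameters from a YAML file
#' @param path YAML file whose keys match [annotation_params()] arguments.
#' @return An `annotation_params` list.
#' @export
read_annotation_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(annotation_params, vals)
}

NUCLEOTIDE_CLASSES <- c("A", "C", "G", "U", "modified")

# half-angle of the allowed hydrogen cone for single-antecedent donors
# (sp2 amino, hydroxyl), degrees
HDONOR_CONE_DEG <- 60

is_nucleotide <- function(r) r$residue_class %in% NUCLEOTIDE_CLASSES

#' Detect hydrogen bonds between two residues
#'
#' Heavy-atom criterion over the bundled N/O donor and acceptor tables
#' (O2' in both roles): donor-acceptor distance inside the configured
#' window; when the donor's antecedent heavy atoms are present, the
#' antecedent-donor-acceptor angle must be at least 90 degrees and the
#' donor-acceptor direction within `hbond_max_angle_dev` of the implied
#' hydrogen direction (the outward bisector of the antecedent bonds).
#'
#' @param r1,r2 Residues (distinct, both nucleotides).
#' @param params [annotation_params()].
#' @return Data frame with one row per bond: `donor_res`, `donor_atom`,
#'   `acceptor_res`, `acceptor_atom`, `distance`.
#' @export
detect_hydrogen_bonds <- function(r1, r2, params = annotation_params()) {
  stopifnot(is_nucleotide(r1), is_nucleotide(r2))
  if (residue_key(r1) == residue_key(r2)) {
    stop("hydrogen bonds are scanned between distinct residues")
  }
  rows <- rbind(scan_donors(r1, r2, params), scan_donors(r2, r1, params))
  if (is.null(rows)) {
    rows <- data.frame(donor_res = character(0), donor_atom = character(0),
                       acceptor_res = character(0),
                       acceptor_atom = character(0), distance = numeric(0))
  }
  rows[order(rows$donor_res, rows$donor_atom, rows$acceptor_atom), ,
       drop = FALSE]
}

scan_donors <- function(rd, ra, params) {
  out <- NULL
  donors <- residue_donors(rd$residue_class)
  acceptors <- intersect(residue_acceptors(ra$residue_class), ra$atoms$name)
  base_n <- NULL
  frame <- try(base_frame(rd), silent = TRUE)
  if (!inherits(frame, "try-error")) base_n <- frame$normal
  for (dn in intersect(names(donors), rd$atoms$name)) {
    dpos <- atom_xyz(rd, dn)
    ante <- lapply(intersect(donors[[dn]], rd$atoms$name),
                   function(a) atom_xyz(rd, a))
    hdir <- implied_h_direction(dpos, ante)
    for (an in acceptors) {
      apos <- atom_xyz(ra, an)
      d <- vnorm(apos - dpos)
      if (d < params$hbond_min_da || d > params$hbond_max_da) next
      if (length(ante)) {
        angs <- vapply(ante, function(x) angle_at(x, dpos, apos), 1)
        if (any(angs < 90)) next
        if (!is.null(hdir)) {
          dev <- donor_h_deviation(dn, dpos, hdir, length(ante), base_n,
                                   apos)
          if (dev > params$hbond_max_angle_dev) next
        }
      }
      out <- rbind(out, data.frame(
        donor_res = residue_key(rd), donor_atom = dn,
        acceptor_res = residue_key(ra), acceptor_atom = an,
        distance = d, stringsAsFactors = FALSE))
    }
  }
  out
}

# Deviation of the donor-acceptor direction from the nearest plausible
# hydrogen direction. Ring N-H donors (two antecedents) aim the hydrogen
# along the outward bisector; sp2 amino donors carry two in-plane
# hydrogens at +-60 degrees from it; the 2'-hydroxyl hydrogen lies on a
# 60-degree cone (free torsion about C2'-O2').
donor_h_deviation <- function(donor_name, dpos, hdir, n_ante, base_n,
                              apos) {
  da <- apos - dpos
  dev <- angle_between(hdir, da)
  if (n_ante >= 2) return(dev)
  if (donor_name == "O2'" || is.null(base_n)) {
    return(abs(dev - HDONOR_CONE_DEG))
  }
  devs <- vapply(c(-HDONOR_CONE_DEG, HDONOR_CONE_DEG), function(a) {
    angle_between(hdir %*% t(rotation_about_axis(base_n, a)), da)
  }, 1)
  min(devs)
}

implied_h_direction <- function(donor, antecedents) {
  if (length(antecedents) == 0) return(NULL)
  s <- c(0, 0, 0)
  for (a in antecedents) {
    v <- a - donor
    s <- s + v / vnorm(v)
  }
  if (vnorm(s) < 1e-9) return(NULL)
  -s / vnorm(s)
}

angle_at <- function(a, vertex, b) {
  angle_between(a - vertex, b - vertex)
}

angle_between <- function(u, v) {
  cth <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cth))) * 180 / pi
}

# Flattened residue index of a model: list of residues plus ordering info.
model_residues <- function(model) {
  out <- list()
  for (ck in names(model$chains)) {
    rs <- model$chains[[ck]]
    for (i in seq_along(rs)) {
      r <- rs[[i]]
      out[[length(out) + 1]] <- list(res = r, chain = ck, pos = i,
                                     key = residue_key(r))
    }
  }
  out
}

residue_order_key <- function(entry) {
  sprintf("%s|%09d|%s", entry$chain, entry$res$seq_num + 500000L,
          entry$res$icode)
}

#' Detect base pairs in a structure model
#'
#' Every residue pair with at least one hydrogen bond between face atoms
#' contributes; bonds are grouped by (sub-edge, sub-edge) into sub-edge
#' interactions and a pair is emitted when the interaction count reaches
#' `pair_min_interactions`. The Leontis-Westhof edge on each side is the
#' edge of the sub-edge carrying the most hydrogen bonds on that side (ties
#' resolved by the first interaction). Orientation is `cis` when the two
#' glycosidic bonds point to the same side of the pair axis.
#'
#' @param model A structure model (element of a
#'   `molecular_structure_file`'s `models`).
#' @param params [annotation_params()].
#' @return List of `base_pair` objects, ordered by residue reference.
#' @export
detect_base_pairs <- function(model, params = annotation_params()) {
  entries <- Filter(function(e) is_nucleotide(e$res), model_residues(model))
  entries <- entries[order(vapply(entries, residue_order_key, ""))]
  pairs <- list()
  n <- length(entries)
  if (n < 2) return(pairs)
  cents <- lapply(entries, function(e) residue_centroid(e$res))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (vnorm(cents[[j]] - cents[[i]]) > 15) next
      bp <- make_base_pair(entries[[i]], entries[[j]], params)
      if (!is.null(bp)) pairs[[length(pairs) + 1]] <- bp
    }
  }
  pairs
}

residue_centroid <- function(r) {
  colMeans(as.matrix(r$atoms[, c("x", "y", "z")]))
}

make_base_pair <- function(ei, ej, params) {
  ri <- ei$res; rj <- ej$res
  hb <- detect_hydrogen_bonds(ri, rj, params)
  if (nrow(hb) == 0) return(NULL)
  ki <- residue_key(ri)
  # face of each bonded atom, seen from residue i and residue j
  se_i <- ifelse(hb$donor_res == ki,
                 subedge_of_atom(ri$residue_class, hb$donor_atom),
                 subedge_of_atom(ri$residue_class, hb$acceptor_atom))
  se_j <- ifelse(hb$donor_res == ki,
                 subedge_of_atom(rj$residue_class, hb$acceptor_atom),
                 subedge_of_atom(rj$residue_class, hb$donor_atom))
  keep <- !is.na(se_i) & !is.na(se_j)
  if (!any(keep)) return(NULL)
  hb <- hb[keep, , drop = FALSE]
  se_i <- se_i[keep]; se_j <- se_j[keep]
  groups <- split(seq_len(nrow(hb)), paste(se_i, se_j, sep = "/"))
  groups <- groups[order(vapply(groups, min, 1L))]  # first-seen order
  interactions <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    list(subedge_i = se_i[idx[1]], subedge_j = se_j[idx[1]],
         hbonds = hb[idx, , drop = FALSE])
  })
  if (length(interactions) < params$pair_min_interactions) return(NULL)
  structure(
    list(res_i = residue_ref(ri), res_j = residue_ref(rj),
         interactions = interactions,
         lw_edge_i = dominant_edge(interactions, "subedge_i"),
         lw_edge_j = dominant_edge(interactions, "subedge_j"),
         orientation = pair_orientation(ri, rj)),
    class = "base_pair"
  )
}

residue_ref <- function(r) {
  list(chain = r$chain_id, seq_num = r$seq_num, icode = r$icode,
       res_name = r$res_name)
}

# Edge of the sub-edge with the most hydrogen bonds on one side; ties fall
# back to the first interaction's sub-edge.
dominant_edge <- function(interactions, side) {
  counts <- list()
  for (it in interactions) {
    se <- it[[side]]
    counts[[se]] <- (counts[[se]] %||% 0L) + nrow(it$hbonds)
  }
  tallies <- unlist(counts)
  best <- names(tallies)[tallies == max(tallies)]
  if (length(best) > 1) best <- interactions[[1]][[side]]
  edge_of_subedge(best[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cis when both glycosidic bonds point to the same side of the pair axis
# (sign of the triple product with the reference base normal).
pair_orientation <- function(ri, rj) {
  fi <- try(base_frame(ri), silent = TRUE)
  fj <- try(base_frame(rj), silent = TRUE)
  gi <- glycosidic_vector(ri)
  gj <- glycosidic_vector(rj)
  if (inherits(fi, "try-error") || inherits(fj, "try-error") ||
      is.null(gi) || is.null(gj)) {
    return(NA_character_)
  }
  axis <- fj$centroid - fi$centroid
  s_i <- sign(sum(cross3(axis, gi) * fi$normal))
  s_j <- sign(sum(cross3(axis, gj) * fi$normal))
  if (s_i == s_j) "cis" else "trans"
}

glycosidic_vector <- function(r) {
  c1p <- atom_xyz(r, "C1'")
  n <- atom_xyz(r, "N9") %||% atom_xyz(r, "N1")
  if (is.null(c1p) || is.null(n)) return(NULL)
  c1p - n
}

#' Detect base stacks in a structure model
#'
#' Two bases stack when their ring centroids are within
#' `stack_max_centroid_dist`, the angle between their normals (or its
#' supplement) is at most `stack_max_normal_angle`, and the centroid offset
#' projects at least `stack_min_vertical` onto the mean normal. The
#' normal-orientation quality follows the sign pair
#' (sign(n_i . c_ij), sign(n_j . c_ij)): (+,+) upward, (-,-) downward,
#' (+,-) inward, (-,+) outward. A stack is `adjacent` when the residues are
#' consecutive in the same chain.
#'
#' @inheritParams detect_base_pairs
#' @return List of `base_stack` objects.
#' @export
detect_base_stacks <- function(model, params = annotation_params()) {
  entries <- Filter(function(e) is_nucleotide(e$res), model_residues(model))
  entries <- entries[order(vapply(entries, residue_order_key, ""))]
  frames <- lapply(entries, function(e) try(base_frame(e$res), silent = TRUE))
  ok <- !vapply(frames, inherits, TRUE, "try-error")
  entries <- entries[ok]; frames <- frames[ok]
  stacks <- list()
  n <- length(entries)
  if (n < 2) return(stacks)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      fi <- frames[[i]]; fj <- frames[[j]]
      cij <- fj$centroid - fi$centroid
      if (vnorm(cij) > params$stack_max_centroid_dist) next
      ang <- angle_between(fi$normal, fj$normal)
      if (min(ang, 180 - ang) > params$stack_max_normal_angle) next
      mean_n <- fi$normal + sign(sum(fi$normal * fj$normal)) * fj$normal
      mean_n <- mean_n / vnorm(mean_n)
      if (abs(sum(cij * mean_n)) < params$stack_min_vertical) next
      s1 <- sign(sum(fi$normal * cij))
      s2 <- sign(sum(fj$normal * cij))
      orientation <- if (s1 > 0 && s2 > 0) "upward"
        else if (s1 < 0 && s2 < 0) "downward"
        else if (s1 > 0) "inward" else "outward"
      adjacent <- entries[[i]]$chain == entries[[j]]$chain &&
        abs(entries[[i]]$pos - entries[[j]]$pos) == 1
      stacks[[length(stacks) + 1]] <- structure(
        list(res_i = residue_ref(entries[[i]]$res),
             res_j = residue_ref(entries[[j]]$res),
             adjacency = if (adjacent) "adjacent" else "non_adjacent",
             normal_orientation = orientation),
        class = "base_stack")
    }
  }
  stacks
}

RIBOSE_RING <- c("C1'", "C2'", "C3'", "C4'", "O4'")

#' Classify the ribose sugar pucker
#'
#' Envelope when one ring atom lies off the plane of the four others (the
#' quad coplanar within `pucker_tol`, the apex further than `pucker_tol`);
#' twist when two atoms lie on opposite sides of the plane of the remaining
#' three; planar otherwise. Each apex is `endo` when displaced to the same
#' side of the reference plane as C5', `exo` otherwise. When several
#' candidates qualify the one with the largest apex deviation is reported.
#'
#' @param r Residue with a complete ribose ring (C1'-C4', O4') and C5'.
#' @param params [annotation_params()].
#' @return List with `mode` (`"envelope"`, `"twist"` or `"planar"`),
#'   `apex_atoms` and `apex_sides`.
#' @export
classify_pucker <- function(r, params = annotation_params()) {
  ring <- atom_coords(r, RIBOSE_RING)
  c5p <- atom_xyz(r, "C5'")
  if (is.null(ring) || is.null(c5p)) {
    stop("missing ribose ring or C5' atom in residue ", residue_key(r))
  }
  tol <- params$pucker_tol
  side_of <- function(plane, p) {
    if (signed_side(plane, p) * signed_side(plane, c5p) > 0) "endo" else "exo"
  }
  # envelope scan: one apex against the plane of the other four
  best <- NULL
  for (apex in RIBOSE_RING) {
    others <- ring[setdiff(RIBOSE_RING, apex), , drop = FALSE]
    pl <- fit_plane(others)
    if (pl$rms_deviation > tol) next
    dev <- abs(signed_side(pl, ring[apex, ]))
    if (dev <= tol) next
    if (is.null(best) || dev > best$dev) {
      best <- list(mode = "envelope", apex_atoms = apex,
                   apex_sides = side_of(pl, ring[apex, ]), dev = dev)
    }
  }
  if (!is.null(best)) return(best[c("mode", "apex_atoms", "apex_sides")])
  # twist scan: two apexes on opposite sides of the plane of three
  combs <- utils::combn(RIBOSE_RING, 2)
  for (k in seq_len(ncol(combs))) {
    ab <- combs[, k]
    others <- ring[setdiff(RIBOSE_RING, ab), , drop = FALSE]
    pl <- fit_plane(others)
    da <- signed_side(pl, ring[ab[1], ])
    db <- signed_side(pl, ring[ab[2], ])
    if (abs(da) <= tol || abs(db) <= tol || da * db >= 0) next
    dev <- abs(da) + abs(db)
    if (is.null(best) || dev > best$dev) {
      best <- list(mode = "twist", apex_atoms = ab,
                   apex_sides = c(side_of(pl, ring[ab[1], ]),
                                  side_of(pl, ring[ab[2], ])), dev = dev)
    }
  }
  if (!is.null(best)) return(best[c("mode", "apex_atoms", "apex_sides")])
  list(mode = "planar", apex_atoms = character(0), apex_sides = character(0))
}

#' Classify the glycosidic conformation (syn/anti)
#'
#' chi is the torsion O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for
#' pyrimidines; the conformation is `syn` for chi in \[-90, +90\] degrees
#' and `anti` otherwise.
#'
#' @param r Residue with the required atoms.
#' @return List with `chi` (degrees) and `conformation`.
#' @export
classify_glycosidic <- function(r) {
  o4p <- atom_xyz(r, "O4'")
  c1p <- atom_xyz(r, "C1'")
  if (all(c("N9", "C4") %in% r$atoms$name)) {
    n <- atom_xyz(r, "N9"); cc <- atom_xyz(r, "C4")
  } else if (all(c("N1", "C2") %in% r$atoms$name)) {
    n <- atom_xyz(r, "N1"); cc <- atom_xyz(r, "C2")
  } else {
    stop("missing glycosidic atoms in residue ", residue_key(r))
  }
  if (is.null(o4p) || is.null(c1p)) {
    stop("missing O4'/C1' in residue ", residue_key(r))
  }
  chi <- torsion_angle(o4p, c1p, n, cc)
  list(chi = chi,
       conformation = if (chi >= -90 && chi <= 90) "syn" else "anti")
}

#' Annotate one structure model
#'
#' Aggregates all detectors over a model: base pairs, base stacks, and
#' per-residue pucker and glycosidic annotations. Per-residue detector
#' failures (incomplete residues) degrade to warnings, never a global
#' failure.
#'
#' @inheritParams detect_base_pairs
#' @return A `model_annotation`: list with `model_num`, `pairs`, `stacks`,
#'   `puckers` and `glycosidics` (the latter two keyed by residue
#'   reference `chain:seq[icode]`).
#' @export
annotate_model <- function(model, params = annotation_params()) {
  puckers <- list()
  glycosidics <- list()
  for (e in model_residues(model)) {
    if (!is_nucleotide(e$res)) {
      # a standard-named residue stripped of its nucleobase degrades to
      # non_nucleic and silently drops out of every detector; flag it
      if (!is.na(STANDARD_RES_NAMES[toupper(e$res$res_name)])) {
        warning("residue ", e$key, " has a standard nucleotide name but ",
                "no nucleobase atoms; excluded from annotation")
      }
      next
    }
    pk <- try(classify_pucker(e$res, params), silent = TRUE)
    if (inherits(pk, "try-error")) {
      warning("pucker not classified for ", e$key, ": ",
              attr(pk, "condition")$message)
    } else {
      puckers[[e$key]] <- pk
    }
    gl <- try(classify_glycosidic(e$res), silent = TRUE)
    if (inherits(gl, "try-error")) {
      warning("glycosidic conformation not classified for ", e$key, ": ",
              attr(gl, "condition")$message)
    } else {
      glycosidics[[e$key]] <- gl
    }
  }
  structure(
    list(model_num = model$model_num,
         pairs = detect_base_pairs(model, params),
         stacks = detect_base_stacks(model, params),
         puckers = puckers, glycosidics = glycosidics),
    class = "model_annotation"
  )
}

#' Annotate every model of a structure file
#' @param f A `molecular_structure_file`.
#' @param params [annotation_params()].
#' @return List of `model_annotation`, one per model.
#' @export
annotate_structure <- function(f, params = annotation_params()) {
  lapply(f$models, annotate_model, params = params)
}
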