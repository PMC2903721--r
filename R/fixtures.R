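# Synthetic test inputs, generated without downloads: idealized A-form
# duplexes with known Watson-Crick pairs and neighbor stacks, constructed
# envelope pucker rings, and planned knowledge-graph fixtures with
# combinatorial ground truth for the stored queries.
#
# Nucleotide templates are constructed from idealized internal coordinates:
# planar base rings (regular polygons at ring-bond length), exocyclic
# substituents placed radially, C3'-endo riboses with anti glycosidic
# torsion. Watson-Crick pair geometry is obtained by a deterministic rigid
# fit of the complementary base that places the canonical hydrogen bonds at
# 2.9 Angstrom and the C1'-C1' distance at 10.4 Angstrom.

BASE_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

deg2rad <- function(x) x * pi / 180

rot2 <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# --- idealized base templates (planar, z = 0) -------------------------------

RING_BOND <- 1.38  # aromatic ring bond length, Angstrom
GLYC_BOND <- 1.48  # N9/N1 - C1'

hexagon_points <- function(names) {
  ang <- 90 - 60 * (seq_along(names) - 1)
  m <- cbind(RING_BOND * cos(deg2rad(ang)), RING_BOND * sin(deg2rad(ang)), 0)
  rownames(m) <- names
  m
}

# Planar template of one nucleobase plus the C1' anchor, rows named by atom.
base_template <- function(base) {
  hexn <- c("N1", "C2", "N3", "C4", "C5", "C6")
  m <- hexagon_points(hexn)
  radial <- function(p, center = c(0, 0, 0)) {
    v <- p - center; v[3] <- 0; v / vnorm(v)
  }
  add <- function(m, name, anchor, L, center = c(0, 0, 0)) {
    rbind(m, matrix(m[anchor, ] + L * radial(m[anchor, ], center), 1, 3,
                    dimnames = list(name)))
  }
  if (base %in% c("C", "U")) {
    m <- add(m, "O2", "C2", 1.23)
    m <- add(m, if (base == "C") "N4" else "O4", "C4", 1.33)
    m <- add(m, "C1'", "N1", GLYC_BOND)
    return(m)
  }
  # purines: fuse a regular pentagon C4-C5-N7-C8-N9 on the C4-C5 edge
  s <- vnorm(m["C5", ] - m["C4", ])
  mid <- (m["C4", ] + m["C5", ]) / 2
  pc <- mid + (s / (2 * tan(deg2rad(36)))) * radial(mid)
  rp <- s / (2 * sin(deg2rad(36)))
  th4 <- atan2(m["C4", 2] - pc[2], m["C4", 1] - pc[1])
  th5 <- atan2(m["C5", 2] - pc[2], m["C5", 1] - pc[1])
  step <- th5 - th4
  step <- atan2(sin(step), cos(step))  # wrap to (-pi, pi]
  for (k in 1:3) {
    nm <- c("N7", "C8", "N9")[k]
    th <- th5 + k * step
    m <- rbind(m, matrix(c(pc[1] + rp * cos(th), pc[2] + rp * sin(th), 0),
                         1, 3, dimnames = list(nm)))
  }
  if (base == "A") {
    m <- add(m, "N6", "C6", 1.34)
  } else {
    m <- add(m, "O6", "C6", 1.23)
    m <- add(m, "N2", "C2", 1.34)
  }
  m <- add(m, "C1'", "N9", GLYC_BOND, center = pc)
  m
}

glycosidic_n <- function(base) if (base %in% c("A", "G")) "N9" else "N1"
chi_partner <- function(base) if (base %in% c("A", "G")) "C4" else "C2"

# Canonical Watson-Crick hydrogen-bond rails, listed so the k-th atoms of
# the two rails bond to each other.
WC_RAIL <- list(G = c("O6", "N1", "N2"), C = c("N4", "N3", "O2"),
                A = c("N6", "N1"), U = c("O4", "N3"))
WC_HBOND_TARGET <- 2.9   # Angstrom

# Rigid pose of one base: its Watson-Crick rail runs along +y (so the two
# rails of a pair are parallel with matched order), its rail centroid sits
# at x = side * gap/2, y = 0, and the ring body extends to the `side` half
# plane. When the body lands on the wrong side the base is flipped 180
# degrees about the rail line - a proper rotation for a planar base (the
# base seen from its other face), which makes the two normals of a pair
# antiparallel as in an antiparallel duplex.
pose_on_rail <- function(m, base, side, gap = WC_HBOND_TARGET) {
  rail <- WC_RAIL[[base]]
  rd <- m[rail[length(rail)], ] - m[rail[1], ]
  a1 <- atan2(rd[2], rd[1])
  R <- rot2(90 - a1 * 180 / pi)
  ec <- colMeans(m[rail, , drop = FALSE])
  m[, 1:2] <- sweep(m[, 1:2], 2, ec[1:2]) %*% t(R)
  ring <- intersect(c(PURINE_RING, PYRIMIDINE_RING), rownames(m))
  body_x <- mean(m[ring, 1])
  if (sign(body_x) != sign(side)) m[, 1] <- -m[, 1]
  m[, 1] <- m[, 1] + side * gap / 2
  m
}

# Deterministic Watson-Crick pair frame: the two complementary bases face
# each other across x = 0 with parallel rails, every canonical hydrogen
# bond at the target length; the frame is then recentred on the mean of
# the two base-ring centroids (where the helix axis will pass), which
# keeps stacked neighbors close and cross-strand neighbors apart.
fit_wc_pair <- function(b1) {
  b2 <- BASE_COMPLEMENT[[b1]]
  m1 <- pose_on_rail(base_template(b1), b1, +1)
  m2 <- pose_on_rail(base_template(b2), b2, -1)
  ringc <- function(m) {
    ring <- intersect(c(PURINE_RING, PYRIMIDINE_RING), rownames(m))
    colMeans(m[ring, , drop = FALSE])
  }
  midp <- (ringc(m1) + ringc(m2)) / 2
  m1 <- sweep(m1, 2, midp)
  m2 <- sweep(m2, 2, midp)
  r1 <- WC_RAIL[[b1]]; r2 <- WC_RAIL[[b2]]
  resid <- max(abs(vapply(seq_along(r1), function(k)
    vnorm(m1[r1[k], ] - m2[r2[k], ]), 1) - WC_HBOND_TARGET))
  list(base1 = m1, base2 = m2, residual = resid)
}

# --- ribose attachment ------------------------------------------------------

RIBOSE_RADIUS <- 1.26   # circumradius of the idealized five-ring
CHI_ANTI <- -160        # anti glycosidic torsion, degrees

# Local ribose template: ring in the xy-plane, C3' displaced +z
# (C3'-endo once C5' is attached on the +z side), C1' at the origin.
ribose_local <- function(c3p_amplitude = 0.5) {
  names5 <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  ang <- 90 - 72 * (0:4)
  m <- cbind(RIBOSE_RADIUS * cos(deg2rad(ang)),
             RIBOSE_RADIUS * sin(deg2rad(ang)), 0)
  rownames(m) <- names5
  radial <- function(nm, rot = 0) {
    v <- c(m[nm, 1:2], 0)
    v <- v / vnorm(v)
    as.numeric(rotation_about_axis(c(0, 0, 1), rot) %*% v)
  }
  # O2' is placed over the ring on the C5' side; the stylized position
  # keeps the 2'-hydroxyl clear of neighboring residues' face atoms so
  # annotation of the constructed duplex is unambiguous
  ext <- rbind(
    "C5'" = m["C4'", ] + 1.0 * radial("C4'") + c(0, 0, 1.1),
    "O2'" = m["C2'", ] + 1.45 * radial("C2'", -180) + c(0, 0, 0.7),
    "O3'" = m["C3'", ] + 1.3 * radial("C3'") + c(0, 0, -0.6)
  )
  m["C3'", 3] <- c3p_amplitude
  m <- rbind(m, ext)
  m <- rbind(m, "O5'" = m["C5'", ] + c(0, 0, 1.42))
  sweep(m, 2, m["C1'", ])  # C1' to origin
}

# rotation carrying unit vector a onto unit vector b
align_rotation <- function(a, b) {
  a <- a / vnorm(a); b <- b / vnorm(b)
  ax <- cross3(a, b)
  s <- vnorm(ax)
  if (s < 1e-12) {
    if (sum(a * b) > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about_axis(perp, 180))
  }
  ang <- atan2(s, sum(a * b)) * 180 / pi
  rotation_about_axis(ax, ang)
}

# Attach a ribose to a placed base: C1' along the outward glycosidic
# direction, then roll about the glycosidic bond to the target chi.
attach_ribose <- function(base_m, base, chi_target = CHI_ANTI) {
  n_pos <- base_m[glycosidic_n(base), ]
  c1_pos <- base_m["C1'", ]
  v_target <- (n_pos - c1_pos) / vnorm(n_pos - c1_pos)
  loc <- ribose_local()
  R0 <- align_rotation(c(0, 1, 0), v_target)
  m <- loc %*% t(R0)
  m <- sweep(m, 2, c1_pos, FUN = "+")
  chi_of <- function(m) {
    torsion_angle(m["O4'", ], m["C1'", ], n_pos, base_m[chi_partner(base), ])
  }
  axis <- n_pos - c1_pos
  roll <- function(m, ang) {
    shifted <- sweep(m, 2, c1_pos)
    out <- shifted %*% t(rotation_about_axis(axis, ang))
    dimnames(out) <- dimnames(m)
    sweep(out, 2, c1_pos, FUN = "+")
  }
  delta <- chi_target - chi_of(m)
  m2 <- roll(m, delta)
  if (abs(angle_diff(chi_of(m2), chi_target)) > 1e-6) m2 <- roll(m, -delta)
  m2
}

angle_diff <- function(a, b) {
  d <- a - b
  atan2(sin(deg2rad(d)), cos(deg2rad(d))) * 180 / pi
}

# --- duplex generator -------------------------------------------------------

#' Specification for a synthetic A-form duplex
#'
#' @param sequence 5'-3' sequence of strand A over `A`, `C`, `G`, `U`; the
#'   complementary strand is its reverse complement.
#' @param n_models Number of identical-skeleton models.
#' @param helical_rise Rise per base pair, Angstrom (canonical A-form 2.81).
#' @param helical_twist Twist per base pair, degrees (canonical 32.7).
#' @param noise_sigma Standard deviation of Gaussian coordinate noise,
#'   Angstrom (0 = exact geometry; noise is drawn independently per model).
#' @param seed RNG seed for the noise.
#' @return A `duplex_spec` list.
#' @export
duplex_spec <- function(sequence, n_models = 1, helical_rise = 2.81,
                        helical_twist = 32.7, noise_sigma = 0, seed = 1) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) < 2) stop("sequence must have length >= 2")
  if (!all(chars %in% names(BASE_COMPLEMENT))) {
    stop("sequence may only contain A, C, G, U")
  }
  structure(list(sequence = sequence, n_models = as.integer(n_models),
                 helical_rise = helical_rise,
                 helical_twist = helical_twist,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "duplex_spec")
}

#' Generate an idealized A-form RNA duplex with ground truth
#'
#' Places idealized nucleotide templates (planar bases, C3'-endo riboses,
#' anti glycosidic torsion) along a helix with the requested rise and
#' twist; strand B is the reverse complement, paired antiparallel so every
#' position forms a canonical Watson-Crick pair. The returned ground truth
#' lists each complementary pair (whose central interaction is Ww/Ww), each
#' intra-strand neighbor stack, and the constructed glycosidic/pucker
#' states.
#'
#' @param spec A [duplex_spec()], or a sequence string (with the remaining
#'   arguments passed to [duplex_spec()]).
#' @param ... When `spec` is a string: forwarded to [duplex_spec()].
#' @param pdb_id Identifier for the generated structure.
#' @return List with `structure` (a `molecular_structure_file`), `truth`
#'   (`pairs`, `stacks` data frames; `glycosidic`, `pucker` expectations)
#'   and `spec`.
#' @export
make_duplex <- function(spec, ..., pdb_id = "SYN1") {
  if (is.character(spec)) spec <- duplex_spec(spec, ...)
  chars <- strsplit(spec$sequence, "")[[1]]
  n <- length(chars)
  # one fitted pair frame per base type needed
  frames <- list()
  for (b in unique(chars)) frames[[b]] <- fit_wc_pair(b)
  nt_cache <- list()
  pair_nts <- function(b) {
    if (!is.null(nt_cache[[b]])) return(nt_cache[[b]])
    fr <- frames[[b]]
    nt1 <- rbind(fr$base1, attach_ribose(fr$base1, b)[-1, , drop = FALSE])
    b2 <- BASE_COMPLEMENT[[b]]
    nt2 <- rbind(fr$base2, attach_ribose(fr$base2, b2)[-1, , drop = FALSE])
    out <- list(nt1, nt2)
    nt_cache[[b]] <<- out
    out
  }

  build_model_atoms <- function() {
    strandA <- vector("list", n)
    strandB <- vector("list", n)
    for (i in seq_len(n)) {
      b <- chars[i]
      nts <- pair_nts(b)
      ang <- (i - 1) * spec$helical_twist
      Rz <- rotation_about_axis(c(0, 0, 1), ang)
      shift <- c(0, 0, (i - 1) * spec$helical_rise)
      place <- function(m) sweep(m %*% t(Rz), 2, shift, FUN = "+")
      strandA[[i]] <- place(nts[[1]])
      strandB[[n + 1 - i]] <- place(nts[[2]])
    }
    list(A = strandA, B = strandB)
  }

  base_coords <- build_model_atoms()
  seqB <- rev(unname(BASE_COMPLEMENT[chars]))

  models <- with_seed(spec$seed, lapply(seq_len(spec$n_models), function(mi) {
    mk_res <- function(chain, i, b, m) {
      if (spec$noise_sigma > 0) {
        m <- m + matrix(stats::rnorm(length(m), 0, spec$noise_sigma),
                        nrow(m), 3)
      }
      atoms <- do.call(rbind, lapply(rownames(m), function(nm)
        atom_record(nm, m[nm, ])))
      new_residue(chain, i, b, atoms)
    }
    chains <- list(
      A = lapply(seq_len(n), function(i)
        mk_res("A", i, chars[i], base_coords$A[[i]])),
      B = lapply(seq_len(n), function(i)
        mk_res("B", i, seqB[i], base_coords$B[[i]]))
    )
    list(model_num = mi, chains = chains)
  }))

  truth_pairs <- data.frame(
    chain_i = "A", seq_i = seq_len(n),
    chain_j = "B", seq_j = n + 1 - seq_len(n),
    subedge = "Ww/Ww", stringsAsFactors = FALSE)
  truth_stacks <- rbind(
    data.frame(chain_i = "A", seq_i = seq_len(n - 1),
               chain_j = "A", seq_j = 2:n, stringsAsFactors = FALSE),
    data.frame(chain_i = "B", seq_i = seq_len(n - 1),
               chain_j = "B", seq_j = 2:n, stringsAsFactors = FALSE))

  list(structure = new_structure_file(pdb_id, models),
       truth = list(pairs = truth_pairs, stacks = truth_stacks,
                    glycosidic = "anti",
                    pucker = list(mode = "envelope", apex = "C3'",
                                  side = "endo")),
       spec = spec)
}

#' Construct a ribose ring with a prescribed envelope pucker
#'
#' Four ring atoms are placed exactly coplanar on a circle of ribose-like
#' radius; the apex atom is displaced by `amplitude` towards (`endo`) or
#' away from (`exo`) an off-plane C5'. Ground truth: (envelope, apex,
#' side); `amplitude = 0` yields a planar ring.
#'
#' @param apex One of `C1'`, `C2'`, `C3'`, `C4'`, `O4'`.
#' @param side `"endo"` or `"exo"`.
#' @param amplitude Apex displacement, Angstrom (>= 0).
#' @return A `residue` holding the constructed ring and C5'.
#' @export
make_pucker_ring <- function(apex = "C3'", side = c("endo", "exo"),
                             amplitude = 0.5) {
  side <- match.arg(side)
  if (!apex %in% RIBOSE_RING) {
    stop("apex must be one of ", paste(RIBOSE_RING, collapse = ", "))
  }
  if (amplitude < 0) stop("amplitude must be >= 0")
  ang <- 90 - 72 * (0:4)
  m <- cbind(RIBOSE_RADIUS * cos(deg2rad(ang)),
             RIBOSE_RADIUS * sin(deg2rad(ang)), 0)
  rownames(m) <- RIBOSE_RING
  # C5' above the plane, near C4'
  c5 <- m["C4'", ] + c(0, 0, 1.2)
  m[apex, 3] <- if (side == "endo") amplitude else -amplitude
  atoms <- do.call(rbind, c(
    lapply(RIBOSE_RING, function(nm) atom_record(nm, m[nm, ])),
    list(atom_record("C5'", c5))))
  new_residue("A", 1, "RIB", atoms)
}

# --- planned knowledge-graph fixtures ---------------------------------------

#' Specification for a planned knowledge-graph fixture
#'
#' @param n_models,n_chains,residues_per_chain Fixture dimensions.
#' @param pair_plan List of planned base pairs: each a list with `model`,
#'   `chain_i`, `seq_i`, `chain_j`, `seq_j` and `subedges` (a list of
#'   2-vectors of sub-edge tokens, one per sub-edge interaction).
#' @param stack_plan List of planned stacks: each a list with `model`,
#'   `chain_i`, `seq_i`, `chain_j`, `seq_j` and optional `orientation`.
#' @param sequence Residue types per position (recycled); default cycles
#'   `G`, `A`, `C`, `U`.
#' @param pdb_id Identifier for the fixture.
#' @param seed Seed recorded with the spec.
#' @return A `kb_fixture_spec` list.
#' @export
kb_fixture_spec <- function(n_models = 1, n_chains = 1,
                            residues_per_chain = 4, pair_plan = list(),
                            stack_plan = list(), sequence = NULL,
                            pdb_id = "TEST", seed = 1) {
  if (is.null(sequence)) {
    sequence <- rep(c("G", "A", "C", "U"),
                    length.out = residues_per_chain)
  }
  structure(list(n_models = as.integer(n_models),
                 n_chains = as.integer(n_chains),
                 residues_per_chain = as.integer(residues_per_chain),
                 pair_plan = pair_plan, stack_plan = stack_plan,
                 sequence = sequence, pdb_id = pdb_id,
                 seed = as.integer(seed)),
            class = "kb_fixture_spec")
}

hoogsteen_subedges <- function() {
  names(SUBEDGE_TO_EDGE)[SUBEDGE_TO_EDGE == "Hoogsteen"]
}

#' Build a knowledge graph from a planned fixture, with query ground truth
#'
#' Constructs a skeleton structure (no coordinates needed) and planned
#' annotations, populates the graph through the regular emission rules, and
#' computes the exact expected answer sets for the stored query templates
#' combinatorially from the plan: A/F = the structure models; B/E = pairs
#' with a Hoogsteen-group sub-edge in any interaction; C = those whose
#' Hoogsteen sub-edge sits on a guanosine; D = pairs with a Ww/Hh
#' interaction.
#'
#' @param spec A [kb_fixture_spec()].
#' @param schema A `schema_catalog`.
#' @return List with `graph` (unsaturated `kb_graph`), `truth` (named list
#'   of sorted URI sets per query letter) and `spec`.
#' @export
make_kb_fixture <- function(spec, schema = load_schema()) {
  stopifnot(inherits(spec, "kb_fixture_spec"))
  chains <- LETTERS[seq_len(spec$n_chains)]
  empty_atoms <- data.frame(name = character(0), element = character(0),
                            x = numeric(0), y = numeric(0), z = numeric(0),
                            occupancy = numeric(0), altloc = character(0),
                            stringsAsFactors = FALSE)
  res_name_at <- function(chain, seq) {
    spec$sequence[(seq - 1) %% length(spec$sequence) + 1]
  }
  mk_residue <- function(chain, seq) {
    nm <- res_name_at(chain, seq)
    structure(list(chain_id = chain, seq_num = as.integer(seq), icode = "",
                   res_name = nm, atoms = empty_atoms, residue_class = nm),
              class = "residue")
  }
  model_chains <- stats::setNames(lapply(chains, function(ck)
    lapply(seq_len(spec$residues_per_chain), function(i)
      mk_residue(ck, i))), chains)
  models <- lapply(seq_len(spec$n_models), function(mi)
    list(model_num = mi, chains = model_chains))
  msf <- new_structure_file(spec$pdb_id, models)

  check_res <- function(chain, seq) {
    if (!chain %in% chains || seq < 1 || seq > spec$residues_per_chain) {
      stop("plan references nonexistent residue ", chain, ":", seq)
    }
  }
  plan_ref <- function(chain, seq) {
    check_res(chain, seq)
    list(chain = chain, seq_num = as.integer(seq), icode = "",
         res_name = res_name_at(chain, seq))
  }
  oriented <- function(e) {
    # keep res_i < res_j in (chain, seq) order, swapping sub-edge sides
    if (e$chain_i > e$chain_j ||
        (e$chain_i == e$chain_j && e$seq_i > e$seq_j)) {
      e[c("chain_i", "chain_j")] <- e[c("chain_j", "chain_i")]
      e[c("seq_i", "seq_j")] <- e[c("seq_j", "seq_i")]
      if (!is.null(e$subedges)) {
        e$subedges <- lapply(e$subedges, rev)
      }
    }
    e
  }

  anns <- lapply(seq_len(spec$n_models), function(mi) {
    pairs <- list()
    for (e in spec$pair_plan) {
      if (e$model != mi) next
      e <- oriented(e)
      ri <- plan_ref(e$chain_i, e$seq_i)
      rj <- plan_ref(e$chain_j, e$seq_j)
      ki <- paste0(ri$chain, ":", ri$seq_num)
      kj <- paste0(rj$chain, ":", rj$seq_num)
      interactions <- lapply(e$subedges, function(se) {
        stopifnot(length(se) == 2, all(se %in% SUBEDGE_KINDS))
        list(subedge_i = se[1], subedge_j = se[2],
             hbonds = data.frame(donor_res = ki, donor_atom = "N1",
                                 acceptor_res = kj, acceptor_atom = "N3",
                                 distance = 2.9, stringsAsFactors = FALSE))
      })
      pairs[[length(pairs) + 1]] <- structure(
        list(res_i = ri, res_j = rj, interactions = interactions,
             lw_edge_i = dominant_edge(interactions, "subedge_i"),
             lw_edge_j = dominant_edge(interactions, "subedge_j"),
             orientation = "cis"),
        class = "base_pair")
    }
    stacks <- list()
    for (e in spec$stack_plan) {
      if (e$model != mi) next
      e <- oriented(e)
      ri <- plan_ref(e$chain_i, e$seq_i)
      rj <- plan_ref(e$chain_j, e$seq_j)
      adjacent <- ri$chain == rj$chain && abs(ri$seq_num - rj$seq_num) == 1
      stacks[[length(stacks) + 1]] <- structure(
        list(res_i = ri, res_j = rj,
             adjacency = if (adjacent) "adjacent" else "non_adjacent",
             normal_orientation = e$orientation %||% "upward"),
        class = "base_stack")
    }
    structure(list(model_num = mi, pairs = pairs, stacks = stacks,
                   puckers = list(), glycosidics = list()),
              class = "model_annotation")
  })

  graph <- build_graph(msf, anns, schema)

  pair_uri <- function(e, mi) {
    mint_uri(list(kind = "base_pair", pdb_id = spec$pdb_id, model_num = mi,
                  chain = e$chain_i, seq_num = e$seq_i, icode = "",
                  chain2 = e$chain_j, seq_num2 = e$seq_j, icode2 = ""))
  }
  truth <- list(A = character(0), B = character(0), C = character(0),
                D = character(0), E = character(0), F = character(0))
  truth$A <- sort(vapply(seq_len(spec$n_models), function(mi)
    mint_uri(list(kind = "structure_model", pdb_id = spec$pdb_id,
                  model_num = mi)), ""))
  truth$F <- truth$A
  # Participant identity is (model, residue, face), so pairs sharing a
  # residue share its participants; and because 'has part' is transitive
  # through the residue (pair has part residue, sub-edge part of residue),
  # a pair has as parts every participant attached to its residues in that
  # model, whichever interaction asserted it. The query truths replicate
  # that entailment combinatorially.
  # Residues (and their parthood) are model-independent, so a pair reaches
  # participants asserted in any model of the file through its residues.
  participant <- function(mi, chain, seq, se) {
    paste(mi, chain, seq, se, sep = "|")
  }
  p_res <- function(p) {
    bits <- strsplit(p, "|", fixed = TRUE)[[1]]
    paste(bits[2], bits[3], sep = "|")
  }
  p_face <- function(p) sub("^.*\\|", "", p)
  attached <- list()   # residue key -> participants
  ect <- character(0)  # "p q" links, symmetric
  for (e in spec$pair_plan) {
    e <- oriented(e)
    for (se in e$subedges) {
      pi <- participant(e$model, e$chain_i, e$seq_i, se[1])
      pj <- participant(e$model, e$chain_j, e$seq_j, se[2])
      ri <- p_res(pi); rj <- p_res(pj)
      attached[[ri]] <- union(attached[[ri]], pi)
      attached[[rj]] <- union(attached[[rj]], pj)
      ect <- union(ect, c(paste(pi, pj), paste(pj, pi)))
    }
  }
  ect_partners <- function(p) {
    hits <- ect[startsWith(ect, paste0(p, " "))]
    sub("^.* ", "", hits)
  }
  for (e in spec$pair_plan) {
    e <- oriented(e)
    uri <- pair_uri(e, e$model)
    parts <- unique(c(
      attached[[paste(e$chain_i, e$seq_i, sep = "|")]] %||% character(0),
      attached[[paste(e$chain_j, e$seq_j, sep = "|")]] %||% character(0)))
    res_is_g <- function(p) {
      bits <- strsplit(p, "|", fixed = TRUE)[[1]]
      res_name_at(bits[2], as.integer(bits[3])) == "G"
    }
    h_parts <- parts[p_face(parts) %in% hoogsteen_subedges()]
    if (length(h_parts)) {
      truth$B <- union(truth$B, uri)
      if (any(vapply(h_parts, res_is_g, TRUE))) {
        truth$C <- union(truth$C, uri)
      }
    }
    ww <- parts[p_face(parts) == "Ww"]
    if (any(vapply(ww, function(p)
      any(p_face(ect_partners(p)) == "Hh"), TRUE))) {
      truth$D <- union(truth$D, uri)
    }
  }
  truth$E <- truth$B
  truth <- lapply(truth, sort)

  list(graph = graph, truth = truth, spec = spec)
}

#' Random planned fixture for oracle testing
#'
#' Draws a fixture spec with random dimensions and a random pair/stack plan
#' (sub-edge tokens drawn uniformly) under a fixed seed.
#'
#' @param seed RNG seed.
#' @param max_models,max_pairs Upper bounds for the draw.
#' @return A [kb_fixture_spec()].
#' @export
random_kb_fixture_spec <- function(seed, max_models = 3, max_pairs = 6) {
  with_seed(seed, {
    n_models <- sample(max_models, 1)
    n_chains <- sample(2, 1)
    rpc <- sample(3:6, 1)
    chains <- LETTERS[seq_len(n_chains)]
    n_pairs <- sample(0:max_pairs, 1)
    pair_plan <- lapply(seq_len(n_pairs), function(k) {
      ci <- sample(chains, 1); cj <- sample(chains, 1)
      si <- sample(rpc, 1)
      repeat {
        sj <- sample(rpc, 1)
        if (!(ci == cj && si == sj)) break
      }
      n_int <- sample(2, 1)
      list(model = sample(n_models, 1), chain_i = ci, seq_i = si,
           chain_j = cj, seq_j = sj,
           subedges = lapply(seq_len(n_int), function(x)
             sample(SUBEDGE_KINDS, 2, replace = TRUE)))
    })
    n_stacks <- sample(0:3, 1)
    stack_plan <- lapply(seq_len(n_stacks), function(k) {
      ci <- sample(chains, 1)
      si <- sample(rpc - 1, 1)
      list(model = sample(n_models, 1), chain_i = ci, seq_i = si,
           chain_j = ci, seq_j = si + 1,
           orientation = sample(c("upward", "downward", "inward",
                                  "outward"), 1))
    })
    kb_fixture_spec(n_models = n_models, n_chains = n_chains,
                    residues_per_chain = rpc, pair_plan = pair_plan,
                    stack_plan = stack_plan, seed = seed,
                    pdb_id = sprintf("R%03d", seed %% 1000))
  })
}
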