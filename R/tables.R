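# Bundled chemical tables: hydrogen-bond donors/acceptors per base and the
# LW+ face (sub-edge) assignment of base atoms.
#
# Sub-edge tokens follow the Lemieux-Major face nomenclature: Ww/Wh/Ws/Bw on
# the Watson-Crick edge, Hh/Hw/Bh/C8 on the Hoogsteen edge, Ss/Sw/Bs/O2p on
# the sugar edge. The O2' atom and the glycosidic nitrogen (N9 in purines,
# N1 in pyrimidines) extend the faces along the ribose. Only O2', C8, N9/N1
# and the edge agglomerations are pinned by the underlying classification
# scheme; the remaining per-atom assignments are a documented approximation
# (one face per atom, chosen so canonical Watson-Crick hydrogen bonds group
# as Ww/Ww, Wh/Wh and Ws/Ws interactions).

SUBEDGE_KINDS <- c("Ww", "Wh", "Ws", "Bw", "Hh", "Hw", "Bh", "C8",
                   "Ss", "Sw", "Bs", "O2p")

# Sub-edge -> Leontis-Westhof edge agglomeration.
SUBEDGE_TO_EDGE <- c(
  Ww = "WatsonCrick", Wh = "WatsonCrick", Ws = "WatsonCrick",
  Bw = "WatsonCrick",
  Hh = "Hoogsteen", Hw = "Hoogsteen", Bh = "Hoogsteen", C8 = "Hoogsteen",
  Ss = "Sugar", Sw = "Sugar", Bs = "Sugar", O2p = "Sugar"
)

#' Leontis-Westhof edge of a sub-edge
#' @param subedge Sub-edge token(s), e.g. `"Hh"`.
#' @return `"WatsonCrick"`, `"Hoogsteen"` or `"Sugar"`.
#' @export
edge_of_subedge <- function(subedge) {
  out <- SUBEDGE_TO_EDGE[subedge]
  if (anyNA(out)) stop("unknown sub-edge: ",
                       paste(subedge[is.na(out)], collapse = ", "))
  unname(out)
}

# Per-base face tables (atom name -> sub-edge token).
FACE_TABLE <- list(
  A = c(N1 = "Ww", N6 = "Wh", C2 = "Ws", N7 = "Hh", C8 = "C8",
        N3 = "Ss", N9 = "Sw", "O2'" = "O2p"),
  G = c(N1 = "Ww", O6 = "Wh", N2 = "Ws", N7 = "Hh", C8 = "C8",
        N3 = "Ss", N9 = "Sw", "O2'" = "O2p"),
  C = c(N3 = "Ww", N4 = "Wh", O2 = "Ws", C5 = "Hh", C6 = "Hw",
        N1 = "Sw", "O2'" = "O2p"),
  U = c(N3 = "Ww", O4 = "Wh", O2 = "Ws", C5 = "Hh", C6 = "Hw",
        N1 = "Sw", "O2'" = "O2p")
)
# Modified nucleotides: purine assignments take precedence, pyrimidine
# entries fill the gaps, so faces remain defined for noncanonical bases.
FACE_TABLE$modified <- c(FACE_TABLE$G,
                         FACE_TABLE$U[setdiff(names(FACE_TABLE$U),
                                              names(FACE_TABLE$G))])

#' Sub-edge (face) of a base atom
#'
#' Table lookup of the LW+ face an atom belongs to. Atoms on no face
#' (backbone phosphate, sugar carbons, ...) return `NA`.
#'
#' @param residue_class `"A"`, `"C"`, `"G"`, `"U"` or `"modified"`.
#' @param atom_name PDB atom name.
#' @return Sub-edge token or `NA_character_`.
#' @export
subedge_of_atom <- function(residue_class, atom_name) {
  tab <- FACE_TABLE[[residue_class]]
  if (is.null(tab)) stop("unknown residue class: ", residue_class)
  out <- unname(tab[atom_name])
  out
}

# Hydrogen-bond chemistry: N/O donors with their antecedent heavy atoms
# (used to aim the implied hydrogen) and N/O acceptors. O2' plays both
# roles in every nucleotide. Carbons are never donors here.
DONOR_TABLE <- list(
  A = list(N6 = c("C6")),
  G = list(N1 = c("C2", "C6"), N2 = c("C2")),
  C = list(N4 = c("C4")),
  U = list(N3 = c("C2", "C4"))
)
ACCEPTOR_TABLE <- list(
  A = c("N1", "N3", "N7"),
  G = c("O6", "N3", "N7"),
  C = c("O2", "N3"),
  U = c("O2", "O4")
)
DONOR_TABLE$modified <- c(DONOR_TABLE$G, DONOR_TABLE$U["N3"],
                          DONOR_TABLE$A["N6"], DONOR_TABLE$C["N4"])
ACCEPTOR_TABLE$modified <- unique(unlist(ACCEPTOR_TABLE[c("A", "G", "C", "U")]))
O2P_ANTECEDENT <- c("C2'")

residue_donors <- function(residue_class) {
  d <- DONOR_TABLE[[residue_class]]
  if (is.null(d)) d <- list()
  d[["O2'"]] <- O2P_ANTECEDENT
  d
}

residue_acceptors <- function(residue_class) {
  c(ACCEPTOR_TABLE[[residue_class]], "O2'")
}
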