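# Vector primitives shared by the annotator: dihedral angles, least-squares
# planes, signed out-of-plane distances and nucleobase reference frames.

#' Dihedral (torsion) angle of four points
#'
#' Computes the proper dihedral angle defined by the bonds p1-p2, p2-p3 and
#' p3-p4 using the IUPAC sign convention: looking from p2 towards p3, a
#' clockwise rotation carrying the projection of p1 onto that of p4 is
#' positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Cartesian coordinates, Angstrom).
#' @return Angle in degrees in the interval (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(b2) < 1e-12 || vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12) {
    stop("undefined torsion: three consecutive points are collinear or coincident")
  }
  u2 <- b2 / vnorm(b2)
  ang <- atan2(sum(cross3(n1, n2) * u2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Least-squares plane through a set of points
#'
#' Fits the plane minimizing the sum of squared point-to-plane distances: the
#' normal is the singular direction of smallest singular value of the centered
#' coordinate matrix.
#'
#' @param points Numeric matrix with one row per point and 3 columns (or a
#'   list of 3-vectors); at least 3 non-collinear points.
#' @return An object of class `plane3`: list with unit `normal`, `centroid`
#'   and `rms_deviation` (root-mean-square of the fitted points' distances).
#' @export
fit_plane <- function(points) {
  m <- as_coord_matrix(points)
  if (nrow(m) < 3) stop("fit_plane needs at least 3 points")
  centroid <- colMeans(m)
  x <- sweep(m, 2, centroid)
  sv <- svd(x)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    stop("degenerate plane: points are collinear")
  }
  normal <- sv$v[, 3]
  normal <- normal / vnorm(normal)
  d <- as.numeric(x %*% normal)
  structure(
    list(normal = normal, centroid = centroid,
         rms_deviation = sqrt(mean(d^2))),
    class = "plane3"
  )
}

#' Signed distance of a point from a plane
#'
#' Positive on the side the plane normal points to, negative on the other.
#'
#' @param plane A `plane3` object from [fit_plane()].
#' @param p Numeric 3-vector.
#' @return Signed distance in Angstrom.
#' @export
signed_side <- function(plane, p) {
  sum(plane$normal * (as.numeric(p) - plane$centroid))
}

# Ordered base-ring atom tables; the fixed traversal order pins the frame
# handedness regardless of atom order in the input file.
PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

#' Nucleobase reference frame (centroid + oriented normal)
#'
#' The normal is the least-squares plane normal of the base ring atoms, with
#' its sign fixed by the right-hand rule over the tabulated ring traversal
#' (purines N9-C8-N7-C5-C6-N1-C2-N3-C4, pyrimidines N1-C2-N3-C4-C5-C6), so it
#' is independent of the order atoms appear in the file.
#'
#' @param residue A residue object (see [read_pdb()]).
#' @return List with `centroid`, unit `normal` and `rms_deviation`.
#' @export
base_frame <- function(residue) {
  ring <- base_ring_atoms(residue)
  if (is.null(ring)) {
    stop("incomplete base: ring atoms missing for residue ",
         residue_key(residue))
  }
  pl <- fit_plane(ring)
  # Newell-style reference normal from the ordered ring polygon
  nref <- c(0, 0, 0)
  n <- nrow(ring)
  for (k in seq_len(n)) {
    a <- ring[k, ] - pl$centroid
    b <- ring[if (k == n) 1 else k + 1, ] - pl$centroid
    nref <- nref + cross3(a, b)
  }
  normal <- pl$normal
  if (sum(normal * nref) < 0) normal <- -normal
  list(centroid = pl$centroid, normal = normal,
       rms_deviation = pl$rms_deviation)
}

# Coordinates of the tabulated ring atoms in traversal order, or NULL when
# any is absent. Standard residues must carry their own ring type;
# modified residues use whichever canonical ring is complete.
base_ring_atoms <- function(residue) {
  tabs <- switch(residue$residue_class,
                 A = , G = list(PURINE_RING),
                 C = , U = list(PYRIMIDINE_RING),
                 list(PURINE_RING, PYRIMIDINE_RING))
  for (tab in tabs) {
    m <- atom_coords(residue, tab)
    if (!is.null(m)) return(m)
  }
  NULL
}

# --- internal helpers -------------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

as_coord_matrix <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, as.numeric))
  }
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  if (ncol(m) != 3) stop("points must have 3 columns")
  if (!all(is.finite(m))) stop("non-finite coordinates")
  m
}

# Rotation matrix about a unit axis by angle (degrees), Rodrigues form.
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / vnorm(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Named coordinate lookup inside a residue's atom table.
atom_xyz <- function(residue, name) {
  i <- match(name, residue$atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(residue$atoms[i, c("x", "y", "z")])
}

# Matrix of coordinates for a vector of atom names (NULL when any missing).
atom_coords <- function(residue, names) {
  idx <- match(names, residue$atoms$name)
  if (anyNA(idx)) return(NULL)
  m <- as.matrix(residue$atoms[idx, c("x", "y", "z")])
  storage.mode(m) <- "double"
  rownames(m) <- names
  m
}
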