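## Coordinate mathematics: dihedrals, plane angles, internal-coordinate atom
## placement, virtual cystine modelling and Kabsch superposition.

#' Ideal stereochemistry constants
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used for
#' internal-coordinate construction and virtual side-chain placement.
#' Values are standard protein stereochemistry dictionary values.
#'
#' @format Named list with elements `b_*` (bond lengths) and `a_*` (angles).
#' @export
ss_ideal <- list(
  b_n_ca  = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530, b_cb_sg = 1.810, b_sg_sg = 2.050,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.5, a_ca_cb_sg = 114.0, a_cb_sg_sg = 104.0
)

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vnorm <- function(u) sqrt(sum(u^2))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## map angle in degrees to (-180, 180]
wrap_angle <- function(x) {
  x <- ((x + 180) %% 360) - 180
  ifelse(x <= -180, x + 360, x)
}

#' Signed dihedral angle of four points
#'
#' Torsion angle defined by points p1-p2-p3-p4 under the IUPAC sign
#' convention: looking from p2 towards p3, a clockwise rotation of the
#' far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Signed angle in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop_ssf("degenerate geometry: three consecutive points are collinear",
             "ssf_degenerate_geometry")
  }
  b2h <- b2 / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2h)
  wrap_angle(rad2deg(atan2(y, x)))
}

#' Angle between two planes
#'
#' Each plane is given by three points; the angle between the plane
#' normals (orientation fixed by the point order, normal =
#' (a2-a1) x (a3-a1)) is returned in `[0, 180]` degrees.
#'
#' @param a1,a2,a3 Points defining the first plane.
#' @param b1,b2,b3 Points defining the second plane.
#' @return Angle in degrees in `[0, 180]`.
#' @export
plane_dihedral <- function(a1, a2, a3, b1, b2, b3) {
  na <- vcross(a2 - a1, a3 - a1)
  nb <- vcross(b2 - b1, b3 - b1)
  if (vnorm(na) < 1e-9 || vnorm(nb) < 1e-9) {
    stop_ssf("degenerate geometry: collinear plane triple",
             "ssf_degenerate_geometry")
  }
  ct <- sum(na * nb) / (vnorm(na) * vnorm(nb))
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

#' Place an atom from internal coordinates
#'
#' Natural extension reference frame (NeRF) placement: given three
#' positioned atoms a-b-c, returns the position d such that |c-d| = `bond`,
#' the angle b-c-d equals `angle` and the dihedral a-b-c-d equals
#' `torsion`.
#'
#' @param a,b,c Numeric 3-vectors.
#' @param bond Bond length c-d in Angstrom.
#' @param angle Bond angle b-c-d in degrees.
#' @param torsion Dihedral a-b-c-d in degrees.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-9) {
    stop_ssf("degenerate geometry: reference atoms are collinear",
             "ssf_degenerate_geometry")
  }
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

## Virtual C-beta from backbone N, CA, C (standard L-amino-acid constants;
## resulting CA-CB bond length ~1.53 A, tetrahedral geometry).
virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- vcross(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `moving` and `fixed` with correspondence given by row order. Reflections
#' are excluded.
#'
#' @param moving,fixed Numeric matrices of equal dimension (n x 3), n >= 3.
#' @return Object of class `ssf_superposition`: list with `rmsd` (Angstrom),
#'   `rotation` (3x3 proper rotation, det +1), `translation` (3-vector) such
#'   that `fitted = moving %*% t(rotation) + translation`, and `fitted`.
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed))) {
    stop_ssf("superpose: coordinate sets differ in size", "ssf_contract_error")
  }
  if (nrow(moving) < 3L || ncol(moving) != 3L) {
    stop_ssf("superpose: need at least 3 atoms of 3 coordinates each",
             "ssf_contract_error")
  }
  cm <- colMeans(moving); cf <- colMeans(fixed)
  M <- sweep(moving, 2, cm); F <- sweep(fixed, 2, cf)
  s <- svd(t(M) %*% F)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- M %*% t(R)
  fitted <- sweep(fitted, 2, cf, "+")
  rmsd <- sqrt(mean(rowSums((fitted - fixed)^2)))
  structure(
    list(rmsd = rmsd, rotation = R, translation = as.numeric(cf - R %*% cm),
         fitted = fitted),
    class = "ssf_superposition")
}

#' @export
print.ssf_superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

## random proper rotation (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure An `ssf_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric 3-vector.
#' @return Transformed `ssf_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}
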