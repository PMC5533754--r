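## Vectorized 3D geometry and circular (angular) arithmetic.
## All angles are degrees throughout the package.

#' Wrap angles to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to (-180, 180]; NA preserved.
#' @export
wrap180 <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

#' Wrap angles to the canonical display interval [-135, 225)
#'
#' The interval is chosen so both landmark values of the backbone
#' dihedral-sum statistic (about -105 deg for an alpha-helix, about +200 deg
#' for a flipped peptide bond) appear without wrapping.
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to [-135, 225).
#' @export
wrap_sum <- function(x) {
  w <- x %% 360
  ifelse(w >= 225, w - 360, w)
}

#' Circular distance between two angles
#'
#' @param a,b angles in degrees (recycled).
#' @return absolute circular difference in [0, 180].
#' @export
circ_dist <- function(a, b) abs(wrap180(a - b))

#' Circular mean of angles
#'
#' Unit-vector (resultant) average; NA values are dropped.
#'
#' @param x angles in degrees.
#' @return circular mean in (-180, 180], or NA if no finite values.
#' @export
circ_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  wrap180(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Circular standard deviation of angles
#'
#' sqrt(-2 log R) where R is the mean resultant length, in degrees.
#'
#' @param x angles in degrees.
#' @return circular SD (degrees), NA if no finite values.
#' @export
circ_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  R <- min(max(R, .Machine$double.eps), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

## --- internal row-wise vector helpers (n x 3 matrices) ------------------

.as_mat3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3L) else p
}

.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.vdot <- function(a, b) rowSums(a * b)

.vnorm <- function(a) sqrt(rowSums(a * a))

.vunit <- function(a) a / .vnorm(a)

#' Torsion (dihedral) angle from four points
#'
#' IUPAC sign convention: looking along b-c, the angle is positive when
#' a-b rotates clockwise onto c-d. Accepts n x 3 matrices (one torsion per
#' row) or plain length-3 vectors.
#'
#' @param p1,p2,p3,p4 coordinates (n x 3 matrices or length-3 vectors).
#' @return torsion angle(s) in degrees, in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  p1 <- .as_mat3(p1); p2 <- .as_mat3(p2); p3 <- .as_mat3(p3); p4 <- .as_mat3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  ang <- -atan2(.vdot(m1, n2), .vdot(n1, n2)) * 180 / pi
  wrap180(ang)
}

#' Bond angle at p2 from three points
#'
#' @param p1,p2,p3 coordinates (n x 3 matrices or length-3 vectors).
#' @return angle in degrees, [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  p1 <- .as_mat3(p1); p2 <- .as_mat3(p2); p3 <- .as_mat3(p3)
  u <- .vunit(p1 - p2)
  v <- .vunit(p3 - p2)
  acos(pmin(pmax(.vdot(u, v), -1), 1)) * 180 / pi
}

#' Place an atom by internal coordinates (NeRF)
#'
#' Given the positions of three previously placed atoms A-B-C, returns D
#' such that |C-D| = `bond`, angle(B,C,D) = `angle` and
#' torsion(A,B,C,D) = `torsion`. Vectorized: A, B, C may be n x 3 matrices
#' (one frame per row) with scalar or length-n internal coordinates.
#'
#' @param a,b,c positions of the three reference atoms.
#' @param bond bond length C-D (Angstrom).
#' @param angle bond angle B-C-D (degrees).
#' @param torsion torsion A-B-C-D (degrees).
#' @return n x 3 matrix of D positions.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c)
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  n <- nrow(c)
  d2x <- rep_len(-bond * cos(th), n)
  d2y <- rep_len(bond * sin(th), n) * rep_len(cos(ph), n)
  d2z <- rep_len(bond * sin(th), n) * rep_len(sin(ph), n)
  bc <- .vunit(c - b)
  nrm <- .vunit(.vcross(b - a, bc))
  m2 <- .vcross(nrm, bc)
  c + bc * d2x + m2 * d2y + nrm * d2z
}

## Apply a rigid rotation+translation to an n x 3 coordinate matrix.
## Used by tests and the synthetic module; exported for convenience.

#' Rigid-body transform of coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 translation vector (default zero).
#' @return transformed n x 3 matrix.
#' @export
rigid_transform <- function(xyz, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- .as_mat3(xyz)
  sweep(xyz %*% t(rotation), 2, translation, "+")
}
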