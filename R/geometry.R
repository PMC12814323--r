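## Vectorised 3-D geometry primitives shared by the synthetic generator and
## the dihedral module. All coordinate arguments are n x 3 matrices (one row
## per frame); all angles are degrees.

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped into `(-180, 180]`.
#' @examples
#' wrap_angle(c(190, -190, 360, 180, -180))
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360 + 0.5)  # (-180, 180)
  w[w == -180] <- 180                  # half-open on the left
  w
}

`%dot%` <- function(a, b) rowSums(a * b)

cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

unit3 <- function(a) a / sqrt(rowSums(a^2))

as_mat3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else p
}

#' Torsion angle of four points, vectorised over frames
#'
#' Standard IUPAC sign convention: looking from the second atom toward the
#' third, a clockwise rotation of the far bond is positive; cis = 0,
#' trans = 180.
#'
#' @param p1,p2,p3,p4 n x 3 coordinate matrices (or length-3 vectors).
#' @return numeric vector of n torsion angles in degrees, in `(-180, 180]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- as_mat3(p1); p2 <- as_mat3(p2); p3 <- as_mat3(p3); p4 <- as_mat3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  wrap_angle(atan2(-(m1 %dot% n2), n1 %dot% n2) * 180 / pi)
}

#' Place a fourth atom from three reference atoms and internal coordinates
#'
#' Natural extension reference frame (NeRF) construction: given positions of
#' atoms A-B-C, returns D such that |C-D| = `bond`, angle B-C-D = `angle`
#' and torsion A-B-C-D = `torsion` under the convention of
#' [dihedral_angle()]. Vectorised over frames.
#'
#' @param a,b,c n x 3 matrices (or length-3 vectors) of reference positions.
#' @param bond bond length C-D (scalar or length n).
#' @param angle bond angle B-C-D in degrees (scalar or length n).
#' @param torsion torsion A-B-C-D in degrees (scalar or length n).
#' @return n x 3 matrix of D positions.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  a <- as_mat3(a); b <- as_mat3(b); c <- as_mat3(c)
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- unit3(c - b)
  n  <- unit3(cross3(b - a, bc))
  m  <- cross3(n, bc)
  # local displacement expressed in the (bc, m, n) frame
  d_bc <- -bond * cos(th)
  d_m  <-  bond * sin(th) * cos(ph)
  d_n  <-  bond * sin(th) * sin(ph)
  c + bc * d_bc + m * d_m + n * d_n
}
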