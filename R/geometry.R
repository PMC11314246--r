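# Small 3D geometry helpers shared by the chain builder, dihedral
# measurement and RMSD code.  Coordinates are plain numeric length-3
# vectors or n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral (torsion) angle of four points
#'
#' Signed torsion about the b-c axis, IUPAC convention, in radians in
#' (-pi, pi].
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors (Angstrom).
#' @return Torsion angle in radians.
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x)
}

# Place atom D given positions of A, B, C and internal coordinates:
# bond |C-D|, angle B-C-D (rad), torsion A-B-C-D (rad).  Natural
# extension reference frame (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(
    -cos(angle),
    sin(angle) * cos(torsion),
    -sin(angle) * sin(torsion)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Minimal superposition RMSD (Kabsch algorithm)
#'
#' Root-mean-square deviation between two coordinate sets after optimal
#' rigid-body superposition (translation plus proper rotation, determinant
#' +1, found by SVD of the covariance matrix).
#'
#' @param a,b Numeric n x 3 coordinate matrices with identical atom order.
#' @return RMSD in the units of the inputs (Angstrom).
#'
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch_rmsd(a, a + 5)  # pure translation: 0
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || ncol(a) != 3L) {
    abort("Coordinate sets must be n x 3 matrices with equal n.")
  }
  if (nrow(a) < 3L) abort("At least 3 atoms are required for superposition.")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$v %*% t(s$u)))
  # proper rotation (det +1): flip the smallest singular axis if needed
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(sum((ac - bc %*% rot)^2) / nrow(a))
}

# All-pairs minimal RMSD for a list of n x 3 matrices, computed in blocks.
# Returns a symmetric matrix.
pairwise_rmsd <- function(coords) {
  n <- length(coords)
  centred <- lapply(coords, function(m) sweep(m, 2, colMeans(m)))
  norms <- vapply(centred, function(m) sum(m^2), numeric(1))
  rmat <- matrix(0, n, n)
  na <- nrow(coords[[1]])
  for (i in seq_len(n - 1L)) {
    ai <- centred[[i]]
    for (j in seq.int(i + 1L, n)) {
      s <- svd(crossprod(ai, centred[[j]]))
      d <- sign(det(s$v %*% t(s$u)))
      e2 <- norms[i] + norms[j] - 2 * sum(s$d * c(1, 1, d))
      rmat[i, j] <- rmat[j, i] <- sqrt(max(e2, 0) / na)
    }
  }
  rmat
}

# Column-wise cross product of 3 x n matrices.
cross_cols <- function(a, b) {
  rbind(
    a[2, ] * b[3, ] - a[3, ] * b[2, ],
    a[3, ] * b[1, ] - a[1, ] * b[3, ],
    a[1, ] * b[2, ] - a[2, ] * b[1, ]
  )
}

# Torsion angle for one atom quadruple across many frames; a, b, c, d are
# 3 x n matrices of coordinates.  Same convention as torsion_angle().
torsion_series <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross_cols(b1, b2)
  n2 <- cross_cols(b2, b3)
  b2u <- sweep(b2, 2, sqrt(colSums(b2^2)), "/")
  m1 <- cross_cols(n1, b2u)
  atan2(colSums(m1 * n2), colSums(n1 * n2))
}

# Rotation matrix about z by theta radians.
rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
}
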