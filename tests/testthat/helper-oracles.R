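# Independent oracles used to cross-check the implementation.

# Minimal RMSD by Horn's closed-form quaternion method (eigendecomposition
# of the 4x4 key matrix) -- algorithmically independent of the SVD-based
# Kabsch implementation in the package.
horn_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  m <- crossprod(a, b)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(e2, 0))
}

# Naive reference implementation of greedy neighbour-count clustering,
# written as plain loops over a Horn-RMSD matrix.
brute_daura <- function(coords, cutoff) {
  n <- length(coords)
  rmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) rmat[i, j] <- rmat[j, i] <- horn_rmsd(coords[[i]], coords[[j]])
    }
  }
  assignment <- rep(NA_integer_, n)
  centers <- integer(0)
  cl <- 0L
  while (anyNA(assignment)) {
    best <- 0L; best_count <- -1L
    for (i in seq_len(n)) {
      if (!is.na(assignment[i])) next
      cnt <- 0L
      for (j in seq_len(n)) {
        if (is.na(assignment[j]) && rmat[i, j] <= cutoff) cnt <- cnt + 1L
      }
      if (cnt > best_count) { best_count <- cnt; best <- i }
    }
    cl <- cl + 1L
    centers[cl] <- best
    for (j in seq_len(n)) {
      if (is.na(assignment[j]) && rmat[best, j] <= cutoff) assignment[j] <- cl
    }
  }
  list(assignment = assignment, centers = centers)
}

# Random rigid transform of an n x 3 matrix.
random_rigid <- function(m) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
    2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
    1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
  sweep(m %*% t(r), 2, rnorm(3, sd = 5), "+")
}
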