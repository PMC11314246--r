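#' Backbone dihedrals for every frame
#'
#' Vectorised phi/psi computation across a whole trajectory.
#'
#' @param trajectory A `ps_trajectory`.
#' @return A list with `phi` and `psi`, each an `n_res x n_frames` matrix in
#'   radians (`NA` for the undefined terminal angles).
#' @export
trajectory_dihedrals <- function(trajectory) {
  top <- trajectory$topology
  at <- top$atoms
  res_idx <- top$residues$author_index
  nres <- length(res_idx)
  nf <- n_frames(trajectory)
  row_of <- function(name) {
    match(paste(res_idx, name), paste(at$author_index, at$name))
  }
  nr <- row_of("N"); car <- row_of("CA"); cr <- row_of("C")
  get3 <- function(row) matrix(trajectory$coords[row, , ], nrow = 3)
  phi <- matrix(NA_real_, nres, nf, dimnames = list(res_idx, NULL))
  psi <- matrix(NA_real_, nres, nf, dimnames = list(res_idx, NULL))
  for (i in seq_len(nres)) {
    if (i > 1L) {
      phi[i, ] <- torsion_series(get3(cr[i - 1]), get3(nr[i]),
                                 get3(car[i]), get3(cr[i]))
    }
    if (i < nres) {
      psi[i, ] <- torsion_series(get3(nr[i]), get3(car[i]),
                                 get3(cr[i]), get3(nr[i + 1]))
    }
  }
  list(phi = phi, psi = psi)
}

# TRUE where the run of TRUEs containing each element has length >= min_run.
in_run <- function(x, min_run = 2L) {
  r <- rle(x)
  rep(r$values & r$lengths >= min_run, r$lengths)
}

#' Assign secondary structure from dihedrals and hydrogen bonds
#'
#' A deliberately simple per-frame assigner (it does not reproduce STRIDE or
#' DSSP): dihedral continuity defines candidate helices and hydrogen bonds
#' confirm them.
#' * `H` (alpha-helix): a maximal run of consecutive residues whose (phi,
#'   psi) lie within `helix_tol` of the ideal helix angles is marked helical
#'   when it contains at least two consecutive O(i)...H(i+4) hydrogen bonds
#'   (switching value > `hb_threshold`) lying fully inside the run;
#' * `G` (3/10 helix): likewise with O(i)...H(i+3) bonds;
#' * `E` (strand): runs of at least two consecutive residues with (phi,
#'   psi) within `strand_tol` of the ideal strand angles;
#' * `T` (turn): residues covered by an isolated helical hydrogen bond;
#' * `C` (coil): everything else.
#'
#' The alpha basin is deliberately tight (20 degrees, the canonical alpha
#' core); the strand basin is the customary 40 degrees.
#'
#' @param trajectory A `ps_trajectory`.
#' @param params Switching parameters ([switching_params()]).
#' @param helix_tol Half-width of the helical dihedral basin, degrees.
#' @param strand_tol Half-width of the strand dihedral basin, degrees.
#' @param hb_threshold Switching value above which a hydrogen bond counts.
#'
#' @return An object of class `ps_sstruct`: list with `states` (`n_res x
#'   n_frames` character matrix) and `propensity` (tibble: `author_index`,
#'   `code`, `klass`, one column per state, and `helix` = the `H`
#'   frequency).  `tidy()` returns the propensity tibble.
#' @export
assign_secondary_structure <- function(trajectory,
                                       params = switching_params(),
                                       helix_tol = 20,
                                       strand_tol = 40,
                                       hb_threshold = 0.5) {
  top <- trajectory$topology
  res <- top$residues
  nres <- nrow(res)
  nf <- n_frames(trajectory)
  at <- top$atoms
  res_idx <- res$author_index
  hel <- ideal_dihedrals("helix")
  strd <- ideal_dihedrals("strand")

  dih <- trajectory_dihedrals(trajectory)
  in_basin <- function(ref, tol_deg) {
    tol <- tol_deg * pi / 180
    dphi <- abs(wrap_angle(dih$phi - ref[["phi"]])) <= tol
    dpsi <- abs(wrap_angle(dih$psi - ref[["psi"]])) <= tol
    # terminal residues are judged on their one defined angle
    (dphi | is.na(dih$phi)) & (dpsi | is.na(dih$psi))
  }
  helical_basin <- in_basin(hel, helix_tol)
  strand_basin <- in_basin(strd, strand_tol)

  o_rows <- match(paste(res_idx, "O"), paste(at$author_index, at$name))
  h_rows <- match(paste(res_idx, "H"), paste(at$author_index, at$name))
  bond_mat <- function(offset) {
    m <- matrix(FALSE, nres, nf)
    for (i in seq_len(nres - offset)) {
      oi <- o_rows[i]; hj <- h_rows[i + offset]
      if (is.na(oi) || is.na(hj)) next
      d <- sqrt(colSums((matrix(trajectory$coords[oi, , ], nrow = 3) -
                           matrix(trajectory$coords[hj, , ], nrow = 3))^2))
      m[i, ] <- switching(d, params) > hb_threshold
    }
    m
  }
  bond4 <- bond_mat(4L)
  bond3 <- bond_mat(3L)

  cover <- function(active, offset) {
    cov <- logical(nres)
    for (i in which(active)) cov[i:min(i + offset, nres)] <- TRUE
    cov
  }
  # mark basin runs that contain two consecutive bonds O(j)..H(j+offset),
  # O(j+1)..H(j+1+offset) lying fully inside the run
  confirmed_runs <- function(basin, bonds, offset) {
    out <- logical(nres)
    r <- rle(basin)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    pair <- bonds & c(bonds[-1], FALSE)  # bond j and j+1 both active
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      jmax <- e - offset - 1L
      if (jmax >= s && any(pair[s:jmax])) out[s:e] <- TRUE
    }
    out
  }
  states <- matrix("C", nres, nf, dimnames = list(res_idx, NULL))
  for (f in seq_len(nf)) {
    b4 <- bond4[, f]; b3 <- bond3[, f]
    h_cov <- confirmed_runs(helical_basin[, f], b4, 4L)
    g_cov <- confirmed_runs(helical_basin[, f], b3, 3L) & !h_cov
    e_cov <- in_run(strand_basin[, f], 2L) & !h_cov & !g_cov
    iso <- (b4 & !in_run(b4, 2L)) | (b3 & !in_run(b3, 2L))
    t_cov <- cover(iso, 4L) & !h_cov & !g_cov & !e_cov
    st <- rep("C", nres)
    st[t_cov] <- "T"; st[e_cov] <- "E"; st[g_cov] <- "G"; st[h_cov] <- "H"
    states[, f] <- st
  }

  prop <- tibble(author_index = res_idx, code = res$code, klass = res$klass)
  for (s in c("H", "G", "E", "T", "C")) {
    prop[[s]] <- unname(rowMeans(states == s))
  }
  prop$helix <- prop$H
  structure(list(states = states, propensity = prop), class = "ps_sstruct")
}

#' @export
tidy.ps_sstruct <- function(x, ...) x$propensity

#' @export
print.ps_sstruct <- function(x, ...) {
  cat("<ps_sstruct> ", nrow(x$states), " residues x ", ncol(x$states),
      " frames; mean helix propensity ",
      format(mean(x$propensity$H), digits = 3), "\n", sep = "")
  invisible(x)
}
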