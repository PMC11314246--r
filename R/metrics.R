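#' Switching-function parameters
#'
#' Parameters of the rational switching function used to count helical
#' hydrogen bonds: `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with defaults
#' `r0 = 2.5` Angstrom, `n = 8`, `m = 12`.
#'
#' @param r0 Switching distance, Angstrom.
#' @param n,m Integer exponents with `m > n > 0`.
#' @return A named list used by [switching()] and
#'   [helical_hbond_counts()].
#' @export
switching_params <- function(r0 = 2.5, n = 8, m = 12) {
  if (r0 <= 0) abort("r0 must be positive.")
  if (!(m > n && n > 0)) abort("Exponents must satisfy m > n > 0.")
  list(r0 = r0, n = n, m = m)
}

#' Rational switching function
#'
#' Evaluates `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)`, a smooth counter
#' that is 1 at contact and decays to 0 beyond `r0`.  The removable
#' singularity at `r = r0` is evaluated as its limit `n/m`.
#'
#' @param r Distances, Angstrom (vectorised, must be non-negative).
#' @param params Parameters from [switching_params()].
#' @return Values in \[0, 1\].
#'
#' @examples
#' switching(c(0, 2.5, 5))
#' @export
switching <- function(r, params = switching_params()) {
  if (any(r < 0)) abort("Distances must be non-negative.")
  x <- r / params$r0
  s <- numeric(length(x))
  at_r0 <- abs(x - 1) < 1e-9
  s[at_r0] <- params$n / params$m
  s[!at_r0] <- (1 - x[!at_r0]^params$n) / (1 - x[!at_r0]^params$m)
  s
}

#' Helical hydrogen-bond counts per frame
#'
#' Counts alpha-helical and 3/10-helical backbone hydrogen bonds as sums of
#' the switching function over carbonyl-oxygen/amide-hydrogen distances
#' O(i)...H(i+4) (alpha) and O(i)...H(i+3) (3/10).  Pairs whose amide
#' hydrogen is absent are skipped.
#'
#' @param trajectory A `ps_trajectory`.
#' @param params Switching parameters ([switching_params()]).
#' @return A tibble with columns `frame`, `n_alpha_hb`, `n_310_hb`.
#' @export
helical_hbond_counts <- function(trajectory, params = switching_params()) {
  top <- trajectory$topology
  res_idx <- top$residues$author_index
  nres <- length(res_idx)
  nf <- n_frames(trajectory)
  at <- top$atoms
  o_rows <- match(paste(res_idx, "O"), paste(at$author_index, at$name))
  h_rows <- match(paste(res_idx, "H"), paste(at$author_index, at$name))

  pair_sum <- function(offset) {
    tot <- numeric(nf)
    for (i in seq_len(nres - offset)) {
      oi <- o_rows[i]; hj <- h_rows[i + offset]
      if (is.na(oi) || is.na(hj)) next
      d <- sqrt(colSums((matrix(trajectory$coords[oi, , ], nrow = 3) -
                           matrix(trajectory$coords[hj, , ], nrow = 3))^2))
      tot <- tot + switching(d, params)
    }
    tot
  }
  tibble(
    frame = seq_len(nf),
    n_alpha_hb = pair_sum(4L),
    n_310_hb = pair_sum(3L)
  )
}

#' Dihedral offset function
#'
#' Measures the similarity of a backbone conformation to an ideal
#' beta-strand:
#' `DH = 1/2 * sum_i [(1 + cos(phi_i - phi_ref)) + (1 + cos(psi_i - psi_ref))]`
#' with strand references `phi_ref = -2.36` rad and `psi_ref = +2.36` rad.
#' For an N-residue chain there are N-1 defined phi and N-1 defined psi
#' angles, so DH ranges from 0 (anti-strand) to `2(N-1)` (ideal strand).
#' Missing (`NA`) dihedrals are skipped; the number of terms actually used
#' is attached as attribute `n_terms`.
#'
#' @param dihedrals A tibble with columns `phi` and `psi` in radians, as
#'   from [measure_dihedrals()].
#' @param phi_ref,psi_ref Strand reference angles, radians.
#' @return The scalar DH value.
#'
#' @examples
#' d <- tibble::tibble(phi = rep(-2.36, 31), psi = rep(2.36, 31))
#' d$phi[1] <- NA; d$psi[31] <- NA
#' dihedral_offset(d)  # 60 for a 31-residue ideal strand
#' @export
dihedral_offset <- function(dihedrals, phi_ref = -2.36, psi_ref = 2.36) {
  stopifnot(all(c("phi", "psi") %in% names(dihedrals)))
  phi <- dihedrals$phi[!is.na(dihedrals$phi)]
  psi <- dihedrals$psi[!is.na(dihedrals$psi)]
  if (length(phi) + length(psi) == 0L) {
    abort("No defined dihedrals; need at least 2 residues.")
  }
  dh <- 0.5 * (sum(1 + cos(phi - phi_ref)) + sum(1 + cos(psi - psi_ref)))
  attr(dh, "n_terms") <- length(phi) + length(psi)
  dh
}

#' Gyration radius and gyration-tensor shape descriptors
#'
#' Computes the radius of gyration `Rg^2 = (1/N) sum_i (r_i - r_centre)^2`
#' and the square roots of the three eigenvalues of the gyration tensor
#' (`Gmax >= Gmid >= Gmin`), which satisfy
#' `Gmax^2 + Gmid^2 + Gmin^2 = Rg^2`.  Unweighted by default, matching the
#' per-atom definition; pass atomic masses in `weights` for the
#' mass-weighted variant.
#'
#' @param coords `n x 3` coordinate matrix, Angstrom.
#' @param weights Optional per-atom weights (e.g. masses).
#' @return A one-row tibble: `rg`, `gmax`, `gmid`, `gmin` (Angstrom).
#'
#' @examples
#' gyration(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))  # Rg = 1
#' @export
gyration <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) abort("At least 2 atoms are required.")
  w <- if (is.null(weights)) rep(1, nrow(coords)) else weights
  stopifnot(length(w) == nrow(coords), all(w > 0))
  w <- w / sum(w)
  ctr <- colSums(coords * w)
  dc <- sweep(coords, 2, ctr)
  gt <- crossprod(dc * w, dc)  # 3x3 gyration tensor
  ev <- sort(eigen(gt, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  tibble(
    rg = sqrt(sum(ev)),
    gmax = sqrt(ev[1]), gmid = sqrt(ev[2]), gmin = sqrt(ev[3])
  )
}

#' Per-frame conformation metrics
#'
#' Convenience wrapper computing, for every frame: the alpha and 3/10
#' helical hydrogen-bond counts, the dihedral offset DH, and the gyration
#' descriptors (Rg, Gmax, Gmid, Gmin).
#'
#' @param trajectory A `ps_trajectory`.
#' @param params Switching parameters.
#' @param mass_weighted Use mass-weighted gyration (default unweighted).
#' @param heavy_only Restrict gyration to heavy atoms.
#' @return A tibble with one row per frame.
#' @export
conformation_metrics <- function(trajectory, params = switching_params(),
                                 mass_weighted = FALSE, heavy_only = TRUE) {
  hb <- helical_hbond_counts(trajectory, params)
  top <- trajectory$topology
  sel <- if (heavy_only) top$atoms$element != "H" else rep(TRUE, nrow(top$atoms))
  w <- if (mass_weighted) top$atoms$mass[sel] else NULL
  nf <- n_frames(trajectory)
  gyr <- purrr::map_dfr(seq_len(nf), function(f) {
    gyration(trajectory$coords[sel, , f], weights = w)
  })
  dh <- vapply(seq_len(nf), function(f) {
    as.numeric(dihedral_offset(
      measure_dihedrals(frame_coords(trajectory, f), top)
    ))
  }, numeric(1))
  bind_cols(hb, tibble(dh = dh), gyr)
}
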