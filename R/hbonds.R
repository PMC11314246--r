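#' Protein-surface hydrogen bonds
#'
#' Counts hydrogen bonds between the peptide and a hydroxyl-terminated SAM
#' surface with a standard geometric criterion: donor-acceptor heavy-atom
#' distance at most `dist_cutoff` (default 3.5 Angstrom) and D-H...A angle
#' at least `angle_cutoff` degrees (default 150).  A residue acts as donor
#' when one of its N-H groups bridges to a surface oxygen, and as acceptor
#' when a surface O-H donates to one of its O/N acceptors.  Methyl-terminated
#' (CH3) surfaces cannot hydrogen bond; all counts are zero with a notice.
#'
#' @param trajectory A `ps_trajectory` with a surface.
#' @param dist_cutoff Donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cutoff Minimum D-H...A angle, degrees.
#'
#' @return A tibble with one row per residue: `author_index`, `code`,
#'   `klass`, `donor_mean`, `acceptor_mean` (mean hydrogen-bond counts per
#'   frame).
#' @export
surface_hbonds <- function(trajectory, dist_cutoff = 3.5,
                           angle_cutoff = 150) {
  require_surface(trajectory)
  top <- trajectory$topology
  res <- top$residues
  nf <- n_frames(trajectory)
  out <- tibble(
    author_index = res$author_index, code = res$code, klass = res$klass,
    donor_mean = 0, acceptor_mean = 0
  )
  if (trajectory$surface$ligand != "OH") {
    inform("CH3-terminated surface cannot hydrogen bond; returning zeros.")
    return(out)
  }
  satoms <- surface_atoms(trajectory$surface)
  s_o <- as.matrix(satoms[satoms$name == "OT", c("x", "y", "z")])
  s_h <- as.matrix(satoms[satoms$name == "HT", c("x", "y", "z")])

  at <- top$atoms
  # peptide N-H donor pairs (H follows its N within the residue)
  don_h <- which(at$donor)
  don_n <- vapply(don_h, function(i) {
    cand <- which(at$author_index == at$author_index[i] & at$name == "N")
    cand[1]
  }, integer(1))
  acc <- which(at$acceptor)
  cos_min <- cos(angle_cutoff * pi / 180)

  reach <- dist_cutoff + 2  # only frames/atoms near the plane can bond
  z0 <- trajectory$surface$z0
  donor_counts <- matrix(0, nrow(res), nf)
  acceptor_counts <- matrix(0, nrow(res), nf)
  res_row <- function(atom) match(at$author_index[atom], res$author_index)

  for (f in seq_len(nf)) {
    xyz <- frame_coords(trajectory, f)
    # peptide donor -> surface O acceptor
    near <- which(xyz[don_n, 3] - z0 <= reach)
    for (k in near) {
      nd <- xyz[don_n[k], ]; hd <- xyz[don_h[k], ]
      d2 <- colSums((t(s_o) - nd)^2)
      ok <- which(d2 <= dist_cutoff^2)
      for (j in ok) {
        v1 <- nd - hd; v2 <- s_o[j, ] - hd
        cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
        if (cosang <= cos_min) {
          r <- res_row(don_n[k])
          donor_counts[r, f] <- donor_counts[r, f] + 1
        }
      }
    }
    # surface O-H donor -> peptide acceptor
    near_a <- which(xyz[acc, 3] - z0 <= reach)
    for (k in near_a) {
      a_xyz <- xyz[acc[k], ]
      d2 <- colSums((t(s_o) - a_xyz)^2)
      ok <- which(d2 <= dist_cutoff^2)
      for (j in ok) {
        v1 <- s_o[j, ] - s_h[j, ]; v2 <- a_xyz - s_h[j, ]
        cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
        if (cosang <= cos_min) {
          r <- res_row(acc[k])
          acceptor_counts[r, f] <- acceptor_counts[r, f] + 1
        }
      }
    }
  }
  out$donor_mean <- rowMeans(donor_counts)
  out$acceptor_mean <- rowMeans(acceptor_counts)
  out
}
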