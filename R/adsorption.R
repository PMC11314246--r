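# Per-residue minimum heavy-atom height above the surface plane, as an
# n_res x n_frames matrix.  Column-wise pmin over the few atoms per residue
# keeps this vectorised over frames.
residue_min_z <- function(trajectory) {
  top <- trajectory$topology
  heavy <- top$atoms$element != "H"
  res_of_atom <- match(top$atoms$author_index, top$residues$author_index)
  nf <- n_frames(trajectory)
  out <- matrix(NA_real_, nrow(top$residues), nf,
                dimnames = list(top$residues$author_index, NULL))
  zmat <- matrix(trajectory$coords[, 3, ], ncol = nf)
  for (r in seq_len(nrow(top$residues))) {
    rows <- which(heavy & res_of_atom == r)
    out[r, ] <- do.call(pmin, lapply(rows, function(i) zmat[i, ]))
  }
  out
}

require_surface <- function(trajectory) {
  if (is.null(trajectory$surface)) {
    abort("This analysis requires a trajectory with a surface model.")
  }
  invisible(trajectory)
}

#' Centre-of-mass separation from the surface plane
#'
#' Computes, per frame, the mass-weighted peptide centre-of-mass height above
#' the surface reference plane `z0`, together with the closest residue (by
#' nearest heavy atom) and its separation, and a normalised histogram of the
#' centre-of-mass separation.
#'
#' @param trajectory A `ps_trajectory` with a surface.
#' @param bin_width Histogram bin width in Angstrom.
#'
#' @return An object of class `ps_separation`: list with `series` (tibble:
#'   `frame`, `separation`, `closest_residue`, `closest_code`,
#'   `closest_distance`), `histogram` (tibble: `bin_mid`, `probability`;
#'   probabilities sum to 1) and `bin_width`.  `tidy()` returns the series.
#' @export
com_separation <- function(trajectory, bin_width = 0.5) {
  require_surface(trajectory)
  top <- trajectory$topology
  z0 <- trajectory$surface$z0
  masses <- top$atoms$mass
  nf <- n_frames(trajectory)
  zmat <- matrix(trajectory$coords[, 3, ], ncol = nf)
  com_z <- colSums(zmat * masses) / sum(masses) - z0

  rz <- residue_min_z(trajectory) - z0
  closest <- apply(rz, 2, which.min)
  series <- tibble(
    frame = seq_len(nf),
    separation = com_z,
    closest_residue = top$residues$author_index[closest],
    closest_code = top$residues$code[closest],
    closest_distance = rz[cbind(closest, seq_len(nf))]
  )
  breaks <- seq(floor(min(com_z) / bin_width) * bin_width,
                ceiling(max(com_z) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(com_z, breaks = breaks, plot = FALSE)
  structure(
    list(
      series = series,
      histogram = tibble(bin_mid = h$mids, probability = h$counts / nf),
      bin_width = bin_width
    ),
    class = "ps_separation"
  )
}

#' @export
tidy.ps_separation <- function(x, ...) x$series

#' @export
print.ps_separation <- function(x, ...) {
  cat("<ps_separation> ", nrow(x$series), " frames; mean separation ",
      format(mean(x$series$separation), digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Closest-residue frequency table
#'
#' Counts, over all frames, how often each residue is the closest one to the
#' surface.  Counts sum to the number of frames.
#'
#' @param separation A `ps_separation` from [com_separation()].
#' @return A tibble `author_index`, `code`, `count`, sorted by decreasing
#'   count.
#' @export
closest_residue_table <- function(separation) {
  stopifnot(inherits(separation, "ps_separation"))
  arrange(
    count(separation$series, .data$closest_residue, .data$closest_code,
          name = "count"),
    desc(.data$count)
  ) |>
    dplyr::rename(author_index = "closest_residue", code = "closest_code")
}

#' Per-residue surface separation profile
#'
#' Mean and standard deviation over frames of each residue's nearest
#' heavy-atom height above the surface plane, annotated with the residue
#' class.  The overall mean across residues is attached as attribute
#' `overall_mean`.
#'
#' @param trajectory A `ps_trajectory` with a surface.
#' @return A tibble `author_index`, `code`, `klass`, `mean_separation`,
#'   `sd_separation`.
#' @export
residue_surface_profile <- function(trajectory) {
  require_surface(trajectory)
  rz <- residue_min_z(trajectory) - trajectory$surface$z0
  res <- trajectory$topology$residues
  out <- tibble(
    author_index = res$author_index,
    code = res$code,
    klass = res$klass,
    mean_separation = unname(rowMeans(rz)),
    sd_separation = unname(apply(rz, 1, sd))
  )
  attr(out, "overall_mean") <- mean(rz)
  out
}

#' Residue-surface contact probability and fingerprints
#'
#' A residue is in contact with the surface in a frame when its nearest
#' heavy atom lies within `cutoff` of the surface plane (default 3.5
#' Angstrom, approximately the van der Waals diameter of a carbon atom).
#' Returns the per-residue contact probability (fraction of frames in
#' contact) and the per-frame binary contact fingerprints used for contact
#' clustering.
#'
#' @param trajectory A `ps_trajectory` with a surface.
#' @param cutoff Contact cutoff in Angstrom.
#'
#' @return An object of class `ps_contacts`: list with `probability`
#'   (tibble: `author_index`, `code`, `klass`, `probability`),
#'   `fingerprints` (`n_frames x n_res` logical matrix) and `cutoff`.
#'   `tidy()` returns the probability tibble.
#' @export
contact_probability <- function(trajectory, cutoff = 3.5) {
  require_surface(trajectory)
  if (cutoff <= 0) abort("Contact cutoff must be positive.")
  rz <- residue_min_z(trajectory) - trajectory$surface$z0
  fp <- t(rz <= cutoff)
  res <- trajectory$topology$residues
  colnames(fp) <- res$author_index
  structure(
    list(
      probability = tibble(
        author_index = res$author_index,
        code = res$code,
        klass = res$klass,
        probability = unname(colMeans(fp))
      ),
      fingerprints = fp,
      cutoff = cutoff
    ),
    class = "ps_contacts"
  )
}

#' @export
tidy.ps_contacts <- function(x, ...) x$probability

#' @export
print.ps_contacts <- function(x, ...) {
  cat("<ps_contacts> ", nrow(x$fingerprints), " frames, cutoff ",
      x$cutoff, " A; adsorbed fraction ",
      format(mean(rowSums(x$fingerprints) > 0), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Cluster frames by their residue-contact fingerprints
#'
#' Groups adsorbed frames by the set of residues in contact with the
#' surface.  Identical fingerprints are grouped exactly, then groups whose
#' fingerprints differ by at most `merge_distance` residues (Hamming
#' distance, single linkage) are merged.  Clusters are ranked by population;
#' populations are fractions of *all* frames, so they sum to the
#' adsorbed-frame fraction when `adsorbed_only = TRUE`.
#'
#' @param contacts A `ps_contacts` from [contact_probability()].
#' @param adsorbed_only Cluster only frames with at least one residue in
#'   contact.
#' @param merge_distance Maximum Hamming distance merged by single linkage.
#'
#' @return A tibble with one row per cluster: `cluster`, `n_frames`,
#'   `population`, `n_residues`, `residues` (list column of author indices
#'   of the cluster's modal fingerprint) and `label` (comma-separated
#'   residue labels).  Attribute `assignments` maps each clustered frame to
#'   its cluster.
#' @export
cluster_contacts <- function(contacts, adsorbed_only = TRUE,
                             merge_distance = 1) {
  stopifnot(inherits(contacts, "ps_contacts"))
  fp <- contacts$fingerprints
  n_total <- nrow(fp)
  keep <- if (adsorbed_only) rowSums(fp) > 0 else rep(TRUE, n_total)
  if (!any(keep)) {
    warn("No adsorbed frames; returning an empty cluster table.")
    return(tibble(cluster = integer(), n_frames = integer(),
                  population = numeric(), n_residues = integer(),
                  residues = list(), label = character()))
  }
  fp_k <- fp[keep, , drop = FALSE] * 1L
  key <- apply(fp_k, 1, paste, collapse = "")
  uk <- unique(key)
  ufp <- fp_k[match(uk, key), , drop = FALSE]
  nu <- length(uk)

  # single-linkage merge of distinct fingerprints at Hamming <= merge_distance
  comp <- seq_len(nu)
  if (nu > 1L && merge_distance > 0) {
    hm <- as.matrix(stats::dist(ufp * 1, method = "manhattan"))
    for (i in seq_len(nu - 1L)) {
      for (j in seq.int(i + 1L, nu)) {
        if (hm[i, j] <= merge_distance && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
  }
  frame_comp <- comp[match(key, uk)]
  sizes <- table(frame_comp)
  ord <- order(-as.integer(sizes))
  ranked_ids <- as.integer(names(sizes))[ord]

  res_idx <- as.integer(colnames(fp))
  rows <- purrr::map(seq_along(ranked_ids), function(r) {
    cid <- ranked_ids[r]
    members <- which(frame_comp == cid)
    modal_key <- names(sort(table(key[members]), decreasing = TRUE))[1]
    modal_fp <- as.logical(as.integer(strsplit(modal_key, "")[[1]]))
    resids <- res_idx[modal_fp]
    tibble(
      cluster = r,
      n_frames = length(members),
      population = length(members) / n_total,
      n_residues = length(resids),
      residues = list(resids),
      label = paste(resids, collapse = ",")
    )
  })
  out <- bind_rows(rows)
  assign <- setNames(match(frame_comp, ranked_ids), which(keep))
  attr(out, "assignments") <- assign
  out
}

#' Keep only adsorbed frames
#'
#' A frame is adsorbed when any residue is in contact with the surface at
#' the contact cutoff (nearest heavy atom within `cutoff` of the plane).
#'
#' @param trajectory A `ps_trajectory` with a surface.
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `ps_trajectory` containing only the adsorbed frames; the
#'   logical frame mask is attached as attribute `adsorbed`.
#' @export
adsorbed_filter <- function(trajectory, cutoff = 3.5) {
  require_surface(trajectory)
  rz <- residue_min_z(trajectory) - trajectory$surface$z0
  keep <- apply(rz <= cutoff, 2, any)
  if (!any(keep)) {
    warn("No adsorbed frames at this cutoff; returning an empty trajectory.")
  }
  out <- subset_frames(trajectory, keep)
  attr(out, "adsorbed") <- keep
  out
}
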