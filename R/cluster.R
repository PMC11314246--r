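kB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/mol/K

#' Select atoms for RMSD-based analyses
#'
#' @param topology A `ps_topology`.
#' @param selection `"backbone"` (N, CA, C, O; the default for clustering),
#'   `"ca"`, `"heavy"` or `"all"`.
#' @return Integer vector of atom row indices.
#' @export
atom_selection <- function(topology,
                           selection = c("backbone", "ca", "heavy", "all")) {
  selection <- match.arg(selection)
  at <- topology$atoms
  switch(selection,
    backbone = which(at$name %in% c("N", "CA", "C", "O")),
    ca = which(at$name == "CA"),
    heavy = which(at$element != "H"),
    all = seq_len(nrow(at))
  )
}

frames_as_list <- function(trajectory, sel) {
  nf <- n_frames(trajectory)
  lapply(seq_len(nf), function(f) trajectory$coords[sel, , f])
}

#' Daura conformational clustering
#'
#' Greedy neighbour-count clustering on the pairwise minimal-RMSD matrix:
#' repeatedly, the frame with the most neighbours within `cutoff` becomes a
#' cluster centre (ties broken by the lowest frame index), it and its
#' neighbours are removed, until no frames remain.
#'
#' @param trajectory A `ps_trajectory`, or a list of `n x 3` coordinate
#'   matrices.
#' @param cutoff RMSD cutoff in Angstrom (default 3).
#' @param selection Atom selection (see [atom_selection()]); ignored when a
#'   coordinate list is supplied.
#'
#' @return An object of class `ps_cluster`: list with `assignments`
#'   (integer per frame; cluster 1 is the most populated), `centers` (frame
#'   id per cluster), `populations`, `n_conf`, `s_conf` (conformational
#'   entropy in kB units), `cutoff`, `n_frames`.  `tidy()` gives a
#'   per-cluster table including the free energy offset from the most
#'   populated cluster; `glance()` a one-row summary.
#'
#' @examples
#' frames <- replicate(5, matrix(rnorm(12), 4, 3), simplify = FALSE)
#' daura_cluster(frames, cutoff = 10)
#' @export
daura_cluster <- function(trajectory, cutoff = 3, selection = "backbone") {
  coords <- if (inherits(trajectory, "ps_trajectory")) {
    frames_as_list(trajectory, atom_selection(trajectory$topology, selection))
  } else {
    trajectory
  }
  n <- length(coords)
  if (n < 1L) abort("At least one frame is required.")
  rmat <- pairwise_rmsd(coords)
  daura_from_rmsd(rmat, cutoff)
}

# Core greedy loop on a precomputed RMSD matrix.
daura_from_rmsd <- function(rmat, cutoff) {
  n <- nrow(rmat)
  neigh <- rmat <= cutoff
  remaining <- rep(TRUE, n)
  assignments <- integer(n)
  centers <- integer(0)
  k <- 0L
  while (any(remaining)) {
    counts <- colSums(neigh[remaining, , drop = FALSE]) * remaining
    center <- which.max(counts)  # ties: lowest index
    members <- which(neigh[, center] & remaining)
    k <- k + 1L
    assignments[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  populations <- as.vector(table(factor(assignments, levels = seq_len(k)))) / n
  ord <- order(-populations, centers)
  assignments <- match(assignments, ord)
  centers <- centers[ord]
  populations <- populations[ord]
  structure(
    list(
      assignments = assignments,
      centers = centers,
      populations = populations,
      n_conf = k,
      s_conf = conformational_entropy(populations),
      cutoff = cutoff,
      n_frames = n
    ),
    class = "ps_cluster"
  )
}

#' @export
print.ps_cluster <- function(x, ...) {
  cat("<ps_cluster> ", x$n_frames, " frames -> ", x$n_conf,
      " clusters (cutoff ", x$cutoff, " A); Sconf = ",
      format(x$s_conf, digits = 4), " kB\n", sep = "")
  invisible(x)
}

#' @param x A `ps_cluster`.
#' @param temperature Temperature in K for the free-energy column.
#' @param ... Unused.
#' @rdname daura_cluster
#' @export
tidy.ps_cluster <- function(x, temperature = 300, ...) {
  tibble(
    cluster = seq_len(x$n_conf),
    center_frame = x$centers,
    n_frames = as.integer(round(x$populations * x$n_frames)),
    population = x$populations,
    delta_g = -kB_KCAL * temperature *
      log(x$populations / max(x$populations))
  )
}

#' @rdname daura_cluster
#' @export
glance.ps_cluster <- function(x, ...) {
  tibble(n_frames = x$n_frames, n_conf = x$n_conf, s_conf = x$s_conf,
         cutoff = x$cutoff)
}

#' Conformational entropy of cluster populations
#'
#' Shannon entropy `S = -sum_i p_i log(p_i)` of the cluster populations, in
#' units of the Boltzmann constant.  Bounded by `log(n_clusters)`.
#'
#' @param populations Non-negative cluster populations summing to 1.
#' @return Entropy in kB units.
#'
#' @examples
#' conformational_entropy(c(0.5, 0.5))  # log(2)
#' @export
conformational_entropy <- function(populations) {
  if (any(populations < 0)) abort("Populations must be non-negative.")
  if (abs(sum(populations) - 1) > 1e-6) {
    abort("Populations must sum to 1.")
  }
  p <- populations[populations > 0]
  -sum(p * log(p))
}

#' Conformational-ensemble overlap between systems
#'
#' Pools frames from two or more labelled trajectories, clusters the pooled
#' set (Daura method), and reports each cluster's occupancy within every
#' system (the fraction of that system's frames assigned to the cluster).
#' The overlap score is `sum_clusters min_systems occupancy`: 1 when all
#' systems populate the same clusters with identical weights, 0 when no
#' cluster is shared.
#'
#' @param trajectories Named list of `ps_trajectory` objects (or coordinate
#'   lists) with identical atom selections.
#' @param cutoff RMSD cutoff, Angstrom.
#' @param selection Atom selection.
#'
#' @return An object of class `ps_overlap`: list with `table` (tibble:
#'   `cluster`, `population`, one occupancy column per system), `overlap`
#'   (the score) and `cluster` (the pooled `ps_cluster`).
#' @export
combined_overlap <- function(trajectories, cutoff = 3,
                             selection = "backbone") {
  if (length(trajectories) < 2L) {
    abort("At least two labelled trajectories are required.")
  }
  labels <- names(trajectories) %||% paste0("system", seq_along(trajectories))
  coord_lists <- purrr::map(trajectories, function(tr) {
    if (inherits(tr, "ps_trajectory")) {
      frames_as_list(tr, atom_selection(tr$topology, selection))
    } else {
      tr
    }
  })
  n_atoms <- vapply(coord_lists, function(cl) nrow(cl[[1]]), numeric(1))
  if (length(unique(n_atoms)) != 1L) {
    abort("Trajectories have incompatible atom selections.")
  }
  pooled <- purrr::flatten(coord_lists)
  system_of <- rep(labels, vapply(coord_lists, length, integer(1)))
  cl <- daura_cluster(pooled, cutoff = cutoff, selection = selection)

  occ <- purrr::map(labels, function(lb) {
    mine <- cl$assignments[system_of == lb]
    as.vector(table(factor(mine, levels = seq_len(cl$n_conf)))) / length(mine)
  })
  names(occ) <- labels
  tab <- bind_cols(
    tibble(cluster = seq_len(cl$n_conf), population = cl$populations),
    as_tibble(occ)
  )
  overlap <- sum(do.call(pmin, occ))
  structure(list(table = tab, overlap = overlap, cluster = cl),
            class = "ps_overlap")
}

#' @export
print.ps_overlap <- function(x, ...) {
  cat("<ps_overlap> ", x$cluster$n_conf, " pooled clusters across ",
      ncol(x$table) - 2L, " systems; overlap score ",
      format(x$overlap, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ps_overlap <- function(x, ...) x$table

#' Equilibration diagnostic: low-free-energy cluster count over time
#'
#' Clusters growing prefixes of a trajectory and counts, for each prefix,
#' the clusters whose free energy lies within `delta_g_max` (default 2
#' kcal/mol) of the most populated cluster, i.e. whose population satisfies
#' `p_i / p_max >= exp(-delta_g_max / (kB T))` (0.0349 at 300 K).  The
#' curve plateaus once the ensemble stops discovering new thermally
#' relevant conformations.
#'
#' @param trajectory A `ps_trajectory` or list of coordinate matrices.
#' @param window Prefix increment in frames.
#' @param cutoff RMSD cutoff, Angstrom.
#' @param selection Atom selection.
#' @param temperature Temperature, K.
#' @param delta_g_max Free-energy window, kcal/mol.
#' @return A tibble with columns `n_frames`, `n_clusters`,
#'   `n_low_energy`.
#' @export
equilibration_curve <- function(trajectory, window = 50, cutoff = 3,
                                selection = "backbone", temperature = 300,
                                delta_g_max = 2) {
  coords <- if (inherits(trajectory, "ps_trajectory")) {
    frames_as_list(trajectory, atom_selection(trajectory$topology, selection))
  } else {
    trajectory
  }
  n <- length(coords)
  rmat <- pairwise_rmsd(coords)
  ratio_min <- exp(-delta_g_max / (kB_KCAL * temperature))
  sizes <- unique(c(seq(window, n, by = window), n))
  purrr::map_dfr(sizes, function(m) {
    cl <- daura_from_rmsd(rmat[seq_len(m), seq_len(m), drop = FALSE], cutoff)
    tibble(
      n_frames = m,
      n_clusters = cl$n_conf,
      n_low_energy = sum(cl$populations / max(cl$populations) >= ratio_min)
    )
  })
}
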