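#' Trajectory container
#'
#' Bundles per-frame coordinates with their topology and (optionally) the
#' SAM surface the peptide sits on.  Coordinates are stored as an
#' `n_atoms x 3 x n_frames` array in Angstrom; atom rows align with
#' `topology$atoms`.
#'
#' @param topology A `ps_topology`.
#' @param coords `n_atoms x 3 x n_frames` numeric array (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param surface Optional `ps_surface`.
#' @param frame_spacing Frame spacing in ps (metadata).
#'
#' @return An object of class `ps_trajectory`.
#' @export
ps_trajectory <- function(topology, coords, surface = NULL,
                          frame_spacing = 10) {
  stopifnot(inherits(topology, "ps_topology"))
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    abort("coords must be an n_atoms x 3 x n_frames array.")
  }
  if (dim(coords)[1] != nrow(topology$atoms)) {
    abort("coords atom dimension does not match the topology.")
  }
  if (!all(is.finite(coords))) abort("coords must be finite.")
  if (!is.null(surface)) stopifnot(inherits(surface, "ps_surface"))
  structure(
    list(topology = topology, coords = coords, surface = surface,
         frame_spacing = frame_spacing),
    class = "ps_trajectory"
  )
}

#' @export
print.ps_trajectory <- function(x, ...) {
  cat("<ps_trajectory> ", n_frames(x), " frames x ", dim(x$coords)[1],
      " atoms (", nrow(x$topology$residues), " residues)",
      if (!is.null(x$surface)) paste0(", SAM", tolower(x$surface$ligand),
                                      " surface") else ", no surface",
      "\n", sep = "")
  invisible(x)
}

#' @rdname ps_trajectory
#' @param trajectory A `ps_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Tidy view of trajectory coordinates
#'
#' @param x A `ps_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per atom per frame: `frame`, `atom`,
#'   `name`, `author_index`, `x`, `y`, `z`.
#' @export
as_tibble.ps_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- dim(x$coords)[1]
  at <- x$topology$atoms
  tibble(
    frame = rep(seq_len(nf), each = na),
    atom = rep(at$atom, nf),
    name = rep(at$name, nf),
    author_index = rep(at$author_index, nf),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
}

#' Extract one frame's coordinates
#'
#' @param trajectory A `ps_trajectory`.
#' @param frame Frame index.
#' @return An `n_atoms x 3` matrix.
#' @export
frame_coords <- function(trajectory, frame) {
  trajectory$coords[, , frame, drop = TRUE]
}

#' Subset a trajectory by frame
#'
#' @param trajectory A `ps_trajectory`.
#' @param frames Integer or logical frame index.
#' @return A `ps_trajectory` with the selected frames.
#' @export
subset_frames <- function(trajectory, frames) {
  ps_trajectory(
    trajectory$topology,
    trajectory$coords[, , frames, drop = FALSE],
    surface = trajectory$surface,
    frame_spacing = trajectory$frame_spacing
  )
}
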