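.aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
  Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

pdb_atom_line <- function(serial, name, resname, resid, xyz, element) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resid, xyz[1], xyz[2], xyz[3], element)
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL record per frame; atom naming and residue numbering follow the
#' topology (author indices).
#'
#' @param trajectory A `ps_trajectory`.
#' @param path Output file.
#' @param frames Frames to write (default all).
#' @return `path`, invisibly.
#' @export
write_pdb_multi <- function(trajectory, path, frames = NULL) {
  at <- trajectory$topology$atoms
  frames <- frames %||% seq_len(n_frames(trajectory))
  con <- file(path, "w")
  on.exit(close(con))
  resnames <- unname(.aa3[at$code])
  for (k in seq_along(frames)) {
    xyz <- frame_coords(trajectory, frames[k])
    lines <- vapply(seq_len(nrow(at)), function(i) {
      pdb_atom_line(i, at$name[i], resnames[i], at$author_index[i],
                    xyz[i, ], at$element[i])
    }, character(1))
    writeLines(c(sprintf("MODEL %8d", k), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file
#'
#' @param path PDB file with one MODEL per frame.
#' @param topology Optional `ps_topology`; when supplied, the atom count is
#'   checked and a `ps_trajectory` is returned, else a list with `coords`
#'   (array) and `atoms` (tibble of `name`, `resname`, `resid`).
#' @param surface Optional `ps_surface` attached to the returned trajectory.
#' @export
read_pdb_multi <- function(path, topology = NULL, surface = NULL) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_id <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
  al <- lines[is_atom]
  mi <- model_id[is_atom]
  nf <- length(unique(mi))
  na <- sum(mi == mi[1])
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  coords <- array(NA_real_, dim = c(na, 3, nf))
  coords[, 1, ] <- matrix(x, na, nf)
  coords[, 2, ] <- matrix(y, na, nf)
  coords[, 3, ] <- matrix(z, na, nf)
  first <- mi == mi[1]
  atoms <- tibble(
    name = trimws(substr(al[first], 13, 16)),
    resname = trimws(substr(al[first], 18, 20)),
    resid = as.integer(substr(al[first], 23, 26))
  )
  if (!is.null(topology)) {
    if (nrow(topology$atoms) != na) {
      abort("PDB atom count does not match the supplied topology.")
    }
    return(ps_trajectory(topology, coords, surface = surface))
  }
  list(coords = coords, atoms = atoms)
}

#' Write a trajectory as extended XYZ
#'
#' Per frame: an atom-count line, a comment line carrying the frame index
#' and (when a surface is present) the reference plane height `z0`, then
#' one `element x y z` row per atom.
#'
#' @param trajectory A `ps_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, path) {
  at <- trajectory$topology$atoms
  na <- nrow(at)
  z0 <- if (!is.null(trajectory$surface)) trajectory$surface$z0 else NA
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- frame_coords(trajectory, f)
    writeLines(as.character(na), con)
    writeLines(sprintf(
      "frame=%d%s Properties=species:S:1:pos:R:3", f,
      if (is.na(z0)) "" else sprintf(" z0=%.4f", z0)
    ), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       at$element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ frame series
#'
#' @param path XYZ file written by [write_xyz()] (or compatible).
#' @return A list with `coords` (`n_atoms x 3 x n_frames` array),
#'   `elements` and `comments` (one per frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  comments <- character()
  elements <- NULL
  while (pos <= length(lines)) {
    na <- as.integer(lines[pos])
    comments <- c(comments, lines[pos + 1L])
    block <- lines[seq.int(pos + 2L, pos + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    if (is.null(elements)) elements <- vapply(parts, `[[`, character(1), 1)
    frames[[length(frames) + 1L]] <- t(vapply(
      parts, function(p) as.numeric(p[2:4]), numeric(3)
    ))
    pos <- pos + 2L + na
  }
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  list(coords = coords, elements = elements, comments = comments)
}

#' Export a SAM surface as PDB
#'
#' @param surface A `ps_surface`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_surface_pdb <- function(surface, path) {
  sa <- surface_atoms(surface)
  lines <- vapply(seq_len(nrow(sa)), function(i) {
    pdb_atom_line(i, sa$name[i], "SAM", sa$chain[i] %% 9999L,
                  c(sa$x[i], sa$y[i], sa$z[i]), sa$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' Writes comment lines (`# key: value`) recording the package version,
#' date and any parameters, followed by the tab-separated table.
#'
#' @param x A data frame.
#' @param path Output file.
#' @param params Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, params = list()) {
  hdr <- c(
    paste0("# peptsam version: ",
           as.character(utils::packageVersion("peptsam"))),
    purrr::imap_chr(params, function(v, k) {
      paste0("# ", k, ": ", paste(format(v), collapse = " "))
    })
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # list columns are flattened to comma-separated strings
  x <- mutate(as_tibble(x), across(
    dplyr::where(is.list), ~ vapply(.x, paste, character(1), collapse = ",")
  ))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth as JSON
#'
#' @param truth Ground-truth list from [generate_trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(
    seed = truth$seed,
    frames = truth$frames,
    contacts = truth$contacts,
    states = unname(apply(truth$states, 2, paste, collapse = ","))
  )
  jsonlite::write_json(out, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
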