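# Reduced-backbone atom parameter set.  Charges form a neutral backbone
# group per residue; LJ values are generic element-level 12-6 parameters
# (sigma in Angstrom, epsilon in kcal/mol), masses in amu.  These are toy
# parameters for synthetic-trajectory energetics, not a force field.
.atom_params <- tibble::tribble(
  ~name, ~element, ~role,       ~donor, ~acceptor, ~charge, ~sigma, ~epsilon, ~mass,
  "N",   "N",      "backbone",  FALSE,  TRUE,      -0.47,   3.25,   0.17,     14.01,
  "H",   "H",      "backbone",  TRUE,   FALSE,      0.31,   1.00,   0.015,     1.01,
  "CA",  "C",      "backbone",  FALSE,  FALSE,      0.07,   3.40,   0.10,     13.02,
  "C",   "C",      "backbone",  FALSE,  FALSE,      0.51,   3.40,   0.10,     12.01,
  "O",   "O",      "backbone",  FALSE,  TRUE,      -0.51,   2.96,   0.21,     16.00,
  "CB",  "C",      "sidechain", FALSE,  FALSE,      0.09,   3.90,   0.12,     15.00
)

#' Build a reduced peptide topology
#'
#' Constructs the atom-level description used throughout the package: per
#' residue the backbone atoms N, amide H, CA, C and carbonyl O, plus a single
#' sidechain pseudo-atom (named CB) for every non-glycine residue.  Charged
#' sidechains (D, E negative; K, R positive) carry their formal charge on the
#' pseudo-atom, and the termini are charged (+1 on the N-terminal nitrogen,
#' -1 on the C-terminal carbonyl oxygen), as appropriate at pH 7.
#'
#' @param residues A residue tibble as returned by [ab1040_sequence()]
#'   (columns `author_index`, `code`, `klass`), or a character string of
#'   one-letter codes.
#' @param charged_termini Add +1/-1 to the terminal N / O charges.
#'
#' @return An object of class `ps_topology`: a list with elements
#'   `residues` (tibble) and `atoms` (tibble, one row per atom with columns
#'   `atom`, `name`, `element`, `author_index`, `code`, `role`, `donor`,
#'   `acceptor`, `charge`, `sigma`, `epsilon`, `mass`).
#'
#' @examples
#' top <- build_topology(ab1040_sequence())
#' top
#' @export
build_topology <- function(residues = ab1040_sequence(), charged_termini = TRUE) {
  if (is.character(residues) && length(residues) == 1L) {
    codes <- strsplit(residues, "")[[1]]
    residues <- tibble(
      author_index = seq_along(codes),
      code = codes,
      klass = classify_residue(codes)
    )
  }
  stopifnot(is.data.frame(residues),
            all(c("author_index", "code") %in% names(residues)))
  if (anyDuplicated(residues$author_index)) {
    abort("Residue author_index values must be unique.")
  }
  if (!"klass" %in% names(residues)) {
    residues$klass <- classify_residue(residues$code)
  }

  per_res <- function(idx, code) {
    names <- c("N", "H", "CA", "C", "O")
    if (code != "G") names <- c(names, "CB")
    at <- .atom_params[match(names, .atom_params$name), ]
    at$author_index <- idx
    at$code <- code
    if (code == "G") {
      # fold CB's charge back onto CA so the residue stays neutral
      at$charge[at$name == "CA"] <- at$charge[at$name == "CA"] + 0.09
    } else {
      at$mass[at$name == "CB"] <- max(.sidechain_mass[[code]], 1.01)
      extra <- switch(code,
        D = -1, E = -1, K = +1, R = +1, 0
      )
      at$charge[at$name == "CB"] <- at$charge[at$name == "CB"] + extra
    }
    at
  }
  atoms <- purrr::map2_dfr(residues$author_index, residues$code, per_res)
  if (charged_termini) {
    first_n <- which(atoms$author_index == residues$author_index[1] &
                       atoms$name == "N")
    last_o <- which(atoms$author_index == residues$author_index[nrow(residues)] &
                      atoms$name == "O")
    atoms$charge[first_n] <- atoms$charge[first_n] + 1
    atoms$charge[last_o] <- atoms$charge[last_o] - 1
  }
  atoms <- dplyr::relocate(
    mutate(atoms, atom = row_number()),
    "atom", "name", "element", "author_index", "code", "role"
  )
  structure(list(residues = residues, atoms = atoms), class = "ps_topology")
}

#' @export
print.ps_topology <- function(x, ...) {
  cat("<ps_topology> ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms, net charge ",
      format(sum(x$atoms$charge), digits = 3), " e\n", sep = "")
  cat("  sequence: ", paste(x$residues$code, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.ps_topology <- function(x, ...) x$atoms

#' Serialise a topology to TSV
#'
#' Writes the atom table (one atom per row) to a tab-separated file and reads
#' it back.  The residue table is reconstructed from the atom table on read.
#'
#' @param topology A `ps_topology`.
#' @param path File path.
#'
#' @return `write_topology_tsv()` returns `path` invisibly;
#'   `read_topology_tsv()` returns a `ps_topology`.
#' @export
write_topology_tsv <- function(topology, path) {
  stopifnot(inherits(topology, "ps_topology"))
  write.table(topology$atoms, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology_tsv
#' @export
read_topology_tsv <- function(path) {
  atoms <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
  residues <- distinct_residues(atoms)
  structure(list(residues = residues, atoms = atoms), class = "ps_topology")
}

distinct_residues <- function(atoms) {
  res <- dplyr::distinct(atoms, .data$author_index, .data$code)
  res$klass <- classify_residue(res$code)
  arrange(res, .data$author_index)
}
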