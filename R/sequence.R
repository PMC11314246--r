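#' Amyloid-beta(10-40) peptide sequence
#'
#' Returns the 31-residue fragment of amyloid beta spanning residues 10-40,
#' the construct obtained from the full peptide by removing the disordered
#' first nine residues and the final two.  Residue numbering follows the
#' parent protein, so the fragment runs Y10 ... V40.
#'
#' @param as_string Return a single string instead of a per-residue tibble.
#'
#' @return A tibble with columns `author_index` (10-40), `code` (one-letter
#'   amino-acid code) and `klass` (hydrophobicity class, see
#'   [classify_residue()]), or a length-one character string when
#'   `as_string = TRUE`.
#'
#' @examples
#' ab1040_sequence(as_string = TRUE)
#' head(ab1040_sequence())
#' @export
ab1040_sequence <- function(as_string = FALSE) {
  seq_str <- "YEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"
  if (as_string) {
    return(seq_str)
  }
  codes <- strsplit(seq_str, "")[[1]]
  tibble(
    author_index = seq(10L, 40L),
    code = codes,
    klass = classify_residue(codes)
  )
}

# Four-way classification used to colour residues in contact plots.
# A is counted hydrophobic, G polar; H and Y are grouped with the polar
# residues (H neutral at pH 7, Y's hydroxyl dominating its class here).
.residue_klass <- c(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic", P = "hydrophobic",
  C = "hydrophobic",
  G = "polar", S = "polar", T = "polar", N = "polar", Q = "polar",
  Y = "polar", H = "polar",
  D = "negative", E = "negative",
  K = "positive", R = "positive"
)

#' Classify amino acids by hydrophobicity and charge
#'
#' Assigns each one-letter amino-acid code to one of four classes:
#' `hydrophobic`, `polar`, `negative` (acidic) or `positive` (basic), the
#' scheme used to annotate residue-surface contact profiles.  Alanine is
#' treated as hydrophobic and glycine as polar; histidine is taken neutral
#' (polar) as appropriate at pH 7.
#'
#' @param code Character vector of one-letter amino-acid codes.
#'
#' @return Character vector of classes, same length as `code`.
#'
#' @examples
#' classify_residue(c("L", "E", "K", "Y"))
#' @export
classify_residue <- function(code) {
  code <- toupper(as.character(code))
  kl <- unname(.residue_klass[code])
  if (anyNA(kl)) {
    bad <- unique(code[is.na(kl)])
    abort(paste0(
      "Unknown amino-acid code(s): ", paste(bad, collapse = ", "),
      ". Expected one-letter codes of the 20 standard amino acids."
    ))
  }
  kl
}

# Average sidechain masses (residue mass minus the 56.04 amu backbone
# N-H-CA-C=O unit plus CA's hydrogens), amu.  Used for the sidechain
# pseudo-atom so mass-weighted centres of mass are sensible.
.sidechain_mass <- c(
  A = 15.03, R = 100.14, N = 58.06, D = 59.04, C = 47.10, E = 73.07,
  Q = 72.09, G = 1.01, H = 81.10, I = 57.11, L = 57.11, K = 72.13,
  M = 75.15, F = 91.13, P = 41.07, S = 31.03, T = 45.06, W = 130.17,
  Y = 107.13, V = 43.09
)

#' Write and read a sequence as FASTA
#'
#' FASTA round-trip for peptide sequences (backed by seqinr):
#' `write_fasta()` writes one record, `read_fasta()` reads the first record
#' back.
#'
#' @param sequence Character string of one-letter codes.
#' @param path File path.
#' @param name Record header (without the `>`).
#'
#' @return `write_fasta()` returns `path` invisibly; `read_fasta()` returns a
#'   named character string (name = header).
#'
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' write_fasta(ab1040_sequence(as_string = TRUE), tf, name = "abeta_10_40")
#' read_fasta(tf)
#' @export
write_fasta <- function(sequence, path, name = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seqinr::write.fasta(strsplit(sequence, "")[[1]], names = name,
                      file.out = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(recs) == 0L) abort("No FASTA record found in file.")
  setNames(toupper(as.character(recs[[1]])), names(recs)[1])
}
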