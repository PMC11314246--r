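#' Helical wheel projection
#'
#' Projects a residue segment onto the plane perpendicular to an ideal
#' alpha-helix axis: the k-th residue of the segment sits at `(100 * k) mod
#' 360` degrees (3.6 residues per turn).  The hydrophobic moment direction
#' is the vector sum of unit vectors at the angles of the hydrophobic
#' residues; the hydrophobic face is the set of hydrophobic residues within
#' 90 degrees of that direction (the maximal hydrophobic arc).
#'
#' @param residues Residue tibble (as from [ab1040_sequence()]).
#' @param from,to Author-index range of the helical segment.
#'
#' @return An object of class `ps_wheel`: tibble with `author_index`,
#'   `code`, `klass`, `angle` (degrees in \[0, 360)), `face` (logical:
#'   member of the hydrophobic face).  The hydrophobic moment direction
#'   (degrees) and magnitude are attached as attributes `moment_angle` and
#'   `moment_length`.
#'
#' @examples
#' helical_wheel(ab1040_sequence(), 15, 21)
#' @export
helical_wheel <- function(residues = ab1040_sequence(), from, to) {
  stopifnot(is.data.frame(residues))
  seg <- filter(residues, .data$author_index >= from, .data$author_index <= to)
  if (nrow(seg) == 0L) abort("Empty segment: no residues in [from, to].")
  seg$angle <- (100 * (seq_len(nrow(seg)) - 1L)) %% 360
  hyd <- seg$klass == "hydrophobic"
  theta <- seg$angle * pi / 180
  mx <- sum(cos(theta[hyd])); my <- sum(sin(theta[hyd]))
  moment_angle <- (atan2(my, mx) * 180 / pi) %% 360
  moment_length <- sqrt(mx^2 + my^2)
  ang_diff <- abs(((seg$angle - moment_angle + 180) %% 360) - 180)
  seg$face <- hyd & ang_diff <= 90
  out <- structure(seg, class = c("ps_wheel", class(seg)))
  attr(out, "moment_angle") <- moment_angle
  attr(out, "moment_length") <- moment_length
  out
}

#' @export
print.ps_wheel <- function(x, ...) {
  cat("<ps_wheel> segment ", min(x$author_index), "-", max(x$author_index),
      "; hydrophobic face: ",
      paste0(x$code[x$face], x$author_index[x$face], collapse = ", "),
      "\n  hydrophobic moment at ",
      format(attr(x, "moment_angle"), digits = 4), " deg (length ",
      format(attr(x, "moment_length"), digits = 3), ")\n", sep = "")
  NextMethod()
}
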