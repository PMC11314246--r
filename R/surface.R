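# Toy nonbonded parameters for the SAM terminal groups (sigma Angstrom,
# epsilon kcal/mol, charge e).  The CH3 terminus is a neutral united atom;
# the OH terminus is a polar O-H pair with zero net charge.
.surface_params <- list(
  CH3 = tibble::tribble(
    ~name, ~element, ~dz,  ~donor, ~acceptor, ~charge, ~sigma, ~epsilon, ~mass,
    "CT",  "C",      0.0,  FALSE,  FALSE,      0.00,   3.75,   0.195,    15.03
  ),
  OH = tibble::tribble(
    ~name, ~element, ~dz,  ~donor, ~acceptor, ~charge, ~sigma, ~epsilon, ~mass,
    "OT",  "O",      0.0,  FALSE,  TRUE,      -0.40,   3.07,   0.152,    16.00,
    "HT",  "H",      0.96, TRUE,   FALSE,      0.40,   0.40,   0.046,     1.01
  )
)

#' Build a planar SAM surface model
#'
#' Constructs a self-assembled-monolayer surface as a hexagonal
#' (root3 x root3 R30-type overlayer) lattice of `nx * ny` ligand anchor
#' points.  Only the anchor lattice and the terminal group of each chain are
#' modelled; the surface reference plane `z0` is the mean z position of the
#' terminal heavy atoms, the plane all separations in the package are
#' measured from.
#'
#' @param nx,ny Lattice dimensions (chains along x and y).
#' @param ligand `"CH3"` (hydrophobic, methyl-terminated) or `"OH"`
#'   (polar, hydroxyl-terminated).
#' @param lattice_constant Nearest-neighbour chain spacing in Angstrom.
#'   Defaults to 4.97, the standard alkanethiol-on-Au(111) spacing.
#' @param terminal_z Height of the terminal heavy atoms (Angstrom); a scalar
#'   or one value per chain.
#'
#' @return An object of class `ps_surface`: list with `ligand`,
#'   `chain_positions` (tibble `chain`, `x`, `y`), `terminal_z`, `z0`,
#'   `lattice_constant`, `nx`, `ny`.
#'
#' @examples
#' surf <- build_sam_surface(20, 16, "CH3")
#' surf$z0
#' nrow(surf$chain_positions)  # 320 chains
#' @export
build_sam_surface <- function(nx, ny, ligand = c("CH3", "OH"),
                              lattice_constant = 4.97, terminal_z = 15) {
  ligand <- match.arg(ligand)
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 1 || ny < 1) {
    abort("Surface dimensions nx and ny must be positive integers.")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (lattice_constant <= 0) abort("lattice_constant must be positive.")
  n_chain <- nx * ny
  terminal_z <- rep_len(terminal_z, n_chain)

  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  pos <- tibble(
    chain = seq_len(n_chain),
    x = lattice_constant * (ij$i + 0.5 * (ij$j %% 2L)),
    y = lattice_constant * (sqrt(3) / 2) * ij$j
  )
  structure(
    list(
      ligand = ligand,
      chain_positions = pos,
      terminal_z = terminal_z,
      z0 = mean(terminal_z),
      lattice_constant = lattice_constant,
      nx = nx, ny = ny
    ),
    class = "ps_surface"
  )
}

#' @export
print.ps_surface <- function(x, ...) {
  cat("<ps_surface> SAM", tolower(x$ligand), ": ",
      x$nx, " x ", x$ny, " = ", x$nx * x$ny,
      " chains, a = ", x$lattice_constant,
      " A, z0 = ", format(x$z0, digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Atom-level view of a SAM surface
#'
#' Expands a `ps_surface` into one row per terminal-group atom, with the
#' same nonbonded parameter columns as a peptide topology, for use in
#' hydrogen-bond and MM-PBSA calculations.  CH3 surfaces contribute one
#' neutral united carbon per chain; OH surfaces an O-H pair (H pointing away
#' from the substrate).
#'
#' @param surface A `ps_surface`.
#' @return A tibble with columns `chain`, `name`, `element`, `donor`,
#'   `acceptor`, `charge`, `sigma`, `epsilon`, `mass`, `x`, `y`, `z`.
#' @export
surface_atoms <- function(surface) {
  stopifnot(inherits(surface, "ps_surface"))
  par <- .surface_params[[surface$ligand]]
  pos <- surface$chain_positions
  out <- tidyr::crossing(chain = pos$chain, name = par$name)
  out <- left_join(out, par, by = "name")
  out <- left_join(out, pos, by = "chain")
  out$z <- surface$terminal_z[out$chain] + out$dz
  arrange(select(out, -"dz"), .data$chain, desc(.data$name))
}
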