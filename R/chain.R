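# Standard backbone internal coordinates (Engh-Huber-like averages).
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_n_h = 1.010, b_ca_cb = 1.530,
  a_c_n_ca = 121.7 * pi / 180, a_n_ca_c = 111.2 * pi / 180,
  a_ca_c_n = 116.2 * pi / 180, a_ca_c_o = 120.5 * pi / 180,
  a_c_n_h = 119.5 * pi / 180, a_n_ca_cb = 110.5 * pi / 180,
  t_omega = pi, t_cb = -122.6 * pi / 180
)

#' Ideal backbone dihedral angles
#'
#' Reference (phi, psi) pairs in radians: alpha-helix (-57, -47) degrees and
#' ideal beta-strand (-135.2, +135.2) degrees, i.e. (-2.36, +2.36) rad, the
#' strand references of the dihedral offset function.
#'
#' @param state `"helix"` or `"strand"`.
#' @return Named numeric vector `c(phi = , psi = )` in radians.
#' @export
ideal_dihedrals <- function(state = c("helix", "strand")) {
  state <- match.arg(state)
  switch(state,
    helix = c(phi = -57 * pi / 180, psi = -47 * pi / 180),
    strand = c(phi = -2.36, psi = 2.36)
  )
}

#' Build a peptide chain from backbone dihedrals
#'
#' Constructs full backbone coordinates (N, amide H, CA, C, carbonyl O per
#' residue, plus a CB sidechain pseudo-atom for non-glycine residues) by
#' sequential internal-coordinate placement with standard bond lengths and
#' angles and trans (omega = 180 degrees) peptide bonds.  The torsions of
#' the built chain reproduce the requested (phi, psi) exactly (to floating
#' point): phi(i) enters as the torsion C(i-1)-N(i)-CA(i)-C(i) and psi(i) as
#' N(i)-CA(i)-C(i)-N(i+1); the last residue's psi orients its carbonyl.
#'
#' @param sequence Character string of one-letter codes, or a `ps_topology`.
#' @param phi,psi Numeric vectors of backbone dihedrals in radians, one per
#'   residue (recycled if length 1).
#'
#' @return A list with `coords` (n_atoms x 3 matrix, Angstrom, rows aligned
#'   with the topology atom table) and `topology` (`ps_topology`).
#'
#' @examples
#' hel <- ideal_dihedrals("helix")
#' ch <- build_chain_from_dihedrals("AAAAAAAAAA", hel["phi"], hel["psi"])
#' dim(ch$coords)
#' @export
build_chain_from_dihedrals <- function(sequence, phi, psi) {
  top <- if (inherits(sequence, "ps_topology")) sequence else {
    if (!is.character(sequence) || !nzchar(sequence)) {
      abort("sequence must be a nonempty character string or ps_topology.")
    }
    build_topology(sequence)
  }
  nres <- nrow(top$residues)
  phi <- rep_len(as.numeric(phi), nres)
  psi <- rep_len(as.numeric(psi), nres)
  if (any(!is.finite(phi)) || any(!is.finite(psi))) {
    abort("Dihedral angles must be finite.")
  }

  g <- .bb
  n_xyz <- matrix(NA_real_, nres, 3)
  ca_xyz <- matrix(NA_real_, nres, 3)
  c_xyz <- matrix(NA_real_, nres, 3)
  o_xyz <- matrix(NA_real_, nres, 3)
  h_xyz <- matrix(NA_real_, nres, 3)
  cb_xyz <- matrix(NA_real_, nres, 3)

  # first residue in the xy-plane
  n_xyz[1, ] <- c(0, 0, 0)
  ca_xyz[1, ] <- c(g$b_n_ca, 0, 0)
  th <- pi - g$a_n_ca_c
  c_xyz[1, ] <- ca_xyz[1, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  h_xyz[1, ] <- place_atom(c_xyz[1, ], ca_xyz[1, ], n_xyz[1, ],
                           g$b_n_h, g$a_c_n_h, pi)

  for (i in seq_len(nres)) {
    if (i > 1L) {
      n_xyz[i, ] <- place_atom(n_xyz[i - 1, ], ca_xyz[i - 1, ], c_xyz[i - 1, ],
                               g$b_c_n, g$a_ca_c_n, psi[i - 1])
      ca_xyz[i, ] <- place_atom(ca_xyz[i - 1, ], c_xyz[i - 1, ], n_xyz[i, ],
                                g$b_n_ca, g$a_c_n_ca, g$t_omega)
      c_xyz[i, ] <- place_atom(c_xyz[i - 1, ], n_xyz[i, ], ca_xyz[i, ],
                               g$b_ca_c, g$a_n_ca_c, phi[i])
      h_xyz[i, ] <- place_atom(ca_xyz[i - 1, ], c_xyz[i - 1, ], n_xyz[i, ],
                               g$b_n_h, g$a_c_n_h, 0)
    }
    o_xyz[i, ] <- place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                             g$b_c_o, g$a_ca_c_o, wrap_angle(psi[i] + pi))
    if (top$residues$code[i] != "G") {
      cb_xyz[i, ] <- place_atom(c_xyz[i, ], n_xyz[i, ], ca_xyz[i, ],
                                g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
    }
  }

  coords <- matrix(NA_real_, nrow(top$atoms), 3)
  at <- top$atoms
  ridx <- match(at$author_index, top$residues$author_index)
  coords[at$name == "N", ] <- n_xyz[ridx[at$name == "N"], ]
  coords[at$name == "H", ] <- h_xyz[ridx[at$name == "H"], ]
  coords[at$name == "CA", ] <- ca_xyz[ridx[at$name == "CA"], ]
  coords[at$name == "C", ] <- c_xyz[ridx[at$name == "C"], ]
  coords[at$name == "O", ] <- o_xyz[ridx[at$name == "O"], ]
  coords[at$name == "CB", ] <- cb_xyz[ridx[at$name == "CB"], ]
  list(coords = coords, topology = top)
}

#' Measure backbone dihedrals of a coordinate set
#'
#' Computes phi(i) = torsion C(i-1)-N(i)-CA(i)-C(i) and psi(i) =
#' torsion N(i)-CA(i)-C(i)-N(i+1), IUPAC convention, radians.  phi of the
#' first residue and psi of the last are `NA`.
#'
#' @param coords n_atoms x 3 coordinate matrix aligned with `topology`.
#' @param topology A `ps_topology`.
#' @return Tibble with columns `author_index`, `phi`, `psi`.
#' @export
measure_dihedrals <- function(coords, topology) {
  at <- topology$atoms
  res_idx <- topology$residues$author_index
  nres <- length(res_idx)
  pick <- function(name) {
    coords[match(paste(res_idx, name), paste(at$author_index, at$name)), ,
           drop = FALSE]
  }
  nm <- pick("N"); cam <- pick("CA"); cm <- pick("C")
  phi <- rep(NA_real_, nres)
  psi <- rep(NA_real_, nres)
  for (i in seq_len(nres)) {
    if (i > 1L) {
      phi[i] <- torsion_angle(cm[i - 1, ], nm[i, ], cam[i, ], cm[i, ])
    }
    if (i < nres) {
      psi[i] <- torsion_angle(nm[i, ], cam[i, ], cm[i, ], nm[i + 1, ])
    }
  }
  tibble(author_index = res_idx, phi = phi, psi = psi)
}
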