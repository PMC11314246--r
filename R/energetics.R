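COULOMB_KCAL <- 332.06  # kcal A / (mol e^2)

# Bondi-type van der Waals radii (Angstrom) for SASA, by element; the
# sidechain pseudo-atom (CB) gets an enlarged radius.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Default SASA radii for an atom table
#'
#' @param atoms Tibble with columns `element` and `name`.
#' @param cb_radius Radius for the CB sidechain pseudo-atom.
#' @return Numeric vector of radii, Angstrom.
#' @export
sasa_radii <- function(atoms, cb_radius = 2.2) {
  r <- unname(.vdw_radii[atoms$element])
  if (anyNA(r)) abort("Unknown element in atom table; supply radii explicitly.")
  r[atoms$name == "CB"] <- cb_radius
  r
}

# Deterministic quasi-uniform sphere point set (Fibonacci / golden-spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom and total SASA by sampling a deterministic
#' (golden-spiral) point set on each atom's solvent-expanded sphere (radius
#' `r_i + probe`) and counting the points not buried inside any neighbour's
#' expanded sphere.
#'
#' @param coords `n x 3` coordinate matrix, Angstrom.
#' @param radii Per-atom radii, Angstrom.
#' @param probe Probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere points per atom (>= 92).
#'
#' @return A list with `total` (Angstrom^2) and `per_atom` (numeric vector
#'   summing to the total).
#'
#' @examples
#' shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.9)$total  # ~ 4*pi*3.3^2
#' @export
shrake_rupley_sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) abort("Radii must be positive.")
  if (n_points < 92) abort("n_points must be at least 92 for usable accuracy.")
  pts <- fibonacci_sphere(n_points)
  rext <- radii + probe
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    p <- sweep(pts * rext[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in neigh) {
      dj2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      exposed <- exposed & dj2 > rext[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * rext[i]^2 * mean(exposed)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation energy from SASA
#'
#' `G_SA = gamma * SASA` with surface tension `gamma` in kcal/mol/A^2
#' (default 0.005).
#'
#' @param sasa Solvent-accessible surface area, Angstrom^2.
#' @param gamma Surface tension coefficient.
#' @return Energy, kcal/mol.
#' @export
nonpolar_solvation <- function(sasa, gamma = 0.005) {
  if (any(sasa < 0)) abort("SASA must be non-negative.")
  gamma * sasa
}

#' Inter-group molecular-mechanics energy
#'
#' 12-6 Lennard-Jones plus Coulomb energy summed over all pairs between two
#' atom groups, with Lorentz-Berthelot combining rules and no cutoff
#' (intended for finite toy systems).
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices.
#' @param params_a,params_b Tibbles with columns `charge`, `sigma`,
#'   `epsilon` aligned with the coordinate rows.
#' @return A one-row tibble with `evdw` and `eelec`, kcal/mol.
#'
#' @examples
#' a <- tibble::tibble(charge = 1, sigma = 3, epsilon = 0.1)
#' b <- tibble::tibble(charge = -1, sigma = 3, epsilon = 0.1)
#' mm_energy(matrix(0, 1, 3), a, matrix(c(3.3206, 0, 0), 1, 3), b)
#' @export
mm_energy <- function(coords_a, params_a, coords_b, params_b) {
  coords_a <- matrix(as.numeric(coords_a), ncol = 3)
  coords_b <- matrix(as.numeric(coords_b), ncol = 3)
  need <- c("charge", "sigma", "epsilon")
  if (!all(need %in% names(params_a)) || !all(need %in% names(params_b))) {
    abort("params must contain charge, sigma and epsilon columns.")
  }
  if (nrow(coords_a) != nrow(params_a) || nrow(coords_b) != nrow(params_b)) {
    abort("Coordinate and parameter tables have mismatched lengths.")
  }
  # pairwise distances a x b
  r2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), "+") -
    2 * coords_a %*% t(coords_b)
  r <- sqrt(pmax(r2, 1e-12))
  sig <- outer(params_a$sigma, params_b$sigma, "+") / 2
  eps <- sqrt(outer(params_a$epsilon, params_b$epsilon))
  sr6 <- (sig / r)^6
  evdw <- sum(4 * eps * (sr6^2 - sr6))
  eelec <- COULOMB_KCAL * sum(outer(params_a$charge, params_b$charge) / r)
  tibble(evdw = evdw, eelec = eelec)
}

#' Born-style polar solvation backend
#'
#' Returns a pluggable polar-solvation estimator using a generalised-Born
#' style pairwise formula with the atomic radii as effective Born radii, for
#' use as `polar_backend` in [adsorption_free_energy()].  This is a crude
#' stand-in for a numerical Poisson-Boltzmann solver and is off by default.
#'
#' @param epsilon_in,epsilon_out Internal and external dielectric constants.
#' @return A function `(coords, params) -> G_PB` (kcal/mol); `params` must
#'   carry `charge` and `sigma` columns (Born radii taken as `sigma / 2`).
#' @export
born_polar_backend <- function(epsilon_in = 1, epsilon_out = 80) {
  pref <- -COULOMB_KCAL / 2 * (1 / epsilon_in - 1 / epsilon_out)
  function(coords, params) {
    coords <- matrix(as.numeric(coords), ncol = 3)
    q <- params$charge
    rb <- pmax(params$sigma / 2, 0.5)
    d2 <- as.matrix(stats::dist(coords))^2
    bb <- outer(rb, rb)
    fgb <- sqrt(d2 + bb * exp(-d2 / (4 * bb)))
    pref * sum(outer(q, q) / fgb)
  }
}

#' Single-trajectory MM-PBSA adsorption free energy
#'
#' Estimates the adsorption free energy
#' `dG_ads = G_complex - G_protein - G_surface` frame by frame from a single
#' complex trajectory, with `G = E_MM + G_PB + G_SA`.  Because complex,
#' protein and surface coordinates come from the same frames, the internal
#' (bonded) energies cancel identically and `dE_MM` reduces to the
#' inter-group Lennard-Jones and Coulomb energy.  The nonpolar solvation
#' difference is `gamma * (SASA_complex - SASA_protein - SASA_surface)`;
#' the polar term comes from `polar_backend` (default: none, contributing
#' zero).  Conformational entropy is neglected.
#'
#' @param trajectory A `ps_trajectory` with a surface.
#' @param polar_backend Optional function `(coords, params) -> kcal/mol`
#'   applied to complex, protein and surface coordinates per frame (see
#'   [born_polar_backend()]).
#' @param gamma Surface tension for the nonpolar term, kcal/mol/A^2.
#' @param probe SASA probe radius, Angstrom.
#' @param n_points SASA sphere points per atom.
#' @param stride Use every `stride`-th frame.
#'
#' @return An object of class `ps_mmpbsa`: list with `frames` (tibble:
#'   `frame`, `d_evdw`, `d_eelec`, `d_emm`, `d_gsa`, `d_gpb`, `d_gsolv`,
#'   `dg_ads`; `d_eint` is identically zero and included for bookkeeping)
#'   and the call parameters.  `tidy()` returns the frame table;
#'   `glance()` the means with standard errors of the mean.
#' @export
adsorption_free_energy <- function(trajectory, polar_backend = NULL,
                                   gamma = 0.005, probe = 1.4,
                                   n_points = 240, stride = 1) {
  require_surface(trajectory)
  top <- trajectory$topology
  prot_par <- top$atoms
  surf_par <- surface_atoms(trajectory$surface)
  surf_xyz <- as.matrix(surf_par[, c("x", "y", "z")])
  prot_radii <- sasa_radii(prot_par)
  surf_radii <- unname(.vdw_radii[surf_par$element])
  frames <- seq(1, n_frames(trajectory), by = stride)

  # the surface is rigid: its isolated SASA and polar term are constant
  sasa_surf <- shrake_rupley_sasa(surf_xyz, surf_radii, probe, n_points)$total
  gpb_surf <- if (is.null(polar_backend)) 0 else {
    polar_backend(surf_xyz, surf_par)
  }

  all_par <- bind_rows(
    select(prot_par, "charge", "sigma", "epsilon"),
    select(surf_par, "charge", "sigma", "epsilon")
  )
  all_radii <- c(prot_radii, surf_radii)

  rows <- purrr::map_dfr(frames, function(f) {
    pxyz <- frame_coords(trajectory, f)
    mm <- mm_energy(pxyz, prot_par, surf_xyz, surf_par)
    cxyz <- rbind(pxyz, surf_xyz)
    sasa_c <- shrake_rupley_sasa(cxyz, all_radii, probe, n_points)$total
    sasa_p <- shrake_rupley_sasa(pxyz, prot_radii, probe, n_points)$total
    d_gsa <- nonpolar_solvation(sasa_c, gamma) -
      nonpolar_solvation(sasa_p, gamma) -
      nonpolar_solvation(sasa_surf, gamma)
    d_gpb <- if (is.null(polar_backend)) 0 else {
      polar_backend(cxyz, all_par) - polar_backend(pxyz, prot_par) - gpb_surf
    }
    tibble(
      frame = f,
      d_eint = 0,
      d_evdw = mm$evdw, d_eelec = mm$eelec,
      d_emm = mm$evdw + mm$eelec,
      d_gsa = d_gsa, d_gpb = d_gpb, d_gsolv = d_gsa + d_gpb,
      dg_ads = mm$evdw + mm$eelec + d_gsa + d_gpb
    )
  })
  structure(
    list(frames = rows, gamma = gamma, probe = probe, n_points = n_points,
         polar = !is.null(polar_backend)),
    class = "ps_mmpbsa"
  )
}

#' @export
tidy.ps_mmpbsa <- function(x, ...) x$frames

#' @export
glance.ps_mmpbsa <- function(x, ...) {
  fr <- x$frames
  n <- nrow(fr)
  se <- function(v) if (n > 1) sd(v) / sqrt(n) else NA_real_
  tibble(
    n_frames = n,
    dg_ads = mean(fr$dg_ads), dg_ads_se = se(fr$dg_ads),
    d_emm = mean(fr$d_emm), d_emm_se = se(fr$d_emm),
    d_gsolv = mean(fr$d_gsolv), d_gsolv_se = se(fr$d_gsolv)
  )
}

#' @export
print.ps_mmpbsa <- function(x, ...) {
  g <- glance(x)
  cat("<ps_mmpbsa> ", g$n_frames, " frames\n", sep = "")
  cat(sprintf("  dG_ads = %.2f +/- %.2f kcal/mol (dE_MM %.2f, dG_solv %.2f)\n",
              g$dg_ads, g$dg_ads_se %||% NA, g$d_emm, g$d_gsolv))
  invisible(x)
}
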