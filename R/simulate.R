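#' Simulate a two-state adsorption/desorption height track
#'
#' Runs the two-state Markov chain of the scenario (adsorbed <-> desorbed
#' with per-frame probabilities `k_ads`, `k_des`) and emits the peptide
#' reference-point height above the surface plane with Gaussian noise.
#' The stationary adsorbed fraction of the chain is
#' `k_ads / (k_ads + k_des)`.
#'
#' @param spec A `ps_scenario`.
#' @param seed Integer seed; defaults to the seed recorded in `spec`.
#'
#' @return A tibble with columns `frame`, `adsorbed` (logical) and `z`
#'   (height of the reference point above the plane, Angstrom).
#'
#' @examples
#' trk <- simulate_adsorption_track(scenario_spec(k_ads = 0.2, k_des = 0.05,
#'                                                n_frames = 500))
#' mean(trk$adsorbed)
#' @export
simulate_adsorption_track <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "ps_scenario"))
  set.seed(seed)
  n <- spec$n_frames
  adsorbed <- logical(n)
  state <- spec$start_adsorbed
  u <- runif(n)
  for (i in seq_len(n)) {
    adsorbed[i] <- state
    state <- if (state) u[i] >= spec$k_des else u[i] < spec$k_ads
  }
  z <- ifelse(adsorbed, spec$z_adsorbed, spec$z_bulk) +
    rnorm(n, sd = spec$noise_sd)
  tibble(frame = seq_len(n), adsorbed = adsorbed, z = z)
}

# Sample per-residue (phi, psi) targets and state labels for one frame.
sample_frame_dihedrals <- function(spec, residues) {
  nres <- nrow(residues)
  state <- rep("coil", nres)
  seg <- spec$segments
  for (k in seq_len(nrow(seg))) {
    in_seg <- residues$author_index >= seg$from[k] &
      residues$author_index <= seg$to[k]
    hit <- in_seg & (runif(nres) < seg$propensity[k])
    state[hit] <- seg$state[k]
  }
  phi <- numeric(nres)
  psi <- numeric(nres)
  hel <- ideal_dihedrals("helix")
  strd <- ideal_dihedrals("strand")
  for (i in seq_len(nres)) {
    if (state[i] == "coil") {
      # 50/50 mixture of broad basins around the helix and strand ideals
      ref <- if (runif(1) < 0.5) hel else strd
      sd_i <- spec$coil_sd
    } else {
      ref <- if (state[i] == "helix") hel else strd
      sd_i <- spec$jitter_sd
    }
    phi[i] <- wrap_angle(ref[["phi"]] + rnorm(1, sd = sd_i))
    psi[i] <- wrap_angle(ref[["psi"]] + rnorm(1, sd = sd_i))
  }
  list(phi = phi, psi = psi, state = state)
}

#' Generate a synthetic peptide-on-surface trajectory
#'
#' Builds one frame per time step: backbone dihedrals are sampled per
#' residue according to the scenario's segment propensities (ideal helix or
#' strand angles with narrow wrapped-Gaussian jitter; coil from a 50/50
#' mixture of broad basins around both ideals), the chain is rebuilt from
#' those dihedrals, and rigidly placed above the surface at the height given
#' by the simulated adsorption track, with a random in-plane rotation and
#' offset.  In adsorbed frames the chain is oriented flat on the surface
#' (its smallest gyration axis along the surface normal), the geometry a
#' strongly adsorbed disordered peptide adopts; desorbed frames keep a
#' random in-plane pose.  Frames are then shifted vertically so the
#' geometry realises the simulated two-state truth: in adsorbed frames the
#' lowest heavy atom lies inside the residue-surface contact band
#' (between `min_clearance` and just inside `contact_cutoff`), in desorbed
#' frames it stays at least 1 Angstrom clear of the cutoff.  Shifted frames
#' are flagged `lifted` in the ground truth.
#'
#' @param spec A `ps_scenario`.
#' @param surface A `ps_surface`, or `NULL` for a bulk (no-surface)
#'   trajectory.
#' @param sequence Sequence tibble; defaults to [ab1040_sequence()].
#' @param seed Integer seed; defaults to the seed recorded in the scenario.
#' @param contact_cutoff Cutoff used to record ground-truth residue-surface
#'   contacts (Angstrom).
#'
#' @return A list with elements
#' \describe{
#'   \item{trajectory}{a `ps_trajectory`;}
#'   \item{truth}{a list with `frames` (tibble: `frame`, `adsorbed`,
#'     `com_z`, `lifted`), `states` (`n_res x n_frames` character matrix of
#'     designed per-residue states), `contacts` (tibble: `author_index`,
#'     `contact_rate`), and `seed`.}
#' }
#'
#' @examples
#' surf <- build_sam_surface(8, 8, "CH3")
#' out <- generate_trajectory(scenario_preset("samch3-like", n_frames = 10),
#'                            surf)
#' out$trajectory
#' @export
generate_trajectory <- function(spec, surface = NULL,
                                sequence = ab1040_sequence(),
                                seed = spec$seed,
                                contact_cutoff = 3.5) {
  stopifnot(inherits(spec, "ps_scenario"))
  track <- simulate_adsorption_track(spec, seed = seed)
  # track consumed the seed stream; continue on the same stream
  top <- build_topology(sequence)
  nres <- nrow(top$residues)
  na <- nrow(top$atoms)
  nf <- spec$n_frames
  heavy <- top$atoms$element != "H"
  masses <- top$atoms$mass

  has_surface <- !is.null(surface)
  z0 <- if (has_surface) surface$z0 else 0
  centre <- if (has_surface) {
    c(mean(range(surface$chain_positions$x)),
      mean(range(surface$chain_positions$y)))
  } else {
    c(0, 0)
  }
  span <- if (has_surface) {
    max(1, min(diff(range(surface$chain_positions$x)),
               diff(range(surface$chain_positions$y))) / 4)
  } else {
    0
  }
  tilt <- spec$tilt_deg * pi / 180

  coords <- array(NA_real_, dim = c(na, 3, nf))
  states <- matrix(NA_character_, nres, nf,
                   dimnames = list(top$residues$author_index, NULL))
  lifted <- logical(nf)
  contact_hits <- matrix(FALSE, nres, nf)
  res_of_atom <- match(top$atoms$author_index, top$residues$author_index)

  for (f in seq_len(nf)) {
    smp <- sample_frame_dihedrals(spec, top$residues)
    states[, f] <- smp$state
    ch <- build_chain_from_dihedrals(top, smp$phi, smp$psi)
    xyz <- ch$coords
    xyz <- sweep(xyz, 2, colMeans(xyz))  # centre at origin
    if (has_surface && track$adsorbed[f]) {
      # adsorbed peptides lie flat: smallest principal axis along z
      ev <- eigen(crossprod(xyz[heavy, , drop = FALSE]), symmetric = TRUE)
      rot <- ev$vectors  # columns ordered by decreasing variance
      if (det(rot) < 0) rot[, 3] <- -rot[, 3]
      xyz <- xyz %*% rot
    }
    if (tilt != 0) {
      ct <- cos(tilt); st <- sin(tilt)
      xyz <- xyz %*% matrix(c(ct, 0, st, 0, 1, 0, -st, 0, ct), 3, 3)
    }
    xyz <- xyz %*% rot_z(runif(1, 0, 2 * pi))
    offs <- c(centre + runif(2, -span, span), 0)
    com_z_target <- z0 + track$z[f]
    com_z_now <- weighted.mean(xyz[, 3], masses)
    xyz <- sweep(xyz, 2, offs + c(0, 0, com_z_target - com_z_now), FUN = "+")
    if (has_surface) {
      # realise the two-state ground truth geometrically: adsorbed frames
      # keep their lowest heavy atom inside the contact band, desorbed
      # frames stay clear of it
      clearance <- spec$min_clearance %||% 2.5
      band_max <- contact_cutoff - 0.1
      minz <- min(xyz[heavy, 3]) - z0
      target <- if (track$adsorbed[f]) {
        min(max(minz, clearance), band_max)
      } else {
        max(minz, contact_cutoff + 1)
      }
      if (abs(target - minz) > 1e-12) {
        xyz[, 3] <- xyz[, 3] + (target - minz)
        lifted[f] <- TRUE
      }
    }
    coords[, , f] <- xyz
    if (has_surface) {
      zmin <- tapply(xyz[heavy, 3], res_of_atom[heavy], min)
      contact_hits[, f] <- (zmin - z0) <= contact_cutoff
    }
  }
  if (any(lifted)) {
    inform(paste0(sum(lifted), " frame(s) shifted vertically to keep the ",
                  "peptide above the surface plane."))
  }

  com_z <- apply(coords, 3, function(m) weighted.mean(m[, 3], masses))
  truth <- list(
    frames = tibble(
      frame = seq_len(nf),
      adsorbed = if (has_surface) track$adsorbed else NA,
      com_z = com_z - z0,
      lifted = lifted
    ),
    states = states,
    contacts = tibble(
      author_index = top$residues$author_index,
      contact_rate = if (has_surface) rowMeans(contact_hits) else NA_real_
    ),
    seed = as.integer(seed)
  )
  list(
    trajectory = ps_trajectory(top, coords, surface = surface,
                               frame_spacing = spec$frame_spacing),
    truth = truth
  )
}
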