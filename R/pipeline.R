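#' Pipeline configuration
#'
#' Assembles and validates the options of [run_pipeline()].  Defaults
#' reproduce the standard analysis parameters: 3.5 Angstrom residue-surface
#' contact cutoff, 3 Angstrom RMSD cluster cutoff, 300-440 K REST ladder.
#'
#' @param preset Scenario preset name ([scenario_preset()]).
#' @param n_frames Frames to generate.
#' @param seed Integer seed for every stochastic stage.
#' @param surface_nx,surface_ny SAM lattice dimensions.
#' @param contact_cutoff Residue-surface contact cutoff, Angstrom.
#' @param cluster_cutoff RMSD cluster cutoff, Angstrom.
#' @param ladder_T0,ladder_Tmax,ladder_n REST ladder parameters.
#' @param stages Character vector of stages to run, a subset of
#'   `c("adsorption", "conformation", "cluster", "energy", "ladder")`.
#' @param energy_frames Number of (evenly strided) frames entering the
#'   MM-PBSA stage.
#' @param output_dir Directory for TSV outputs, or `NULL` to skip writing.
#'
#' @return A validated list of class `ps_config`.
#' @export
run_config <- function(preset = "samch3-like", n_frames = 200, seed = 1,
                       surface_nx = 8, surface_ny = 8,
                       contact_cutoff = 3.5, cluster_cutoff = 3.0,
                       ladder_T0 = 300, ladder_Tmax = 440, ladder_n = 12,
                       stages = c("adsorption", "conformation", "cluster",
                                  "energy", "ladder"),
                       energy_frames = 10,
                       output_dir = NULL) {
  check_pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      abort(paste0("Invalid value for `", field, "`: must be a positive number."))
    }
  }
  check_pos(contact_cutoff, "contact_cutoff")
  check_pos(cluster_cutoff, "cluster_cutoff")
  check_pos(n_frames, "n_frames")
  check_pos(surface_nx, "surface_nx")
  check_pos(surface_ny, "surface_ny")
  bad <- setdiff(stages, c("adsorption", "conformation", "cluster",
                           "energy", "ladder"))
  if (length(bad)) {
    abort(paste0("Invalid value for `stages`: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(preset = preset, n_frames = as.integer(n_frames),
         seed = as.integer(seed),
         surface_nx = surface_nx, surface_ny = surface_ny,
         contact_cutoff = contact_cutoff, cluster_cutoff = cluster_cutoff,
         ladder_T0 = ladder_T0, ladder_Tmax = ladder_Tmax,
         ladder_n = ladder_n, stages = stages,
         energy_frames = energy_frames, output_dir = output_dir),
    class = "ps_config"
  )
}

#' Run the full analysis pipeline on a synthetic trajectory
#'
#' Generates a synthetic peptide-on-surface trajectory from the configured
#' preset and runs the toggled analysis stages in order: adsorption
#' (separation series, residue profiles, contact probabilities and
#' contact clusters), conformation (per-frame helical hydrogen bonds,
#' dihedral offset, gyration; secondary-structure propensities),
#' conformational clustering, MM-PBSA energetics, and the REST ladder.
#' All analyses operate on the single generated (beta = 1 equivalent)
#' trajectory.  When `output_dir` is set, every table is written as TSV
#' with a provenance header recording the configuration.
#'
#' @param config A `ps_config` from [run_config()].
#' @return A named list of stage results (invisibly contains the trajectory
#'   and ground truth as well).
#'
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(n_frames = 20, energy_frames = 2))
#' names(res)
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "ps_config"))
  prov <- config[c("preset", "n_frames", "seed", "contact_cutoff",
                   "cluster_cutoff")]
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(tbl, file) {
    if (!is.null(out_dir)) {
      write_tsv_provenance(tbl, file.path(out_dir, file), prov)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  results <- list(config = config)
  with_surface <- config$preset != "bulk"
  surface <- if (with_surface) {
    build_sam_surface(config$surface_nx, config$surface_ny,
                      ligand = if (config$preset == "samoh-like") "OH" else "CH3")
  } else {
    NULL
  }
  gen <- stage("generate", generate_trajectory(
    scenario_preset(config$preset, n_frames = config$n_frames,
                    seed = config$seed),
    surface
  ))
  traj <- gen$trajectory
  results$trajectory <- traj
  results$truth <- gen$truth

  if ("adsorption" %in% config$stages && with_surface) {
    results$separation <- stage("adsorption", com_separation(traj))
    emit(results$separation$series, "separation_series.tsv")
    emit(results$separation$histogram, "separation_histogram.tsv")
    results$profile <- stage("adsorption", residue_surface_profile(traj))
    emit(results$profile, "residue_profile.tsv")
    results$contacts <- stage(
      "adsorption", contact_probability(traj, config$contact_cutoff)
    )
    emit(results$contacts$probability, "contact_probability.tsv")
    results$contact_clusters <- stage(
      "adsorption", cluster_contacts(results$contacts)
    )
    emit(results$contact_clusters, "contact_clusters.tsv")
    if (surface$ligand == "OH") {
      results$hbonds <- stage("adsorption", surface_hbonds(traj))
      emit(results$hbonds, "surface_hbonds.tsv")
    }
  }
  if ("conformation" %in% config$stages) {
    results$metrics <- stage("conformation", conformation_metrics(traj))
    emit(results$metrics, "conformation_metrics.tsv")
    results$sstruct <- stage("conformation", assign_secondary_structure(traj))
    emit(results$sstruct$propensity, "ss_propensity.tsv")
  }
  if ("cluster" %in% config$stages) {
    results$clusters <- stage(
      "cluster", daura_cluster(traj, cutoff = config$cluster_cutoff)
    )
    emit(tidy(results$clusters), "conformation_clusters.tsv")
  }
  if ("energy" %in% config$stages && with_surface) {
    stride <- max(1L, floor(n_frames(traj) / config$energy_frames))
    results$energy <- stage(
      "energy", adsorption_free_energy(traj, stride = stride)
    )
    emit(glance(results$energy), "adsorption_energy.tsv")
  }
  if ("ladder" %in% config$stages) {
    results$ladder <- stage("ladder", build_ladder(
      config$ladder_T0, config$ladder_Tmax, config$ladder_n
    ))
    emit(results$ladder, "rest_ladder.tsv")
  }
  results
}
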