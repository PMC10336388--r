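#' Fit the full set of behaviour models
#'
#' Fits the inference suite to a per-fish behaviour table: Poisson GLMM for
#' the number of inspections; Gamma GLMMs for mean event duration and
#' minimum inspection distance; Beta GLMMs for the proportion of time spent
#' inspecting and for the mean inspection distance (scaled by the 30 cm
#' zone radius, since the distribution is bounded there); and a Beta GLMM
#' with phase and group-size-by-phase interactions for refuge use. All
#' models carry water temperature, mean fish length and a trial random
#' intercept.
#'
#' @param behav Behaviour table from [behavior_table()] (one row per fish,
#'   with trial covariates joined).
#' @param mcmc MCMC settings passed to [fit_glmm()].
#' @param zone_radius_cm Inspection-zone radius used to scale mean
#'   distance into (0, 1). Default 30.
#' @return A named list of `shoal_glmm` fits: `number_inspections`,
#'   `duration_inspections`, `prop_time_inspecting`, `minimum_distance`,
#'   `mean_distance`, `refuge`.
#' @export
analyze_behavior <- function(behav, mcmc = list(), zone_radius_cm = 30) {
  b <- behav
  b$mean_distance_scaled <- b$mean_inspection_distance_cm / zone_radius_cm
  refuge_long <- b |>
    tidyr::pivot_longer(
      cols = c("refuge_prop_before", "refuge_prop_during"),
      names_to = "phase", names_prefix = "refuge_prop_",
      values_to = "refuge_prop"
    )
  list(
    number_inspections = fit_glmm(
      b, model_spec("n_inspections", "poisson"), mcmc
    ),
    duration_inspections = fit_glmm(
      b, model_spec("mean_event_duration_s", "gamma"), mcmc
    ),
    prop_time_inspecting = fit_glmm(
      b, model_spec("prop_time_inspecting", "beta", context = "inspection"),
      mcmc
    ),
    minimum_distance = fit_glmm(
      b, model_spec("min_inspection_distance_cm", "gamma"), mcmc
    ),
    mean_distance = fit_glmm(
      b, model_spec("mean_distance_scaled", "beta", context = "inspection"),
      mcmc
    ),
    refuge = fit_glmm(
      refuge_long,
      model_spec("refuge_prop", "beta", context = "refuge",
                 include_phase = TRUE),
      mcmc
    )
  )
}

#' Contrast tables for a list of fitted behaviour models
#'
#' Runs [posterior_summary()] on each fit and binds the results, scaling
#' the mean-distance model's response-scale columns back to centimetres.
#'
#' @param fits List from [analyze_behavior()].
#' @param zone_radius_cm Zone radius used for the mean-distance scaling.
#' @return A tibble with a `response` column plus the
#'   [posterior_summary()] columns.
#' @export
summarize_all_models <- function(fits, zone_radius_cm = 30) {
  purrr::imap_dfr(fits, function(fit, name) {
    ps <- posterior_summary(fit)
    if (name == "mean_distance") {
      ps$hdi_lo <- ps$hdi_lo * zone_radius_cm
      ps$hdi_hi <- ps$hdi_hi * zone_radius_cm
      ps$marginal_effect <- ps$marginal_effect * zone_radius_cm
    }
    dplyr::bind_cols(tibble::tibble(response = name), ps)
  })
}

#' Refit the full pipeline on a deposited-data directory
#'
#' Entry point for reproducing the published analysis from the deposited
#' tracking data. Expects `meta.csv` (columns `trial_id`, `group_size`,
#' `temperature_c`, `mean_length_mm`, `screen_lift_frame`) and one
#' tracking CSV per trial under `tracks/<trial_id>.csv` in the tracker
#' dialect read by [read_tracking()].
#'
#' @param data_dir Directory holding `meta.csv` and `tracks/`.
#' @param arena An [arena_config()].
#' @param mcmc MCMC settings passed to every fit.
#' @return A list: `behavior` (per-fish table), `contrasts` (bound
#'   [posterior_summary()] tables), `inspectors` (the inspectors-per-
#'   inspection GLM coefficient table).
#' @export
refit_deposited <- function(data_dir, arena = arena_config(), mcmc = list()) {
  meta_path <- file.path(data_dir, "meta.csv")
  if (!file.exists(meta_path)) {
    stop("no meta.csv under ", data_dir,
         ": deposited tracking data not available")
  }
  meta <- read_trial_meta(meta_path)
  traj <- purrr::map_dfr(meta$trial_id, function(tr) {
    read_tracking(file.path(data_dir, "tracks", paste0(tr, ".csv")),
                  arena, trial_id = tr)
  })
  traj <- filter_tracks(traj, arena)
  lifts <- stats::setNames(meta$screen_lift_frame, meta$trial_id)
  traj <- label_phases(traj, lifts, arena)
  behav <- behavior_table(traj, meta, arena)
  fits <- analyze_behavior(behav, mcmc)
  events <- detect_inspections(traj, arena)
  list(
    behavior = behav,
    contrasts = summarize_all_models(fits),
    inspectors = fit_inspectors_glm(group_inspections(events), meta)
  )
}
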