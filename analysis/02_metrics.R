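#!/usr/bin/env Rscript

# Step 2: score the tracked trajectories. Reads the tracker-dialect CSVs
# written by step 1, applies the impossible-track filter (50 cm/s speed,
# 50 cm jump), labels the before/during phases from each trial's screen
# lift frame, and extracts: the five per-fish inspection metrics, refuge
# use per phase, merged group inspections, and the minute-level cohesion
# series (Voronoi density and chain-rule sub-group size).
#
# Run from the repository root:  Rscript analysis/02_metrics.R

suppressMessages(library(shoalspect))

arena <- arena_config()
meta <- read_trial_meta("results/meta.csv")
if (!dir.exists("scratch/tracks")) stop("run analysis/01_simulate.R first")

cat("Reading and filtering", nrow(meta), "trials...\n")
traj <- purrr::map_dfr(meta$trial_id, function(tr) {
  read_tracking(file.path("scratch/tracks", paste0(tr, ".csv")), arena,
                trial_id = tr)
})
traj <- filter_tracks(traj, arena)
traj <- label_phases(traj, setNames(meta$screen_lift_frame, meta$trial_id),
                     arena)

behav <- behavior_table(traj, meta, arena)
readr::write_csv(behav, "results/behavior.csv")
cat("Per-fish behaviour written to results/behavior.csv\n")
cat("Mean inspections per fish by group size:\n")
print(round(tapply(behav$n_inspections, behav$group_size, mean), 2))
cat("Mean refuge proportion (during) by group size:\n")
print(round(tapply(behav$refuge_prop_during, behav$group_size, mean), 3))

events <- detect_inspections(traj, arena)
gi <- group_inspections(events)
readr::write_csv(dplyr::select(gi, -"inspector_ids"),
                 "results/group_inspections.csv")
cat("\n", nrow(events), "inspection events merged into", nrow(gi),
    "group inspections; mean inspectors per inspection by group size:\n")
gi2 <- dplyr::inner_join(gi, meta[, c("trial_id", "group_size")], "trial_id")
print(round(tapply(gi2$n_inspectors, gi2$group_size, mean), 2))

cat("\nCohesion series (median Voronoi density, sub-group size)...\n")
dens <- density_series(traj, arena)
subg <- subgroup_series(traj, arena)
cohesion <- dplyr::left_join(dens, subg,
                             by = c("trial_id", "minute_index", "phase"))
readr::write_csv(cohesion, "results/cohesion.csv")
cat("Wrote results/cohesion.csv (",
    sum(!is.na(cohesion$median_density)), "density minutes,",
    sum(!is.na(cohesion$median_subgroup_size)), "sub-group minutes )\n")
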