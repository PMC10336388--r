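#' Detect predator-inspection events
#'
#' An inspection event is a maximal run of consecutive visible frames in the
#' "during" phase on which a fish is within the inspection zone (30 cm of
#' any part of the predator model by default). A gap — an invisible frame, a
#' missing frame, or a frame outside the zone — ends the event; runs
#' separated by no more than `gap_tolerance` frames are merged, with the
#' default 0 giving the strictest reading.
#'
#' @param traj A filtered, phase-labelled trajectory tibble.
#' @param arena An [arena_config()].
#' @param gap_tolerance Maximum number of missing/out-of-zone frames bridged
#'   within one event. Default 0.
#' @return A tibble of events: `trial_id`, `fish_id`, `start_frame`,
#'   `end_frame` (half-open), `duration_s`, `min_distance_cm`,
#'   `mean_distance_cm`.
#' @export
detect_inspections <- function(traj, arena, gap_tolerance = 0) {
  if (!"phase" %in% names(traj)) stop("trajectory must be phase-labelled first")
  d <- traj[!is.na(traj$phase) & traj$phase == "during" & traj$visible, ]
  empty <- tibble::tibble(
    trial_id = character(), fish_id = character(),
    start_frame = integer(), end_frame = integer(),
    duration_s = numeric(), min_distance_cm = numeric(),
    mean_distance_cm = numeric()
  )
  if (nrow(d) == 0) return(empty)
  d$dist <- distance_to_predator(d$x, d$y, arena)
  d <- d[d$dist <= arena$inspection_radius_cm, ]
  if (nrow(d) == 0) return(empty)
  d <- d[order(d$trial_id, d$fish_id, d$frame), ]
  # a new event starts where the frame step exceeds 1 + gap_tolerance
  new_fish <- c(TRUE, d$trial_id[-1] != d$trial_id[-nrow(d)] |
                  d$fish_id[-1] != d$fish_id[-nrow(d)])
  step <- c(0L, diff(d$frame))
  d$event <- cumsum(new_fish | step > 1L + gap_tolerance)
  d |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      trial_id = .data$trial_id[1],
      fish_id = .data$fish_id[1],
      start_frame = min(.data$frame),
      end_frame = max(.data$frame) + 1L,
      duration_s = (max(.data$frame) + 1L - min(.data$frame)) / arena$fps,
      min_distance_cm = min(.data$dist),
      mean_distance_cm = mean(.data$dist),
      .groups = "drop"
    ) |>
    dplyr::select(-"event")
}

#' Per-fish inspection behaviour summary
#'
#' Computes the five per-individual inspection metrics: number of
#' inspections, mean event duration, overall proportion of time spent
#' inspecting (total inspecting time over the phase duration), minimum
#' inspection distance (closest approach over all events), and mean
#' inspection distance (mean over events of each event's mean distance).
#' Distance metrics are `NA` for fish with no inspections.
#'
#' @param events Event tibble from [detect_inspections()].
#' @param traj The trajectory the events came from (supplies the full fish
#'   roster so non-inspecting fish appear with zero counts).
#' @param arena An [arena_config()].
#' @return One row per (trial, fish): `n_inspections`,
#'   `mean_event_duration_s`, `prop_time_inspecting`,
#'   `min_inspection_distance_cm`, `mean_inspection_distance_cm`.
#' @export
summarize_behavior <- function(events, traj, arena) {
  roster <- dplyr::distinct(traj, .data$trial_id, .data$fish_id)
  if (nrow(events) == 0) {
    per_fish <- tibble::tibble(
      trial_id = character(), fish_id = character(),
      n_inspections = integer(), mean_event_duration_s = numeric(),
      total_inspecting_s = numeric(), min_inspection_distance_cm = numeric(),
      mean_inspection_distance_cm = numeric()
    )
  } else per_fish <- events |>
    dplyr::group_by(.data$trial_id, .data$fish_id) |>
    dplyr::summarise(
      n_inspections = dplyr::n(),
      mean_event_duration_s = mean(.data$duration_s),
      total_inspecting_s = sum(.data$duration_s),
      min_inspection_distance_cm = min(.data$min_distance_cm),
      mean_inspection_distance_cm = mean(.data$mean_distance_cm),
      .groups = "drop"
    )
  out <- dplyr::left_join(roster, per_fish, by = c("trial_id", "fish_id"))
  out$n_inspections[is.na(out$n_inspections)] <- 0L
  out$total_inspecting_s[is.na(out$total_inspecting_s)] <- 0
  out$prop_time_inspecting <- out$total_inspecting_s / arena$phase_duration_s
  dplyr::select(
    out, "trial_id", "fish_id", "n_inspections", "mean_event_duration_s",
    "prop_time_inspecting", "min_inspection_distance_cm",
    "mean_inspection_distance_cm"
  )
}

#' Refuge use from tracking visibility
#'
#' Fish in a refuge are not visible to the tracker, so refuge use is
#' measured as the proportion of the phase during which a fish was not
#' visible: `1 - visible_frames / total_phase_frames`. The denominator is
#' the full phase length from the arena config, since frames with no
#' detections at all do not appear in the table.
#'
#' @param traj A phase-labelled trajectory tibble.
#' @param phase `"before"` or `"during"`.
#' @param arena An [arena_config()].
#' @return A tibble with `trial_id`, `fish_id`, `refuge_prop`.
#' @export
refuge_use <- function(traj, phase, arena) {
  phase <- match.arg(phase, c("before", "during"))
  if (!"phase" %in% names(traj)) stop("trajectory must be phase-labelled first")
  if (!any(traj$phase == phase, na.rm = TRUE)) {
    stop("no frames labelled '", phase, "': phase window missing from the table")
  }
  n_phase <- round(arena$phase_duration_s * arena$fps)
  roster <- dplyr::distinct(traj, .data$trial_id, .data$fish_id)
  vis <- traj[!is.na(traj$phase) & traj$phase == phase, ] |>
    dplyr::group_by(.data$trial_id, .data$fish_id) |>
    dplyr::summarise(n_visible = sum(.data$visible), .groups = "drop")
  out <- dplyr::left_join(roster, vis, by = c("trial_id", "fish_id"))
  out$n_visible[is.na(out$n_visible)] <- 0L
  out$refuge_prop <- 1 - out$n_visible / n_phase
  dplyr::select(out, "trial_id", "fish_id", "refuge_prop")
}

#' Full per-fish behaviour table
#'
#' Convenience wrapper running [detect_inspections()],
#' [summarize_behavior()] and [refuge_use()] for both phases, and joining
#' trial covariates.
#'
#' @param traj A filtered, phase-labelled trajectory tibble.
#' @param meta Trial metadata tibble (see [read_trial_meta()]).
#' @param arena An [arena_config()].
#' @param gap_tolerance Passed to [detect_inspections()].
#' @return One row per fish with inspection metrics, `refuge_prop_before`,
#'   `refuge_prop_during`, and the trial covariates.
#' @export
behavior_table <- function(traj, meta, arena, gap_tolerance = 0) {
  events <- detect_inspections(traj, arena, gap_tolerance)
  behav <- summarize_behavior(events, traj, arena)
  rb <- dplyr::rename(refuge_use(traj, "before", arena), refuge_prop_before = "refuge_prop")
  rd <- dplyr::rename(refuge_use(traj, "during", arena), refuge_prop_during = "refuge_prop")
  behav |>
    dplyr::left_join(rb, by = c("trial_id", "fish_id")) |>
    dplyr::left_join(rd, by = c("trial_id", "fish_id")) |>
    dplyr::left_join(meta, by = "trial_id")
}

#' Merge individual events into group inspections
#'
#' Inspection events whose frame intervals overlap in time are merged
#' transitively into a single group inspection (connected components of the
#' interval-overlap graph), within each trial. The number of inspectors is
#' the number of distinct fish contributing events to the component.
#'
#' @param events Event tibble from [detect_inspections()].
#' @return A tibble: `trial_id`, `start_frame`, `end_frame`,
#'   `inspector_ids` (list column), `n_inspectors`.
#' @export
group_inspections <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      trial_id = character(), start_frame = integer(), end_frame = integer(),
      inspector_ids = list(), n_inspectors = integer()
    ))
  }
  events |>
    dplyr::arrange(.data$trial_id, .data$start_frame, .data$end_frame) |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::group_modify(function(ev, key) {
      # sweep: a new component starts when an event begins at or after the
      # running maximum end (half-open intervals: touching does not overlap)
      run_end <- cummax(ev$end_frame)
      ev$comp <- cumsum(c(TRUE, ev$start_frame[-1] >= run_end[-nrow(ev)]))
      ev |>
        dplyr::group_by(.data$comp) |>
        dplyr::summarise(
          start_frame = min(.data$start_frame),
          end_frame = max(.data$end_frame),
          inspector_ids = list(sort(unique(.data$fish_id))),
          n_inspectors = length(unique(.data$fish_id)),
          .groups = "drop"
        ) |>
        dplyr::select(-"comp")
    }) |>
    dplyr::ungroup()
}
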