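#' Read a per-trial tracking table
#'
#' Ingests a tracker-style CSV export (one row per fish per frame, columns
#' `frame`, `id`, `x`, `y` in cm, optional `visible`) into a validated
#' trajectory table. Rows with missing coordinates are marked not visible;
#' visible coordinates outside the arena raise a warning and are flagged
#' invalid (not visible).
#'
#' @param path Path to the CSV file.
#' @param arena An [arena_config()].
#' @param trial_id Label for the trial; defaults to the file name without
#'   extension.
#' @return A tibble with columns `trial_id`, `fish_id`, `frame`, `x`, `y`,
#'   `visible`, sorted by fish then frame.
#' @export
read_tracking <- function(path, arena, trial_id = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("frame", "id", "x", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("tracking file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(trial_id)) {
    trial_id <- sub("\\.[^.]+$", "", basename(path))
  }
  traj <- tibble::tibble(
    trial_id = as.character(trial_id),
    fish_id = as.character(raw$id),
    frame = as.integer(raw$frame),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y),
    visible = if ("visible" %in% names(raw)) as.logical(raw$visible) else TRUE
  )
  traj$visible[is.na(traj$x) | is.na(traj$y)] <- FALSE
  validate_trajectory(traj, arena)
}

# Shared validation: uniqueness, ordering, arena bounds.
validate_trajectory <- function(traj, arena) {
  if (any(is.na(traj$frame)) || any(traj$frame < 0)) {
    stop("frames must be non-negative integers")
  }
  key <- paste(traj$trial_id, traj$fish_id, traj$frame)
  if (anyDuplicated(key)) {
    stop("duplicated (fish, frame) rows within a trial")
  }
  unsorted <- traj |>
    dplyr::group_by(.data$trial_id, .data$fish_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$frame), .groups = "drop")
  if (any(!unsorted$ok)) {
    stop("frames are not ascending within fish: ",
         paste(unsorted$fish_id[!unsorted$ok], collapse = ", "))
  }
  vis <- traj$visible & !is.na(traj$x)
  out_of_bounds <- vis &
    (traj$x < 0 | traj$x > arena$width_cm | traj$y < 0 | traj$y > arena$height_cm)
  if (any(out_of_bounds)) {
    warning(sum(out_of_bounds), " position(s) outside the arena flagged invalid")
    traj$visible[out_of_bounds] <- FALSE
  }
  traj
}

#' Read the trial metadata table
#'
#' @param path CSV with columns `trial_id`, `group_size`, `temperature_c`,
#'   `mean_length_mm` and optionally `screen_lift_frame`.
#' @return A tibble, with `group_size` checked against the experimental
#'   design (5, 10 or 20 fish).
#' @export
read_trial_meta <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("trial_id", "group_size", "temperature_c", "mean_length_mm")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(meta$group_size %in% c(5, 10, 20))) {
    stop("group_size must be one of 5, 10, 20")
  }
  meta$trial_id <- as.character(meta$trial_id)
  meta
}

#' Exclude impossible tracks
#'
#' Removes track points implying impossible movement: any detection whose
#' implied instantaneous speed from the previously retained detection of the
#' same fish exceeds the speed limit (50 cm/s by default), or whose
#' Euclidean displacement from it exceeds the jump limit (50 cm). The two
#' rules are applied disjunctively and sequentially: a removed point does
#' not serve as the reference for the next one. Removal marks the point not
#' visible rather than deleting the row, so that visibility-based refuge
#' accounting stays consistent.
#'
#' Speed across a tracking gap is displacement divided by the elapsed time
#' over the whole gap.
#'
#' @param traj A trajectory tibble.
#' @param arena An [arena_config()].
#' @return The trajectory with impossible points marked `visible = FALSE`.
#' @export
filter_tracks <- function(traj, arena) {
  if (nrow(traj) == 0) return(traj)
  groups <- split(seq_len(nrow(traj)), paste(traj$trial_id, traj$fish_id, sep = "\r"))
  visible <- traj$visible
  x <- traj$x
  y <- traj$y
  frame <- traj$frame
  fps <- arena$fps
  for (idx in groups) {
    vis_idx <- idx[visible[idx]]
    if (length(vis_idx) < 2) next
    last <- vis_idx[1]
    for (i in vis_idx[-1]) {
      disp <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2)
      dt <- (frame[i] - frame[last]) / fps
      if (disp > arena$jump_limit_cm || disp / dt > arena$speed_limit_cm_s) {
        visible[i] <- FALSE
      } else {
        last <- i
      }
    }
  }
  traj$visible <- visible
  traj
}

#' Frame windows of the two analysis phases
#'
#' @param screen_lift_frame Frame at which the screen first began to lift.
#' @param arena An [arena_config()].
#' @return A list with half-open frame intervals `before = c(start, end)`
#'   and `during = c(start, end)`.
#' @export
phase_windows <- function(screen_lift_frame, arena) {
  n_phase <- round(arena$phase_duration_s * arena$fps)
  delay <- round(arena$phase_delay_s * arena$fps)
  list(
    before = c(screen_lift_frame - n_phase, screen_lift_frame),
    during = c(screen_lift_frame + delay, screen_lift_frame + delay + n_phase)
  )
}

#' Label the before/during analysis phases
#'
#' The "before" phase is the 7 minutes immediately prior to the screen
#' beginning to lift; the "during" phase is the 7 minutes beginning 30
#' seconds after the screen first began to lift. Frames outside either
#' window get `phase = NA` and are excluded from all metrics.
#'
#' @param traj A trajectory tibble (one or more trials).
#' @param screen_lift_frame A single frame number, or a named vector keyed
#'   by `trial_id`.
#' @param arena An [arena_config()].
#' @return The trajectory with a `phase` column (`"before"`, `"during"`, or
#'   `NA`) and a `phase_second` column giving the zero-based second within
#'   the phase (used by the per-second cohesion aggregation).
#' @export
label_phases <- function(traj, screen_lift_frame, arena) {
  trials <- unique(traj$trial_id)
  if (is.null(names(screen_lift_frame))) {
    if (length(screen_lift_frame) != 1 && length(trials) > 1) {
      stop("screen_lift_frame must be named by trial_id for multi-trial tables")
    }
    screen_lift_frame <- stats::setNames(
      rep(screen_lift_frame, length(trials)), trials
    )
  }
  traj$phase <- NA_character_
  traj$phase_second <- NA_integer_
  for (tr in trials) {
    lift <- screen_lift_frame[[tr]]
    if (is.null(lift) || is.na(lift)) stop("no screen_lift_frame for trial ", tr)
    win <- phase_windows(lift, arena)
    rows <- traj$trial_id == tr
    max_frame <- max(traj$frame[rows])
    if (win$before[1] < 0) {
      stop(sprintf(
        "trial %s: recording too short for the 'before' window (needs %d frames before screen lift, shortfall %d)",
        tr, win$before[2] - win$before[1], -win$before[1]
      ))
    }
    if (max_frame < win$during[2] - 1) {
      stop(sprintf(
        "trial %s: recording too short for the 'during' window (ends at frame %d, needs %d; shortfall %d frames)",
        tr, max_frame, win$during[2] - 1, win$during[2] - 1 - max_frame
      ))
    }
    f <- traj$frame[rows]
    ph <- rep(NA_character_, sum(rows))
    sec <- rep(NA_integer_, sum(rows))
    in_before <- f >= win$before[1] & f < win$before[2]
    in_during <- f >= win$during[1] & f < win$during[2]
    ph[in_before] <- "before"
    ph[in_during] <- "during"
    sec[in_before] <- (f[in_before] - win$before[1]) %/% arena$fps
    sec[in_during] <- (f[in_during] - win$during[1]) %/% arena$fps
    traj$phase[rows] <- ph
    traj$phase_second[rows] <- sec
  }
  traj
}
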