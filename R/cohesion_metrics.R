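#' Voronoi cell areas clipped to the arena
#'
#' Computes, for each fish position, the area of its Voronoi cell — the
#' region of the pool closer to that fish than to any other — clipped to
#' the arena rectangle so that boundary cells are finite. Each cell is
#' obtained by clipping the rectangle against the perpendicular-bisector
#' half-plane of every other fish (Sutherland–Hodgman against a convex
#' clip region). The cells partition the arena, so the areas sum to the
#' arena area.
#'
#' @param x,y Positions (cm) of the visible fish.
#' @param arena An [arena_config()].
#' @return Numeric vector of cell areas (cm^2), one per position.
#' @export
voronoi_cell_areas <- function(x, y, arena) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n == 1) return(arena$width_cm * arena$height_cm)
  # coincident points break the bisector construction: nudge deterministically
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    warning("coincident positions perturbed by 1e-6 cm for Voronoi tessellation")
    dup <- duplicated(key)
    k <- seq_len(sum(dup))
    x[dup] <- x[dup] + 1e-6 * k
    y[dup] <- y[dup] + 1e-6 * k
  }
  rect_x <- c(0, arena$width_cm, arena$width_cm, 0)
  rect_y <- c(0, 0, arena$height_cm, arena$height_cm)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    px <- rect_x
    py <- rect_y
    for (j in seq_len(n)[-i]) {
      # keep the half-plane a*X + b*Y <= c_ of points nearer i than j
      a <- x[j] - x[i]
      b <- y[j] - y[i]
      c_ <- (x[j]^2 - x[i]^2 + y[j]^2 - y[i]^2) / 2
      res <- clip_halfplane(px, py, a, b, c_)
      px <- res$x
      py <- res$y
      if (length(px) == 0) break
    }
    areas[i] <- polygon_area(px, py)
  }
  areas
}

# Sutherland-Hodgman clip of polygon (px, py) against a*X + b*Y <= c.
clip_halfplane <- function(px, py, a, b, c_) {
  n <- length(px)
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  inside <- a * px + b * py <= c_
  out_x <- numeric(0)
  out_y <- numeric(0)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (inside[k]) {
      out_x <- c(out_x, px[k])
      out_y <- c(out_y, py[k])
    }
    if (inside[k] != inside[k2]) {
      denom <- a * (px[k2] - px[k]) + b * (py[k2] - py[k])
      t <- (c_ - a * px[k] - b * py[k]) / denom
      out_x <- c(out_x, px[k] + t * (px[k2] - px[k]))
      out_y <- c(out_y, py[k] + t * (py[k2] - py[k]))
    }
  }
  list(x = out_x, y = out_y)
}

# Shoelace formula.
polygon_area <- function(px, py) {
  n <- length(px)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

#' Median Voronoi density of a group
#'
#' Each fish's local density is the inverse of its clipped Voronoi cell
#' area; the group-level measure is the median over fish. Needs at least
#' two visible fish.
#'
#' @param x,y Positions (cm) of the visible fish.
#' @param arena An [arena_config()].
#' @return Median density (1/cm^2), or `NA` with fewer than two fish.
#' @export
voronoi_density <- function(x, y, arena) {
  if (length(x) < 2) return(NA_real_)
  stats::median(1 / voronoi_cell_areas(x, y, arena))
}

#' Sub-group sizes by chain-rule clustering
#'
#' Groups fish into sub-groups using density-based clustering with
#' reachability distance `reach_cm` and minimum neighbourhood size 2: two
#' fish belong to the same sub-group if they are linked by a chain of
#' pairwise distances no larger than `reach_cm` (DBSCAN at minPts = 2,
#' where core/border asymmetry vanishes and the procedure reduces to
#' connected components of the proximity graph). Lone individuals are not
#' clusters: only sizes >= 2 are returned.
#'
#' @param x,y Positions (cm) of the visible fish.
#' @param reach_cm Reachability distance in cm (default 6, about four guppy
#'   body lengths).
#' @return Integer vector of cluster sizes (possibly empty).
#' @export
subgroups <- function(x, y, reach_cm = 6) {
  n <- length(x)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= reach_cm^2) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- as.integer(table(roots))
  sort(sizes[sizes >= 2], decreasing = TRUE)
}

# Per-second representative positions: each fish's first visible detection
# within each second of each phase.
per_second_positions <- function(traj) {
  traj[!is.na(traj$phase) & traj$visible, ] |>
    dplyr::arrange(.data$frame) |>
    dplyr::distinct(.data$trial_id, .data$phase, .data$phase_second,
                    .data$fish_id, .keep_all = TRUE)
}

minute_series <- function(per_sec_values, phase_duration_s) {
  # per_sec_values: tibble trial_id, phase, phase_second, value (possibly NA)
  per_minute <- per_sec_values |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(minute = .data$phase_second %/% 60L) |>
    dplyr::group_by(.data$trial_id, .data$phase, .data$minute) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  n_min <- ceiling(phase_duration_s / 60)
  grid <- tidyr::expand_grid(
    trial_id = unique(per_sec_values$trial_id),
    phase = c("before", "during"),
    minute = seq_len(n_min) - 1L
  )
  grid |>
    dplyr::left_join(per_minute, by = c("trial_id", "phase", "minute")) |>
    dplyr::mutate(
      minute_index = .data$minute + 1L + ifelse(.data$phase == "during", n_min, 0L)
    ) |>
    dplyr::arrange(.data$trial_id, .data$minute_index) |>
    dplyr::select("trial_id", "minute_index", "phase", "value")
}

#' Minute-level group density time series
#'
#' Per second, the group density is the median over fish of 1/Voronoi cell
#' area, using each fish's first visible detection within that second;
#' seconds with fewer than two visible fish contribute no value. Densities
#' are then aggregated by the median over each minute, giving a 14-point
#' series per trial under the default 7-minute phases (minutes 1–7 before,
#' 8–14 during). Minutes with no valid seconds are `NA`.
#'
#' @param traj A phase-labelled trajectory tibble.
#' @param arena An [arena_config()].
#' @return Tibble: `trial_id`, `minute_index`, `phase`, `median_density`.
#' @export
density_series <- function(traj, arena) {
  per_sec <- per_second_positions(traj) |>
    dplyr::group_by(.data$trial_id, .data$phase, .data$phase_second) |>
    dplyr::summarise(
      value = voronoi_density(.data$x, .data$y, arena),
      .groups = "drop"
    )
  minute_series(per_sec, arena$phase_duration_s) |>
    dplyr::rename(median_density = "value")
}

#' Minute-level sub-group size time series
#'
#' As [density_series()], but the per-second value is the median chain-rule
#' sub-group size ([subgroups()]); seconds where every fish is isolated
#' (no cluster of two or more) contribute no value.
#'
#' @param traj A phase-labelled trajectory tibble.
#' @param arena An [arena_config()].
#' @param reach_cm Reachability distance (cm). Default 6.
#' @return Tibble: `trial_id`, `minute_index`, `phase`,
#'   `median_subgroup_size`.
#' @export
subgroup_series <- function(traj, arena, reach_cm = 6) {
  per_sec <- per_second_positions(traj) |>
    dplyr::group_by(.data$trial_id, .data$phase, .data$phase_second) |>
    dplyr::summarise(
      value = {
        sz <- subgroups(.data$x, .data$y, reach_cm)
        if (length(sz) == 0) NA_real_ else stats::median(sz)
      },
      .groups = "drop"
    )
  minute_series(per_sec, arena$phase_duration_s) |>
    dplyr::rename(median_subgroup_size = "value")
}
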