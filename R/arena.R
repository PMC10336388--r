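#' Arena and predator-model geometry
#'
#' An `arena_config` bundles everything geometric and temporal that the
#' metric pipeline needs: the pool dimensions, the video frame rate, the
#' predator-model outline, the inspection-zone radius, the track-quality
#' limits, and the timing of the two seven-minute analysis phases relative
#' to the lifting of the opaque screen that hides the predator model.
#'
#' Coordinates are arena-frame centimetres with the origin at one pool
#' corner and y increasing away from it. All frame intervals in the package
#' are half-open (`[start, end)`).
#'
#' @param width_cm,height_cm Pool dimensions in cm. Default 150 x 150.
#' @param fps Video frame rate (frames per second). Default 25.
#' @param predator_polygon Two-column matrix of (x, y) vertices (cm)
#'   outlining the predator model in arena coordinates. Must lie inside the
#'   arena. Defaults to a convex, roughly pike-shaped outline (~17 cm long,
#'   ~5.5 cm deep) centred in the pool.
#' @param inspection_radius_cm A fish within this distance of any part of
#'   the predator polygon is considered to be inspecting. Default 30.
#' @param speed_limit_cm_s Tracks implying instantaneous speed above this
#'   are excluded as impossible. Default 50.
#' @param jump_limit_cm Tracks jumping further than this between retained
#'   detections are excluded. Default 50.
#' @param phase_delay_s Delay between the screen starting to lift and the
#'   start of the "during" phase, allowing screen movement to settle.
#'   Default 30.
#' @param phase_duration_s Duration of each analysis phase. Default 420
#'   (7 minutes).
#'
#' @return An object of class `arena_config` (a named list).
#' @export
arena_config <- function(width_cm = 150,
                         height_cm = 150,
                         fps = 25,
                         predator_polygon = default_predator_polygon(width_cm, height_cm),
                         inspection_radius_cm = 30,
                         speed_limit_cm_s = 50,
                         jump_limit_cm = 50,
                         phase_delay_s = 30,
                         phase_duration_s = 420) {
  stopifnot(
    width_cm > 0, height_cm > 0, fps > 0,
    inspection_radius_cm > 0,
    inspection_radius_cm < min(width_cm, height_cm),
    speed_limit_cm_s > 0, jump_limit_cm > 0,
    phase_delay_s >= 0, phase_duration_s > 0
  )
  poly <- as.matrix(predator_polygon)
  if (ncol(poly) != 2 || nrow(poly) < 3) {
    stop("predator_polygon must be a matrix of >= 3 (x, y) vertices")
  }
  if (any(poly[, 1] < 0 | poly[, 1] > width_cm | poly[, 2] < 0 | poly[, 2] > height_cm)) {
    stop("predator_polygon must lie inside the arena")
  }
  structure(
    list(
      width_cm = width_cm, height_cm = height_cm, fps = fps,
      predator_polygon = poly,
      inspection_radius_cm = inspection_radius_cm,
      speed_limit_cm_s = speed_limit_cm_s,
      jump_limit_cm = jump_limit_cm,
      phase_delay_s = phase_delay_s,
      phase_duration_s = phase_duration_s
    ),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf(
    "<arena_config> %g x %g cm pool, %g fps\n  inspection zone %g cm, speed/jump limits %g cm/s, %g cm\n  phases: %g s each, 'during' starts %g s after screen lift\n  predator polygon: %d vertices\n",
    x$width_cm, x$height_cm, x$fps, x$inspection_radius_cm,
    x$speed_limit_cm_s, x$jump_limit_cm,
    x$phase_duration_s, x$phase_delay_s, nrow(x$predator_polygon)
  ))
  invisible(x)
}

#' Read an arena/predator geometry config file
#'
#' Reads a YAML key/value file with any of the [arena_config()] fields;
#' `predator_polygon` is given as a list of `[x, y]` vertex pairs. Missing
#' keys fall back to the defaults.
#'
#' @param path Path to the YAML file.
#' @return An [arena_config()].
#' @export
read_arena_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("width_cm", "height_cm", "fps", "predator_polygon",
             "inspection_radius_cm", "speed_limit_cm_s", "jump_limit_cm",
             "phase_delay_s", "phase_duration_s")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown arena config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$predator_polygon)) {
    cfg$predator_polygon <- do.call(rbind, cfg$predator_polygon)
  }
  do.call(arena_config, cfg)
}

#' Default predator-model outline
#'
#' A convex hexagonal outline approximating a 17 cm x 5.5 cm pike-cichlid
#' model, centred in the arena and aligned with the x axis.
#'
#' @param width_cm,height_cm Arena dimensions (cm).
#' @return A 6 x 2 matrix of vertices.
#' @export
default_predator_polygon <- function(width_cm = 150, height_cm = 150) {
  cx <- width_cm / 2
  cy <- height_cm / 2
  # half-length 8.5, half-depth 2.75; snout and tail taper to points
  rbind(
    c(cx - 8.5, cy),
    c(cx - 5.0, cy - 2.75),
    c(cx + 5.0, cy - 2.75),
    c(cx + 8.5, cy),
    c(cx + 5.0, cy + 2.75),
    c(cx - 5.0, cy + 2.75)
  )
}

# Minimum distance from points to a segment, vectorised over points.
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return(sqrt((px - ax)^2 + (py - ay)^2))
  }
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# Even-odd point-in-polygon test, vectorised over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Nearest point on the predator polygon boundary, vectorised over points.
# Used by the synthetic generator to steer fish off the inspection zone.
closest_predator_point <- function(x, y, arena) {
  poly <- arena$predator_polygon
  n <- nrow(poly)
  best_d <- rep(Inf, length(x))
  best_x <- best_y <- rep(NA_real_, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
    qx <- ax + t * dx
    qy <- ay + t * dy
    d <- sqrt((x - qx)^2 + (y - qy)^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_x[upd] <- qx[upd]
    best_y[upd] <- qy[upd]
    j <- i
  }
  list(d = best_d, x = best_x, y = best_y)
}

#' Distance from positions to the predator model
#'
#' Minimum Euclidean distance from each point to any part of the predator
#' polygon (its boundary), or 0 for points inside the polygon.
#'
#' @param x,y Numeric vectors of positions (cm).
#' @param arena An [arena_config()].
#' @return Numeric vector of distances (cm).
#' @export
distance_to_predator <- function(x, y, arena) {
  poly <- arena$predator_polygon
  n <- nrow(poly)
  d <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, dist_point_segment(x, y, poly[j, 1], poly[j, 2], poly[i, 1], poly[i, 2]))
    j <- i
  }
  d[point_in_polygon(x, y, poly)] <- 0
  d
}
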