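#' Scenario for synthetic trials
#'
#' Bundles the design and behavioural parameters of a synthetic experiment
#' emulating the study conditions: 25 frames/s trajectories of 5-, 10- and
#' 20-fish groups in a 150 x 150 cm arena over two 7-minute phases, with
#' scheduled excursions into the 30 cm inspection zone, refuge bouts
#' (invisible frames), shoaling around sub-group centroids, and trial-level
#' random variation on the log inspection rate.
#'
#' Defaults emulate the qualitative pattern of the study (large groups
#' inspect most, intermediate groups use refuges most); they are fixture
#' choices, not estimates of the real data.
#'
#' @param group_sizes Experimental group sizes. Default `c(5, 10, 20)`.
#' @param n_trials_per_size Trials per group size. Default 5 (15 trials).
#' @param inspection_rate Mean inspections per fish per 7-minute phase,
#'   named by level. Default `c(small = 7, intermediate = 6.4, large = 13.2)`.
#' @param event_duration_shape,event_duration_scale Gamma parameters of
#'   event durations (seconds). Default shape 2, scale 1.25 (mean 2.5 s).
#' @param event_min_distance_range Range the closest-approach distance of
#'   each excursion is drawn from (cm). Default `c(8, 25)`.
#' @param refuge_before,refuge_during Scheduled hidden-time fractions per
#'   phase, named by level.
#' @param refuge_dwell_s Mean refuge bout length (seconds). Default 8.
#' @param refuge_fish_sd,refuge_trial_sd Logit-scale SDs of fish- and
#'   trial-level variation in refuge fractions.
#' @param trial_sd_log_rate SD of the trial random effect on the log
#'   inspection rate. Default 0.3.
#' @param n_centroids Number of shoal centroids fish are attracted to.
#' @param attraction Pull towards the assigned centroid per frame.
#' @param step_sd SD (cm/frame) of the random-walk innovation.
#' @param temperature_mean,temperature_sd Water temperature distribution
#'   across trials (deg C).
#' @param length_mean,length_sd Mean fish length distribution across
#'   trials (mm).
#' @param fixed_n_events If set, every fish gets exactly this many
#'   scheduled excursions instead of a Poisson draw.
#' @param teleport_rate Per-frame probability of injecting a teleport
#'   fault (impossible jump) into otherwise clean tracks, for testing the
#'   track filter. Default 0.
#' @param arena An [arena_config()].
#' @return A `trial_scenario` object (named list).
#' @export
trial_scenario <- function(group_sizes = c(5, 10, 20),
                           n_trials_per_size = 5,
                           inspection_rate = c(small = 7, intermediate = 6.4,
                                               large = 13.2),
                           event_duration_shape = 2,
                           event_duration_scale = 1.25,
                           event_min_distance_range = c(8, 25),
                           refuge_before = c(small = 0.30, intermediate = 0.28,
                                             large = 0.26),
                           refuge_during = c(small = 0.35, intermediate = 0.45,
                                             large = 0.22),
                           refuge_dwell_s = 8,
                           refuge_fish_sd = 0.25,
                           refuge_trial_sd = 0.2,
                           trial_sd_log_rate = 0.3,
                           n_centroids = 2,
                           attraction = 0.06,
                           step_sd = 0.45,
                           temperature_mean = 25,
                           temperature_sd = 0.7,
                           length_mean = 18,
                           length_sd = 1.2,
                           fixed_n_events = NULL,
                           teleport_rate = 0,
                           arena = arena_config()) {
  stopifnot(all(group_sizes %in% c(5, 10, 20)),
            n_trials_per_size >= 1,
            all(inspection_rate >= 0),
            all(refuge_before >= 0 & refuge_before < 1),
            all(refuge_during >= 0 & refuge_during < 1),
            teleport_rate >= 0, teleport_rate < 0.05)
  structure(as.list(environment()), class = "trial_scenario")
}

# Outward unit normal of polygon edge (a -> b); flipped if it points into
# the polygon.
edge_outward_normal <- function(a, b, poly) {
  d <- b - a
  nrm <- c(d[2], -d[1]) / sqrt(sum(d^2))
  probe <- (a + b) / 2 + 0.1 * nrm
  if (point_in_polygon(probe[1], probe[2], poly)) -nrm else nrm
}

# Scripted distance-to-predator path of one excursion: enter at 29 cm,
# vee down to d_min with steps <= 1.4 cm plus small noise, leave at 29 cm.
# All values <= 29 (< the 30 cm zone) and all steps < 2 cm (the 50 cm/s
# limit at 25 fps).
excursion_distance_path <- function(m, d_min) {
  t <- seq_len(m)
  tri <- pmax(29 - 1.4 * pmin(t - 1, m - t), d_min)
  noise <- c(0, stats::rnorm(max(0, m - 2), 0, 0.1), 0)[seq_len(m)]
  pmin(pmax(tri + noise, d_min - 0.2, 4), 29)
}

# Schedule excursions for one fish within the during window [w0, w1).
# Window is partitioned into equal blocks; each block holds one event with
# a fixed approach lead so the fish can reach the staging point from
# anywhere in the arena without impossible speeds.
schedule_excursions <- function(n_ev, w0, w1, fps, dur_shape, dur_scale,
                                lead = 300L, margin = 12L) {
  W <- w1 - w0
  if (n_ev < 1) return(NULL)
  repeat {
    L <- W %/% n_ev
    if (L >= lead + 3 + margin || n_ev == 0) break
    n_ev <- n_ev - 1
  }
  if (n_ev < 1) return(NULL)
  L <- W %/% n_ev
  ev <- vector("list", n_ev)
  for (k in seq_len(n_ev)) {
    block0 <- w0 + (k - 1) * L
    dur <- max(3L, round(stats::rgamma(1, dur_shape, scale = dur_scale) * fps))
    dur <- min(dur, L - lead - margin)
    slack <- L - lead - dur - margin
    start <- block0 + lead + sample.int(slack + 1, 1) - 1L
    ev[[k]] <- list(approach_start = block0, start = start,
                    end = start + dur)
  }
  ev
}

# Place exactly n_hidden frames of refuge time in the allowed positions of
# a phase window, in contiguous bouts of roughly dwell frames.
place_hidden <- function(allowed, n_hidden, dwell) {
  hidden <- logical(length(allowed))
  n_hidden <- min(n_hidden, sum(allowed))
  remaining <- n_hidden
  while (remaining > 0) {
    open <- which(allowed & !hidden)
    start <- open[sample.int(length(open), 1)]
    len <- min(remaining, max(25, stats::rpois(1, dwell)))
    run <- start
    while (length(run) < len) {
      nxt <- run[length(run)] + 1L
      if (nxt > length(allowed) || !allowed[nxt] || hidden[nxt]) break
      run <- c(run, nxt)
    }
    hidden[run] <- TRUE
    remaining <- remaining - length(run)
  }
  hidden
}

#' Generate ground-truthed synthetic trajectories
#'
#' Simulates every trial of the scenario: fish follow a biased correlated
#' random walk around slowly drifting shoal centroids, make scheduled
#' excursions into the inspection zone (approaching along the outward
#' normal of a predator-polygon edge, so the scripted distance path is the
#' exact distance to the model), and disappear for scheduled refuge bouts.
#' Outside excursions, fish in the post-lift period are kept at least
#' 30.5 cm from the model, so the in-zone frames are exactly the scheduled
#' ones; all per-frame steps stay below 2 cm (50 cm/s at 25 fps), so the
#' track filter removes nothing unless teleport faults are requested.
#'
#' @param scenario A [trial_scenario()].
#' @param seed RNG seed; recorded in the output.
#' @return A list:
#'   \describe{
#'     \item{trajectories}{tibble of all trials (`trial_id`, `fish_id`,
#'       `frame`, `x`, `y`, `visible`); hidden frames have `NA`
#'       coordinates.}
#'     \item{meta}{trial metadata (`trial_id`, `group_size`,
#'       `temperature_c`, `mean_length_mm`, `screen_lift_frame`).}
#'     \item{ground_truth}{list with `events` (scheduled excursions with
#'       realized min/mean distances), `refuge` (scheduled hidden
#'       fractions per fish and phase), `rates` (trial-level true log-rate
#'       multipliers), `teleports` (injected fault frames), `seed`.}
#'   }
#' @export
generate_trajectories <- function(scenario, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  arena <- scenario$arena
  fps <- arena$fps
  n_phase <- round(arena$phase_duration_s * fps)
  delay <- round(arena$phase_delay_s * fps)
  lift <- n_phase
  total <- n_phase + delay + n_phase
  win_before <- c(0L, lift)
  win_during <- c(lift + delay, lift + delay + n_phase)
  poly <- arena$predator_polygon
  poly_c <- colMeans(poly)
  poly_rad <- max(sqrt((poly[, 1] - poly_c[1])^2 + (poly[, 2] - poly_c[2])^2))
  labels <- c("5" = "small", "10" = "intermediate", "20" = "large")

  design <- expand.grid(rep_i = seq_len(scenario$n_trials_per_size),
                        group_size = scenario$group_sizes)
  trial_ids <- sprintf("T%02d", seq_len(nrow(design)))

  traj_list <- list()
  meta_list <- list()
  event_list <- list()
  refuge_list <- list()
  teleport_list <- list()
  rate_list <- list()

  for (ti in seq_len(nrow(design))) {
    gs <- design$group_size[ti]
    lab <- labels[as.character(gs)]
    trial_id <- trial_ids[ti]
    n_fish <- gs
    trial_re <- stats::rnorm(1, 0, scenario$trial_sd_log_rate)
    trial_refuge_re <- stats::rnorm(1, 0, scenario$refuge_trial_sd)
    rate_eff <- scenario$inspection_rate[[lab]] * exp(trial_re) *
      n_phase / (420 * fps)

    # --- schedules -----------------------------------------------------
    schedules <- vector("list", n_fish)
    for (f in seq_len(n_fish)) {
      n_ev <- if (!is.null(scenario$fixed_n_events)) {
        scenario$fixed_n_events
      } else {
        stats::rpois(1, rate_eff)
      }
      evs <- schedule_excursions(n_ev, win_during[1], win_during[2], fps,
                                 scenario$event_duration_shape,
                                 scenario$event_duration_scale)
      if (!is.null(evs)) {
        for (k in seq_along(evs)) {
          e <- evs[[k]]
          edge <- sample.int(nrow(poly), 1)
          a <- poly[edge, ]
          b <- poly[if (edge == nrow(poly)) 1 else edge + 1, ]
          s <- stats::runif(1, 0.25, 0.75)
          q <- a + s * (b - a)
          nrm <- edge_outward_normal(a, b, poly)
          d_min <- stats::runif(1, scenario$event_min_distance_range[1],
                                scenario$event_min_distance_range[2])
          e$q <- q
          e$normal <- nrm
          e$d_path <- excursion_distance_path(e$end - e$start, d_min)
          evs[[k]] <- e
        }
      }
      schedules[f] <- list(evs)  # [f] <- list(): NULL must not drop the slot
    }

    # --- refuge bouts --------------------------------------------------
    hidden <- matrix(FALSE, total, n_fish)
    for (f in seq_len(n_fish)) {
      protected <- logical(total)
      for (e in schedules[[f]]) {
        protected[(e$approach_start + 1):min(e$end + 2, total)] <- TRUE
      }
      for (ph in c("before", "during")) {
        win <- if (ph == "before") win_before else win_during
        target <- if (ph == "before") scenario$refuge_before[[lab]] else
          scenario$refuge_during[[lab]]
        frac <- stats::plogis(stats::qlogis(max(target, 1e-3)) +
                                trial_refuge_re +
                                stats::rnorm(1, 0, scenario$refuge_fish_sd))
        idx <- (win[1] + 1):win[2]
        n_hide <- round(frac * n_phase)
        h <- place_hidden(!protected[idx], n_hide, scenario$refuge_dwell_s * fps)
        hidden[idx, f] <- h
        refuge_list[[length(refuge_list) + 1]] <- tibble::tibble(
          trial_id = trial_id, fish_id = sprintf("F%02d", f), phase = ph,
          n_hidden = sum(h), frac_hidden = sum(h) / n_phase
        )
      }
    }

    # --- movement ------------------------------------------------------
    mode <- matrix(0L, total, n_fish)   # 0 free, 1 approach, 2 inspect
    evid <- matrix(0L, total, n_fish)
    for (f in seq_len(n_fish)) {
      for (k in seq_along(schedules[[f]])) {
        e <- schedules[[f]][[k]]
        mode[(e$approach_start + 1):e$start, f] <- 1L
        mode[(e$start + 1):e$end, f] <- 2L
        evid[(e$approach_start + 1):e$end, f] <- k
      }
    }

    X <- matrix(NA_real_, total, n_fish)
    Y <- matrix(NA_real_, total, n_fish)
    cent <- matrix(0, scenario$n_centroids, 2)
    for (k in seq_len(scenario$n_centroids)) {
      repeat {
        p <- stats::runif(2, 0.2 * arena$width_cm, 0.8 * arena$width_cm)
        if (distance_to_predator(p[1], p[2], arena) >= 45) break
      }
      cent[k, ] <- p
    }
    assign_c <- sample.int(scenario$n_centroids, n_fish, replace = TRUE)
    # start near centroids, outside the guard zone
    for (f in seq_len(n_fish)) {
      repeat {
        p <- cent[assign_c[f], ] + stats::rnorm(2, 0, 4)
        p <- pmin(pmax(p, 1), c(arena$width_cm, arena$height_cm) - 1)
        if (distance_to_predator(p[1], p[2], arena) >= 31) break
      }
      X[1, f] <- p[1]
      Y[1, f] <- p[2]
    }

    # scripted inspection positions and approach staging targets
    tgt_x <- matrix(NA_real_, total, n_fish)
    tgt_y <- matrix(NA_real_, total, n_fish)
    for (f in seq_len(n_fish)) {
      for (e in schedules[[f]]) {
        s_pt <- e$q + 30.8 * e$normal
        rows_a <- (e$approach_start + 1):e$start
        tgt_x[rows_a, f] <- s_pt[1]
        tgt_y[rows_a, f] <- s_pt[2]
        rows_i <- (e$start + 1):e$end
        X[rows_i, f] <- e$q[1] + e$d_path * e$normal[1]
        Y[rows_i, f] <- e$q[2] + e$d_path * e$normal[2]
      }
    }

    vel <- matrix(0, n_fish, 2)
    orbit <- integer(n_fish)  # persistent detour direction while blocked
    guard <- 30.5
    xmax <- arena$width_cm - 0.5
    ymax <- arena$height_cm - 0.5

    for (t in 2:total) {
      frame <- t - 1L
      # centroids: slow OU toward the arena centre, kept off the predator
      drift <- 0.002 * (rep(c(arena$width_cm, arena$height_cm) / 2,
                            each = nrow(cent)) - cent)
      prop_c <- cent + drift + matrix(stats::rnorm(length(cent), 0, 0.25),
                                      nrow(cent), 2)
      prop_c <- pmin(pmax(prop_c, 15), arena$width_cm - 15)
      ok <- distance_to_predator(prop_c[, 1], prop_c[, 2], arena) >= 40
      cent[ok, ] <- prop_c[ok, ]

      act <- which(mode[t, ] != 2L)
      if (length(act) == 0) next
      px <- X[t - 1, act]
      py <- Y[t - 1, act]
      m1 <- mode[t, act] == 1L
      hid <- hidden[t, act]
      free <- !m1 & !hid
      # refuge-dwelling fish hold position (a re-emergence jump would look
      # like an impossible track)
      vel[act[hid], ] <- 0
      sx <- numeric(length(act))
      sy <- numeric(length(act))
      if (any(free)) {
        fidx <- act[free]
        vel[fidx, 1] <- 0.8 * vel[fidx, 1] +
          scenario$attraction * (cent[assign_c[fidx], 1] - px[free]) +
          stats::rnorm(length(fidx), 0, scenario$step_sd)
        vel[fidx, 2] <- 0.8 * vel[fidx, 2] +
          scenario$attraction * (cent[assign_c[fidx], 2] - py[free]) +
          stats::rnorm(length(fidx), 0, scenario$step_sd)
        sp <- sqrt(vel[fidx, 1]^2 + vel[fidx, 2]^2)
        over <- sp > 1.5
        if (any(over)) {
          vel[fidx[over], ] <- vel[fidx[over], , drop = FALSE] * (1.5 / sp[over])
        }
        sx[free] <- vel[fidx, 1]
        sy[free] <- vel[fidx, 2]
      }
      if (any(m1)) {
        dx <- tgt_x[t, act[m1]] - px[m1]
        dy <- tgt_y[t, act[m1]] - py[m1]
        nd <- sqrt(dx^2 + dy^2)
        fac <- ifelse(nd <= 1.6, 1, 1.6 / pmax(nd, 1e-12))
        sx[m1] <- dx * fac
        sy[m1] <- dy * fac
      }
      nx <- pmin(pmax(px + sx, 0.5), xmax)
      ny <- pmin(pmax(py + sy, 0.5), ymax)
      if (frame >= lift) {
        # bounding-circle precheck: exact polygon distances only near the zone
        rough <- sqrt((px - poly_c[1])^2 + (py - poly_c[2])^2) - poly_rad
        near <- which(rough < guard + 4)
        push <- logical(length(act))
        if (length(near)) {
          cp <- closest_predator_point(px[near], py[near], arena)
          pu <- cp$d < guard
          push[near[pu]] <- TRUE
          if (any(pu)) {
            i <- near[pu]
            ux <- px[i] - cp$x[pu]
            uy <- py[i] - cp$y[pu]
            un <- pmax(sqrt(ux^2 + uy^2), 1e-9)
            nx[i] <- pmin(pmax(px[i] + 1.5 * ux / un, 0.5), xmax)
            ny[i] <- pmin(pmax(py[i] + 1.5 * uy / un, 0.5), ymax)
          }
        }
        dprop <- rep(Inf, length(act))
        near2 <- which(sqrt((nx - poly_c[1])^2 + (ny - poly_c[2])^2) -
                         poly_rad < guard + 4)
        if (length(near2)) {
          dprop[near2] <- distance_to_predator(nx[near2], ny[near2], arena)
        }
        viol <- which(!push & dprop < guard)
        for (v in viol) {
          fv <- act[v]
          if (!m1[v]) {
            # free fish just wait out the blocked step
            nx[v] <- px[v]
            ny[v] <- py[v]
            vel[fv, ] <- 0
            next
          }
          # approaching fish walk around the zone along its tangent, in an
          # angular direction held fixed for the whole detour (re-deriving
          # it each frame from the re-aimed step ping-pongs forever)
          rx <- px[v] - poly_c[1]
          ry <- py[v] - poly_c[2]
          rn <- max(sqrt(rx^2 + ry^2), 1e-9)
          if (orbit[fv] == 0L) {
            cr <- rx * (tgt_y[t, fv] - poly_c[2]) -
              ry * (tgt_x[t, fv] - poly_c[1])
            orbit[fv] <- if (cr >= 0) 1L else -1L
          }
          cands <- list(orbit[fv] * 1.6 * c(-ry, rx) / rn,  # ring tangent
                        1.5 * c(rx, ry) / rn)               # radial escape
          moved <- FALSE
          for (cnd in cands) {
            axv <- px[v] + cnd[1]
            ayv <- py[v] + cnd[2]
            if (distance_to_predator(axv, ayv, arena) >= guard) {
              nx[v] <- axv
              ny[v] <- ayv
              moved <- TRUE
              break
            }
          }
          if (!moved) {
            nx[v] <- px[v]
            ny[v] <- py[v]
          }
        }
        if (length(viol)) {
          orbit[act[-viol]] <- 0L
        } else {
          orbit[act] <- 0L
        }
      }
      X[t, act] <- nx
      Y[t, act] <- ny
    }

    # every scripted excursion must be entered from its staging point;
    # a larger jump would be removed by the track filter and break the
    # ground-truth guarantee
    for (f in seq_len(n_fish)) {
      for (e in schedules[[f]]) {
        i0 <- e$start  # row index of frame start-1 (frames are 0-based)
        jump <- sqrt((X[i0 + 1, f] - X[i0, f])^2 + (Y[i0 + 1, f] - Y[i0, f])^2)
        if (jump > 1.95) {
          stop("internal scheduling error: excursion entered with a ",
               round(jump, 2), " cm jump (fish ", f, ", trial ", trial_id, ")")
        }
      }
    }

    # --- teleport faults ----------------------------------------------
    teleports <- integer(0)
    tele_fish <- integer(0)
    if (scenario$teleport_rate > 0) {
      for (f in seq_len(n_fish)) {
        ok_frames <- which(mode[, f] == 0L & !hidden[, f])
        ok_frames <- ok_frames[ok_frames > 2 & ok_frames < total]
        ok_frames <- ok_frames[!hidden[pmax(ok_frames - 1, 1), f] &
                                 mode[pmax(ok_frames - 1, 1), f] == 0L]
        picks <- ok_frames[stats::runif(length(ok_frames)) <
                             scenario$teleport_rate]
        picks <- picks[c(TRUE, diff(picks) > 3)]
        for (t in picks) {
          prev <- c(X[t - 1, f], Y[t - 1, f])
          for (try in 1:100) {
            cand <- c(stats::runif(1, 1, arena$width_cm - 1),
                      stats::runif(1, 1, arena$height_cm - 1))
            if (sqrt(sum((cand - prev)^2)) >= 55 &&
                  distance_to_predator(cand[1], cand[2], arena) >= 31) {
              X[t, f] <- cand[1]
              Y[t, f] <- cand[2]
              teleports <- c(teleports, t - 1L)
              tele_fish <- c(tele_fish, f)
              break
            }
          }
        }
      }
    }

    # --- assemble ------------------------------------------------------
    frames <- rep(0:(total - 1L), n_fish)
    fish <- rep(sprintf("F%02d", seq_len(n_fish)), each = total)
    vis <- !as.vector(hidden)
    xs <- as.vector(X)
    ys <- as.vector(Y)
    xs[!vis] <- NA_real_
    ys[!vis] <- NA_real_
    traj_list[[ti]] <- tibble::tibble(
      trial_id = trial_id, fish_id = fish, frame = frames,
      x = xs, y = ys, visible = vis
    )
    meta_list[[ti]] <- tibble::tibble(
      trial_id = trial_id, group_size = gs,
      temperature_c = stats::rnorm(1, scenario$temperature_mean,
                                   scenario$temperature_sd),
      mean_length_mm = stats::rnorm(1, scenario$length_mean,
                                    scenario$length_sd),
      screen_lift_frame = lift
    )
    rate_list[[ti]] <- tibble::tibble(trial_id = trial_id, group_size = gs,
                                      log_rate_re = trial_re,
                                      rate_per_fish = rate_eff)
    for (f in seq_len(n_fish)) {
      for (e in schedules[[f]]) {
        event_list[[length(event_list) + 1]] <- tibble::tibble(
          trial_id = trial_id, fish_id = sprintf("F%02d", f),
          start_frame = e$start, end_frame = e$end,
          duration_s = (e$end - e$start) / fps,
          min_distance_cm = min(e$d_path),
          mean_distance_cm = mean(e$d_path)
        )
      }
    }
    if (length(teleports) > 0) {
      teleport_list[[length(teleport_list) + 1]] <- tibble::tibble(
        trial_id = trial_id, fish_id = sprintf("F%02d", tele_fish),
        frame = teleports
      )
    }
  }

  events <- if (length(event_list)) dplyr::bind_rows(event_list) else
    tibble::tibble(trial_id = character(), fish_id = character(),
                   start_frame = integer(), end_frame = integer(),
                   duration_s = numeric(), min_distance_cm = numeric(),
                   mean_distance_cm = numeric())
  list(
    trajectories = dplyr::bind_rows(traj_list),
    meta = dplyr::bind_rows(meta_list),
    ground_truth = list(
      events = events,
      refuge = dplyr::bind_rows(refuge_list),
      rates = dplyr::bind_rows(rate_list),
      teleports = if (length(teleport_list)) dplyr::bind_rows(teleport_list)
        else tibble::tibble(trial_id = character(), fish_id = character(),
                            frame = integer()),
      seed = seed
    )
  )
}

#' Write a trajectory table in the tracker CSV dialect
#'
#' Emits one CSV per trial with columns `frame`, `id`, `x`, `y`,
#' `visible`; hidden frames have empty coordinates, as in tracker exports.
#'
#' @param traj Trajectory tibble (possibly several trials).
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_tracking <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(traj, traj$trial_id), function(tr) {
    path <- file.path(dir, paste0(tr$trial_id[1], ".csv"))
    readr::write_csv(
      tibble::tibble(frame = tr$frame, id = tr$fish_id, x = tr$x, y = tr$y,
                     visible = tr$visible),
      path
    )
    path
  }, character(1))
  invisible(paths)
}

#' Generate a behaviour table from the GLMM generative model
#'
#' Samples a per-fish response table directly from the generative structure
#' the inference module assumes: a linear predictor with group-size,
#' centred temperature and length effects plus a trial random intercept,
#' pushed through the family's link, with Poisson, Beta (precision kappa)
#' or Gamma (shape alpha) observation noise. Used for simulation-based
#' calibration of the fitted models.
#'
#' @param true_coefs Named list: `family` (`"poisson"`, `"beta"`,
#'   `"gamma"`), `intercept`, `b_intermediate`, `b_large`,
#'   `b_temperature`, `b_length`, `sigma_trial`, and `kappa` (beta) or
#'   `alpha` (gamma).
#' @param design Named list: `group_sizes`, `n_trials_per_size`,
#'   `temperature_mean`, `temperature_sd`, `length_mean`, `length_sd`.
#'   Missing entries fall back to the study design (5/10/20 fish, 5 trials
#'   each).
#' @param seed RNG seed.
#' @return List with `data` (tibble: `trial_id`, `fish_id`, `group_size`,
#'   `temperature_c`, `mean_length_mm`, `response`) and `truth` (the
#'   coefficients plus the implied response-scale contrasts at the sample
#'   mean covariates: `contrast_response`, `contrast_link`).
#' @export
generate_behavior_table <- function(true_coefs, design = list(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dg <- utils::modifyList(
    list(group_sizes = c(5, 10, 20), n_trials_per_size = 5,
         temperature_mean = 25, temperature_sd = 0.7,
         length_mean = 18, length_sd = 1.2),
    design
  )
  tc <- utils::modifyList(
    list(b_temperature = 0, b_length = 0, sigma_trial = 0,
         kappa = 10, alpha = 2),
    true_coefs
  )
  grid <- expand.grid(rep_i = seq_len(dg$n_trials_per_size),
                      group_size = dg$group_sizes)
  rows <- list()
  for (ti in seq_len(nrow(grid))) {
    gs <- grid$group_size[ti]
    n_fish <- gs
    temp <- stats::rnorm(1, dg$temperature_mean, dg$temperature_sd)
    len <- stats::rnorm(1, dg$length_mean, dg$length_sd)
    u <- stats::rnorm(1, 0, tc$sigma_trial)
    b_gs <- switch(as.character(gs), "5" = 0, "10" = tc$b_intermediate,
                   "20" = tc$b_large)
    eta <- tc$intercept + b_gs +
      tc$b_temperature * (temp - dg$temperature_mean) +
      tc$b_length * (len - dg$length_mean) + u
    y <- switch(tc$family,
      poisson = stats::rpois(n_fish, exp(eta)),
      beta = {
        mu <- stats::plogis(eta)
        stats::rbeta(n_fish, mu * tc$kappa, (1 - mu) * tc$kappa)
      },
      gamma = stats::rgamma(n_fish, tc$alpha, rate = tc$alpha / exp(eta))
    )
    rows[[ti]] <- tibble::tibble(
      trial_id = sprintf("T%02d", ti),
      fish_id = sprintf("F%02d", seq_len(n_fish)),
      group_size = gs, temperature_c = temp, mean_length_mm = len,
      response = y
    )
  }
  data <- dplyr::bind_rows(rows)
  # response-scale contrasts at the realized sample-mean covariates,
  # random intercept zero (the reference point posterior_summary uses)
  ilink <- inv_link(tc$family)
  eta0 <- tc$intercept +
    tc$b_temperature * (mean(data$temperature_c) - dg$temperature_mean) +
    tc$b_length * (mean(data$mean_length_mm) - dg$length_mean)
  lv <- c(small = 0, intermediate = tc$b_intermediate, large = tc$b_large)
  contrast_link <- c(
    "small → intermediate" = unname(lv["intermediate"] - lv["small"]),
    "small → large" = unname(lv["large"] - lv["small"]),
    "intermediate → large" = unname(lv["large"] - lv["intermediate"])
  )
  contrast_response <- c(
    "small → intermediate" = ilink(eta0 + lv[["intermediate"]]) - ilink(eta0),
    "small → large" = ilink(eta0 + lv[["large"]]) - ilink(eta0),
    "intermediate → large" = ilink(eta0 + lv[["large"]]) -
      ilink(eta0 + lv[["intermediate"]])
  )
  list(data = data,
       truth = list(coefs = tc, contrast_link = contrast_link,
                    contrast_response = contrast_response))
}
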