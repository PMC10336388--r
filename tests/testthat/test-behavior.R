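arena <- test_arena(phase_s = 4, delay_s = 0)  # tiny windows for hand fixtures

# A during-phase trajectory at a controlled distance from the model: place
# the fish on the vertical through the bottom-edge midpoint.
at_distance <- function(d, frames, arena) {
  poly <- arena$predator_polygon
  mid <- (poly[2, ] + poly[3, ]) / 2
  make_traj("T1", "F1", frames, x = mid[1], y = mid[2] - d)
}

labelled <- function(tr, arena) label_phases(tr, arena$phase_duration_s * arena$fps, arena)

test_that("a steady in-zone fish yields one event with exact metrics", {
  # during window is frames [100, 200); 50 frames at 29 cm
  tr <- labelled(at_distance(29, 100:199, arena), arena)
  tr$visible <- tr$frame < 150
  ev <- detect_inspections(tr, arena)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 2.0)
  expect_equal(ev$min_distance_cm, 29)
  expect_equal(ev$mean_distance_cm, 29)
  expect_equal(ev$start_frame, 100)
  expect_equal(ev$end_frame, 150)
})

test_that("fish outside the 30 cm zone never inspect", {
  tr <- labelled(at_distance(31, 100:199, arena), arena)
  expect_equal(nrow(detect_inspections(tr, arena)), 0)
})

test_that("invisible frames split events unless gap tolerance bridges them", {
  tr <- labelled(at_distance(25, 100:199, arena), arena)
  tr$visible[tr$frame == 130] <- FALSE
  expect_equal(nrow(detect_inspections(tr, arena)), 2)
  expect_equal(nrow(detect_inspections(tr, arena, gap_tolerance = 1)), 1)
})

test_that("per-fish summaries follow their definitions", {
  ev <- tibble::tibble(
    trial_id = "T1", fish_id = "F1",
    start_frame = c(0L, 100L), end_frame = c(50L, 200L),
    duration_s = c(2, 4), min_distance_cm = c(12, 20),
    mean_distance_cm = c(15, 25)
  )
  a420 <- arena_config()  # 420 s phases
  roster <- make_traj("T1", c("F1", "F2"), 0:1, x = 20, y = 20)
  bs <- summarize_behavior(ev, roster, a420)
  f1 <- bs[bs$fish_id == "F1", ]
  expect_equal(f1$n_inspections, 2L)
  expect_equal(f1$mean_event_duration_s, 3)
  expect_equal(f1$prop_time_inspecting, 6 / 420)
  expect_equal(f1$min_inspection_distance_cm, 12)
  expect_equal(f1$mean_inspection_distance_cm, 20)
  # a fish with no events: zero count, zero proportion, absent distances
  f2 <- bs[bs$fish_id == "F2", ]
  expect_equal(f2$n_inspections, 0L)
  expect_equal(f2$prop_time_inspecting, 0)
  expect_true(is.na(f2$min_inspection_distance_cm))
})

test_that("refuge use is one minus the visible fraction of the phase", {
  n <- arena$phase_duration_s * arena$fps
  tr <- labelled(at_distance(40, 0:(2 * n - 1), arena), arena)
  ru <- refuge_use(tr, "before", arena)
  expect_equal(ru$refuge_prop, 0)
  tr$visible <- FALSE
  expect_equal(refuge_use(tr, "during", arena)$refuge_prop, 1)
  expect_error(refuge_use(tr[tr$phase %in% "before", ], "during", arena),
               "window missing")
})

test_that("refuge use matches scheduled hidden fractions exactly", {
  qs <- quick_sim(51, group_sizes = c(5, 20), phase_s = 60)
  for (ph in c("before", "during")) {
    got <- refuge_use(qs$traj, ph, qs$arena)
    want <- qs$sim$ground_truth$refuge
    want <- want[want$phase == ph, ]
    m <- dplyr::inner_join(got, want, by = c("trial_id", "fish_id"))
    expect_equal(nrow(m), 25)
    expect_equal(m$refuge_prop, m$frac_hidden, tolerance = 1e-12)
  }
  # relabelling fish ids leaves the proportions unchanged
  relab <- qs$traj
  relab$fish_id <- paste0("X", relab$fish_id)
  got2 <- refuge_use(relab, "during", qs$arena)
  got1 <- refuge_use(qs$traj, "during", qs$arena)
  expect_equal(sort(got2$refuge_prop), sort(got1$refuge_prop))
})

test_that("overlapping events merge transitively into group inspections", {
  ev <- tibble::tibble(
    trial_id = "T1", fish_id = c("F1", "F2"),
    start_frame = c(100L, 150L), end_frame = c(200L, 300L),
    duration_s = 1, min_distance_cm = 10, mean_distance_cm = 15
  )
  gi <- group_inspections(ev)
  expect_equal(nrow(gi), 1)
  expect_equal(gi$n_inspectors, 2L)
  expect_equal(gi$start_frame, 100L)
  expect_equal(gi$end_frame, 300L)

  # disjoint events of one fish stay separate (touching does not overlap)
  ev2 <- tibble::tibble(
    trial_id = "T1", fish_id = "F1",
    start_frame = c(100L, 200L), end_frame = c(200L, 250L),
    duration_s = 1, min_distance_cm = 10, mean_distance_cm = 15
  )
  expect_equal(group_inspections(ev2)$n_inspectors, c(1L, 1L))
})

test_that("group merging equals interval-graph connected components", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (r in 1:50) {
    n <- sample(2:12, 1)
    start <- sample.int(300, n, replace = TRUE)
    len <- sample.int(80, n, replace = TRUE)
    ev <- tibble::tibble(
      trial_id = "T1", fish_id = sprintf("F%d", sample.int(5, n, TRUE)),
      start_frame = as.integer(start), end_frame = as.integer(start + len),
      duration_s = len / 25, min_distance_cm = 10, mean_distance_cm = 15
    )
    gi <- group_inspections(ev)
    memb <- oracle_interval_components(ev$start_frame, ev$end_frame)
    expect_equal(nrow(gi), length(unique(memb)))
    # component-wise inspector counts agree
    want <- sort(vapply(split(ev$fish_id, memb),
                        function(f) length(unique(f)), integer(1)))
    expect_equal(sort(gi$n_inspectors), unname(want))
  }
})

test_that("event frames are exactly the in-zone visible during frames", {
  qs <- quick_sim(52, group_sizes = 10, phase_s = 60)
  ev <- detect_inspections(qs$traj, qs$arena)
  d <- qs$traj
  d <- d[!is.na(d$phase) & d$phase == "during" & d$visible, ]
  d$dist <- distance_to_predator(d$x, d$y, qs$arena)
  in_event <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(ev))) {
    in_event <- in_event |
      (d$fish_id == ev$fish_id[i] & d$trial_id == ev$trial_id[i] &
         d$frame >= ev$start_frame[i] & d$frame < ev$end_frame[i])
  }
  expect_true(all(d$dist[in_event] <= 30))
  expect_true(all(d$dist[!in_event] > 30))
  # durations bounded by the phase length
  tot <- tapply(ev$duration_s, paste(ev$trial_id, ev$fish_id), sum)
  expect_true(all(tot <= qs$arena$phase_duration_s))
})
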