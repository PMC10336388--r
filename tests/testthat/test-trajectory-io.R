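arena <- test_arena()

write_csv_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

test_that("read_tracking ingests well-formed tracker exports", {
  path <- write_csv_fixture(data.frame(
    frame = 0:2, id = "F1", x = c(10, 11, 12), y = c(20, 20, 21)
  ))
  tr <- read_tracking(path, arena, trial_id = "T1")
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$visible))
  expect_equal(tr$trial_id, rep("T1", 3))
})

test_that("read_tracking flags missing coordinates and bad files", {
  path <- write_csv_fixture(data.frame(
    frame = 0:2, id = "F1", x = c(10, NA, 12), y = c(20, NA, 21)
  ))
  tr <- read_tracking(path, arena)
  expect_equal(tr$visible, c(TRUE, FALSE, TRUE))

  # missing required column
  bad <- write_csv_fixture(data.frame(frame = 0:2, id = "F1", x = 1:3))
  expect_error(read_tracking(bad, arena), "missing required column")

  # duplicated (fish, frame)
  dup <- write_csv_fixture(data.frame(
    frame = c(0, 0), id = "F1", x = c(1, 2), y = c(1, 2)
  ))
  expect_error(read_tracking(dup, arena), "duplicated")

  # non-monotone frames
  unsorted <- write_csv_fixture(data.frame(
    frame = c(2, 0), id = "F1", x = c(1, 2), y = c(1, 2)
  ))
  expect_error(read_tracking(unsorted, arena), "not ascending")

  # out-of-arena coordinates flagged invalid with a warning
  oob <- write_csv_fixture(data.frame(
    frame = 0:1, id = "F1", x = c(10, 400), y = c(10, 10)
  ))
  expect_warning(tr <- read_tracking(oob, arena), "outside the arena")
  expect_equal(tr$visible, c(TRUE, FALSE))
})

test_that("tracking tables survive a write/read round trip", {
  qs <- quick_sim(21, group_sizes = 5, phase_s = 40)
  dir <- withr::local_tempdir()
  write_tracking(qs$sim$trajectories, dir)
  back <- read_tracking(file.path(dir, "T01.csv"), qs$arena, trial_id = "T01")
  orig <- qs$sim$trajectories
  expect_equal(back$visible, orig$visible)
  expect_equal(back$x[back$visible], orig$x[orig$visible], tolerance = 1e-12)
})

test_that("impossible jumps and speeds are excluded", {
  # 60 cm in one frame violates both rules
  tr <- make_traj("T1", "F1", 0:2, c(10, 70, 71), c(10, 10, 10))
  out <- filter_tracks(tr, arena)
  expect_equal(out$visible, c(TRUE, FALSE, FALSE))
  # second point is judged against the first retained point, so the third
  # (61 cm from it) also goes

  # 1 cm steps (25 cm/s) are fine
  tr2 <- make_traj("T1", "F1", 0:2, c(10, 11, 12), c(10, 10, 10))
  expect_true(all(filter_tracks(tr2, arena)$visible))

  # speed rule alone: 30 cm over 10 frames = 75 cm/s, jump under 50 cm
  tr3 <- make_traj("T1", "F1", c(0, 10), c(10, 40), c(10, 10))
  expect_equal(filter_tracks(tr3, arena)$visible, c(TRUE, FALSE))

  # empty table passes through
  expect_equal(nrow(filter_tracks(tr2[0, ], arena)), 0)
})

test_that("filtering removes exactly the injected teleports", {
  qs <- quick_sim(31, group_sizes = c(5, 10), phase_s = 60,
                  teleport_rate = 0.002)
  injected <- qs$sim$ground_truth$teleports
  expect_gt(nrow(injected), 0)
  raw <- qs$sim$trajectories
  filtered <- filter_tracks(raw, qs$arena)
  removed <- raw$visible & !filtered$visible
  got <- filtered[removed, c("trial_id", "fish_id", "frame")]
  expect_setequal(
    paste(got$trial_id, got$fish_id, got$frame),
    paste(injected$trial_id, injected$fish_id, injected$frame)
  )

  # independent frame-by-frame oracle over consecutive retained pairs
  oracle_flags <- function(tr) {
    bad <- integer(0)
    for (g in split(tr, paste(tr$trial_id, tr$fish_id))) {
      g <- g[g$visible, ]
      if (nrow(g) < 2) next
      last <- 1
      for (i in 2:nrow(g)) {
        disp <- sqrt((g$x[i] - g$x[last])^2 + (g$y[i] - g$y[last])^2)
        dt <- (g$frame[i] - g$frame[last]) / arena$fps
        if (disp > 50 || disp / dt > 50) bad <- c(bad, i) else last <- i
      }
    }
    length(bad)
  }
  expect_equal(sum(removed), oracle_flags(raw))
})

test_that("filtering is idempotent and output satisfies both limits", {
  qs <- quick_sim(32, group_sizes = 10, phase_s = 60, teleport_rate = 0.002)
  once <- filter_tracks(qs$sim$trajectories, qs$arena)
  twice <- filter_tracks(once, qs$arena)
  expect_identical(once$visible, twice$visible)
  worst <- once |>
    dplyr::filter(.data$visible) |>
    dplyr::group_by(.data$trial_id, .data$fish_id) |>
    dplyr::summarise(
      max_jump = max(sqrt(diff(.data$x)^2 + diff(.data$y)^2), 0),
      max_speed = max(sqrt(diff(.data$x)^2 + diff(.data$y)^2) /
                        (diff(.data$frame) / 25), 0),
      .groups = "drop"
    )
  expect_lte(max(worst$max_jump), 50)
  expect_lte(max(worst$max_speed), 50)
})

test_that("phase windows follow the screen-lift arithmetic", {
  a <- arena_config()  # 7-minute phases, 30 s delay, 25 fps
  win <- phase_windows(10500, a)
  expect_equal(win$before, c(0, 10500))
  expect_equal(win$during, c(11250, 21750))
  expect_equal(diff(win$before), a$phase_duration_s * a$fps)
  expect_equal(diff(win$during), a$phase_duration_s * a$fps)
  # disjoint
  expect_lte(win$before[2], win$during[1])

  tr <- make_traj("T1", "F1", c(0, 10499, 10500, 11249, 11250, 21749, 21750),
                  x = 20, y = 20)
  lab <- label_phases(tr, 10500, a)
  expect_equal(lab$phase,
               c("before", "before", NA, NA, "during", "during", NA))
  expect_equal(lab$phase_second[5], 0)
  expect_equal(lab$phase_second[6], 419)
})

test_that("short recordings raise a coverage error naming the shortfall", {
  a <- arena_config()
  tr <- make_traj("T1", "F1", 0:100, x = 20, y = 20)
  expect_error(label_phases(tr, 100, a), "shortfall")
  tr2 <- make_traj("T1", "F1", seq(0, 12000, by = 100), x = 20, y = 20)
  expect_error(label_phases(tr2, 10500, a), "shortfall")
})
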