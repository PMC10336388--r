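arena <- arena_config()

test_that("Voronoi cells of symmetric configurations have known areas", {
  # two fish symmetric about the centre split the pool in half
  expect_equal(voronoi_cell_areas(c(50, 100), c(75, 75), arena),
               c(11250, 11250))
  expect_equal(voronoi_density(c(50, 100), c(75, 75), arena), 1 / 11250)
  # four fish at the quadrant centres get a quarter each
  a4 <- voronoi_cell_areas(c(37.5, 112.5, 37.5, 112.5),
                           c(37.5, 37.5, 112.5, 112.5), arena)
  expect_equal(a4, rep(5625, 4))
})

test_that("Voronoi cells partition the arena and match a Monte-Carlo oracle", {
  set.seed(7)
  x <- runif(20, 2, 148)
  y <- runif(20, 2, 148)
  areas <- voronoi_cell_areas(x, y, arena)
  expect_equal(sum(areas), 22500, tolerance = 1e-6)
  # Monte-Carlo nearest-site assignment
  m <- 100000
  gx <- runif(m, 0, 150)
  gy <- runif(m, 0, 150)
  d2 <- outer(gx, x, "-")^2 + outer(gy, y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  mc_areas <- tabulate(nearest, 20) / m * 22500
  expect_lt(sum(abs(mc_areas - areas)) / 22500, 0.01)
})

test_that("degenerate Voronoi inputs are handled", {
  expect_true(is.na(voronoi_density(75, 75, arena)))
  expect_warning(
    a <- voronoi_cell_areas(c(50, 50, 100), c(75, 75, 75), arena),
    "coincident"
  )
  expect_equal(sum(a), 22500, tolerance = 1e-6)
})

test_that("chain-rule clustering follows the 6 cm reachability rule", {
  # chained fish 5 cm apart form one cluster
  expect_equal(subgroups(c(0, 5, 10), c(0, 0, 0)), 3L)
  # two fish 10 cm apart are lone individuals, not a cluster
  expect_equal(subgroups(c(0, 10), c(0, 0)), integer(0))
  expect_equal(subgroups(numeric(0), numeric(0)), integer(0))
})

test_that("clustering equals the proximity-graph components oracle", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (r in 1:100) {
    n <- sample(2:20, 1)
    # mixed scales so some configs chain and others scatter
    x <- runif(n, 0, sample(c(15, 40, 150), 1))
    y <- runif(n, 0, sample(c(15, 40, 150), 1))
    got <- subgroups(x, y, reach_cm = 6)
    want <- oracle_subgroups(x, y, 6)
    expect_equal(got, want)
    # permutation invariance
    p <- sample.int(n)
    expect_equal(subgroups(x[p], y[p], 6), got)
    # cluster sizes bounded by the group, total at most the group
    if (length(got)) {
      expect_true(all(got >= 2 & got <= n))
      expect_lte(sum(got), n)
    }
    # dilating all pairwise distances beyond reach destroys every cluster
    expect_equal(subgroups(x * 100, y * 100, 6), integer(0))
  }
})

test_that("static configurations give flat cohesion series", {
  a <- test_arena(phase_s = 60, delay_s = 0)
  nf <- a$phase_duration_s * a$fps
  frames <- 0:(2 * nf - 1)
  xs <- c(70, 74, 74, 95)
  ys <- c(70, 70, 74, 95)
  tr <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_traj("T1", paste0("F", i), frames, xs[i], ys[i])
  }))
  tr <- label_phases(tr, nf, a)
  ds <- density_series(tr, a)
  expect_equal(nrow(ds), 2)  # 1 minute per phase
  expect_equal(ds$median_density,
               rep(voronoi_density(xs, ys, a), 2))
  sg <- subgroup_series(tr, a)
  expect_equal(sg$median_subgroup_size, c(3, 3))  # F1-F3 chained, F4 lone

  # all fish far apart: sub-group series entirely absent
  tr2 <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_traj("T1", paste0("F", i), frames, 30 * i, 140 - 30 * i)
  }))
  tr2 <- label_phases(tr2, nf, a)
  expect_true(all(is.na(subgroup_series(tr2, a)$median_subgroup_size)))
})

test_that("minute aggregation is the median of per-second medians", {
  a <- test_arena(phase_s = 60, delay_s = 0)
  nf <- a$phase_duration_s * a$fps
  frames <- 0:(2 * nf - 1)
  # two fish alternating each second between 55 and 95 cm apart; the
  # minute value must equal the median of the per-second densities
  sec <- frames %/% a$fps
  offs <- ifelse(sec %% 2 == 0, 55, 95)
  tr <- dplyr::bind_rows(
    make_traj("T1", "F1", frames, 20, 75),
    make_traj("T1", "F2", frames, 20 + offs, 75)
  )
  tr <- label_phases(tr, nf, a)
  ds <- density_series(tr, a)
  d_tight <- voronoi_density(c(20, 75), c(75, 75), a)
  d_loose <- voronoi_density(c(20, 115), c(75, 75), a)
  expect_equal(ds$median_density,
               rep(median(rep(c(d_tight, d_loose), 30)), 2))
})

test_that("series recompute matches a frame-by-frame oracle on synthetic data", {
  qs <- quick_sim(61, group_sizes = 5, phase_s = 60)
  ds <- density_series(qs$traj, qs$arena)
  expect_equal(nrow(ds), 2)
  expect_equal(ds$minute_index, 1:2)
  expect_equal(ds$phase, c("before", "during"))
  # oracle: recompute one minute directly from first-visible positions
  tr <- qs$traj
  tr <- tr[!is.na(tr$phase) & tr$phase == "before" & tr$visible, ]
  per_sec <- sapply(0:59, function(s) {
    g <- tr[tr$phase_second == s, ]
    g <- g[order(g$frame), ]
    g <- g[!duplicated(g$fish_id), ]
    if (nrow(g) < 2) NA_real_ else voronoi_density(g$x, g$y, qs$arena)
  })
  expect_equal(ds$median_density[1], median(per_sec, na.rm = TRUE))
})
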