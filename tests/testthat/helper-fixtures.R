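# Shared fixtures: small arenas and scenarios so trajectory simulations run
# in seconds, plus independent brute-force oracles used across test files.

test_arena <- function(phase_s = 60, delay_s = 30) {
  arena_config(phase_duration_s = phase_s, phase_delay_s = delay_s)
}

# Generate, filter and phase-label a small synthetic experiment.
quick_sim <- function(seed, group_sizes = c(5, 10), n_trials = 1,
                      phase_s = 60, ...) {
  arena <- test_arena(phase_s)
  sc <- trial_scenario(group_sizes = group_sizes,
                       n_trials_per_size = n_trials, arena = arena, ...)
  sim <- generate_trajectories(sc, seed = seed)
  traj <- filter_tracks(sim$trajectories, arena)
  traj <- label_phases(
    traj, stats::setNames(sim$meta$screen_lift_frame, sim$meta$trial_id),
    arena
  )
  list(sim = sim, traj = traj, arena = arena, scenario = sc)
}

# Minimal hand-built trajectory table (already "valid").
make_traj <- function(trial_id, fish_id, frame, x, y, visible = TRUE) {
  tibble::tibble(trial_id = trial_id, fish_id = fish_id,
                 frame = as.integer(frame), x = x, y = y,
                 visible = visible)
}

# Oracle: minimum distance to a polygon by dense boundary sampling.
oracle_poly_distance <- function(px, py, poly, step = 0.01) {
  n <- nrow(poly)
  bx <- c()
  by <- c()
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    len <- sqrt(sum((poly[j, ] - poly[i, ])^2))
    t <- seq(0, 1, by = step / len)
    bx <- c(bx, poly[i, 1] + t * (poly[j, 1] - poly[i, 1]))
    by <- c(by, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
  }
  vapply(seq_along(px), function(k) {
    min(sqrt((bx - px[k])^2 + (by - py[k])^2))
  }, numeric(1))
}

# Oracle: chain-rule sub-grouping as connected components of the proximity
# graph (igraph), singletons dropped.
oracle_subgroups <- function(x, y, reach) {
  n <- length(x)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    (x[i] - x[j])^2 + (y[i] - y[j])^2 <= reach^2
  })
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  sizes <- igraph::components(g)$csize
  sort(as.integer(sizes[sizes >= 2]), decreasing = TRUE)
}

# Oracle: transitive interval-overlap grouping as graph components.
oracle_interval_components <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    start[i] < end[j] & start[j] < end[i]   # half-open overlap
  })
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# Oracle: expected volunteer/defect payoffs by exhaustive enumeration of
# all 2^(n-1) co-player outcomes.
oracle_vd_payoffs <- function(game, p) {
  n <- game$n
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n - 1)))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  k <- rowSums(outcomes)
  ben <- function(kk) shoalspect:::benefit_k(game, kk)
  c_eff <- shoalspect:::base_cost(game)
  pay_v <- if (game$variant == "shared_cost") {
    sum(probs * (ben(k + 1) - c_eff / (k + 1)))
  } else {
    sum(probs * ben(k + 1)) - c_eff
  }
  pay_d <- sum(probs * ben(k))
  c(volunteer = pay_v, defect = pay_d)
}

# A fake fitted-model object with fixed posterior draws, for closed-form
# checks of the contrast machinery.
fake_fit <- function(draws, family = "poisson", b_sd = 1) {
  structure(
    list(draws = draws, X_names = colnames(draws),
         spec = list(family = family, include_phase = FALSE,
                     priors = list(b_sd = b_sd)),
         centers = c(temperature_c = 0, mean_length_mm = 0),
         n_obs = nrow(draws), n_trials = 2, rhat = NULL, ess = NULL),
    class = "shoal_glmm"
  )
}
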