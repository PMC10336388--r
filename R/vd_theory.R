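#' Define a volunteer's dilemma game
#'
#' In the volunteer's dilemma a single volunteer suffices to produce a
#' public good worth `benefit` to every group member; volunteering costs
#' `cost`, and if nobody volunteers everyone forgoes the benefit (payoffs:
#' a volunteer gets `benefit - cost`; a defector gets `benefit` if at
#' least one other volunteers, otherwise 0). With `0 < cost < benefit`
#' the evolutionarily stable state is a mixed strategy.
#'
#' Variants modify the payoff structure:
#' \describe{
#'   \item{`baseline`}{the classic game above.}
#'   \item{`groupsize_cost`}{the volunteering cost declines with group
#'     size: `c(n) = cost * n^(-cost_exponent) * exp(-cost_decay * (n - 2)^2)`.
#'     A power-law decline (`cost_exponent`) never overturns the decline of
#'     volunteering with group size — the `(1 - p)^(n - 1)` term always
#'     wins — but a superexponential decline (`cost_decay > 0`) can make
#'     volunteering rise with group size over a range.}
#'   \item{`shared_cost`}{the realized cost is split equally among the
#'     volunteers, `cost / k` for `k` volunteers.}
#'   \item{`synergy`}{the good's value grows with the number of
#'     volunteers, `benefit * (1 + synergy_slope * (k - 1)^synergy_power)`
#'     for `k >= 1` volunteers. With accelerating returns
#'     (`synergy_power > 1`) the game becomes bistable in large groups:
#'     full volunteering can be stable for large `n` while small groups
#'     sustain only a low mixed equilibrium, reversing the group-size
#'     ordering.}
#' }
#'
#' @param n Group size (integer >= 2).
#' @param cost Cost of volunteering (payoff units), `0 < cost < benefit`.
#' @param benefit Value of the public good to each member.
#' @param variant One of `"baseline"`, `"shared_cost"`,
#'   `"groupsize_cost"`, `"synergy"`.
#' @param variant_params Named list of variant parameters (see above).
#' @return A `vd_game` object.
#' @export
vd_game <- function(n, cost, benefit, variant = c("baseline", "shared_cost",
                                                  "groupsize_cost", "synergy"),
                    variant_params = list()) {
  variant <- match.arg(variant)
  if (n != round(n) || n < 2) stop("n must be an integer >= 2")
  if (cost <= 0) stop("cost must be positive")
  if (cost >= benefit) stop("no dilemma: cost must be smaller than benefit")
  defaults <- list(cost_exponent = 1, cost_decay = 0,
                   synergy_slope = 0.1, synergy_power = 2)
  vp <- utils::modifyList(defaults, variant_params)
  structure(
    list(n = as.integer(n), cost = cost, benefit = benefit,
         variant = variant, variant_params = vp),
    class = "vd_game"
  )
}

# Effective volunteering cost before any sharing.
base_cost <- function(game) {
  if (game$variant == "groupsize_cost") {
    vp <- game$variant_params
    game$cost * game$n^(-vp$cost_exponent) *
      exp(-vp$cost_decay * (game$n - 2)^2)
  } else {
    game$cost
  }
}

# Benefit to a group member when k group members volunteered.
benefit_k <- function(game, k) {
  b <- game$benefit
  if (game$variant == "synergy") {
    vp <- game$variant_params
    ifelse(k >= 1,
           b * (1 + vp$synergy_slope * (k - 1)^vp$synergy_power), 0)
  } else {
    ifelse(k >= 1, b, 0)
  }
}

#' Expected payoffs of volunteering and defecting
#'
#' Given that each of the other `n - 1` players volunteers independently
#' with probability `p`, returns the focal player's expected payoff for
#' volunteering and for defecting, summing analytically over the binomial
#' number of co-volunteers.
#'
#' @param game A [vd_game()].
#' @param p Probability each other player volunteers.
#' @return Named vector `c(volunteer = , defect = )`.
#' @export
vd_payoffs <- function(game, p) {
  k <- 0:(game$n - 1)                  # co-volunteers among the others
  w <- stats::dbinom(k, game$n - 1, p)
  c_eff <- base_cost(game)
  pay_v <- if (game$variant == "shared_cost") {
    sum(w * (benefit_k(game, k + 1) - c_eff / (k + 1)))
  } else {
    sum(w * benefit_k(game, k + 1)) - c_eff
  }
  pay_d <- sum(w * benefit_k(game, k))
  c(volunteer = pay_v, defect = pay_d)
}

#' Solve the mixed-ESS volunteering probability
#'
#' At a mixed evolutionarily stable state each individual volunteers with
#' the probability `p` that makes volunteering and defecting
#' payoff-equivalent. The baseline game (and the group-size-dependent-cost
#' variant, which only rescales the cost) has the closed form
#' `1 - p = (c/b)^(1/(n-1))`. Other variants are solved numerically on the
#' indifference condition (payoff of volunteering minus defecting) to an
#' absolute payoff-difference tolerance better than 1e-10: the payoff gap
#' is scanned over a fine grid of `p`, stable equilibria are the points
#' where it crosses from positive to negative (plus the boundaries `p = 0`
#' when the gap starts negative and `p = 1` when it ends positive), and
#' the highest stable equilibrium is returned — relevant for synergy
#' games, which can be bistable.
#'
#' @param game A [vd_game()].
#' @return List: `p_volunteer`, `p_good` (probability at least one group
#'   member volunteers, `1 - (1 - p)^n`), `expected_volunteers` (`n p`).
#' @export
solve_ess <- function(game) {
  n <- game$n
  gap <- function(p) {
    pay <- vd_payoffs(game, p)
    unname(pay["volunteer"] - pay["defect"])
  }
  if (game$variant %in% c("baseline", "groupsize_cost")) {
    ratio <- base_cost(game) / game$benefit
    p <- if (ratio >= 1) 0 else 1 - ratio^(1 / (n - 1))
  } else {
    grid <- seq(0, 1, by = 0.001)
    g <- vapply(grid, gap, numeric(1))
    stable <- numeric(0)
    if (g[1] <= 0) stable <- 0
    if (g[length(g)] >= 0) stable <- c(stable, 1)
    down <- which(g[-length(g)] > 0 & g[-1] <= 0)
    for (i in down) {
      stable <- c(stable,
                  stats::uniroot(gap, grid[c(i, i + 1)], tol = 1e-14)$root)
    }
    p <- max(stable)
  }
  list(
    p_volunteer = p,
    p_good = 1 - (1 - p)^n,
    expected_volunteers = n * p
  )
}

#' ESS volunteering across group sizes
#'
#' Solves the mixed ESS for each group size in `n_range` and reports the
#' monotonicity of the per-individual volunteering probability and of the
#' probability that the good is produced (the classic prediction is that
#' both decline with group size; cost and synergy variants can reverse the
#' individual-level ordering).
#'
#' @param variant Game variant (see [vd_game()]).
#' @param cost,benefit Payoff parameters.
#' @param variant_params Variant parameters.
#' @param n_range Integer group sizes (subset of 2..50).
#' @return A tibble `n`, `p_volunteer`, `p_good`, `expected_volunteers`,
#'   with a `monotonicity` attribute: signs of successive differences of
#'   `p_volunteer` and `p_good`.
#' @export
predict_group_size_curve <- function(variant = "baseline", cost, benefit,
                                     variant_params = list(),
                                     n_range = c(5, 10, 20)) {
  stopifnot(all(n_range >= 2 & n_range <= 50))
  res <- purrr::map_dfr(n_range, function(n) {
    ess <- solve_ess(vd_game(n, cost, benefit, variant, variant_params))
    tibble::tibble(n = n, p_volunteer = ess$p_volunteer, p_good = ess$p_good,
                   expected_volunteers = ess$expected_volunteers)
  })
  attr(res, "monotonicity") <- list(
    p_volunteer = sign(diff(res$p_volunteer)),
    p_good = sign(diff(res$p_good))
  )
  res
}

#' Monte-Carlo check of a volunteering equilibrium
#'
#' Simulates independent Bernoulli volunteering decisions and returns the
#' empirical probability that the public good is produced (at least one
#' volunteer) and the mean number of volunteers.
#'
#' @param game A [vd_game()].
#' @param p Per-individual volunteering probability.
#' @param reps Number of simulated groups.
#' @param seed RNG seed.
#' @return List: `p_good`, `mean_volunteers`, `reps`.
#' @export
simulate_vd <- function(game, p, reps = 1e4, seed = 1) {
  stopifnot(reps >= 1, p >= 0, p <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k <- stats::rbinom(reps, game$n, p)
  list(p_good = mean(k >= 1), mean_volunteers = mean(k), reps = reps)
}

# Save/restore global RNG state so simulation helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
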