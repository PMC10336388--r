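test_that("the HDI is the narrowest interval holding the requested mass", {
  set.seed(1)
  x <- runif(20000)
  h <- hdi(x, 0.89)
  expect_equal(h[2] - h[1], 0.89, tolerance = 0.01)
  # narrower than (or equal to) the central quantile interval
  skewed <- rexp(20000)
  h2 <- hdi(skewed, 0.89)
  central <- unname(quantile(skewed, c(0.055, 0.945)))
  expect_lte(h2[2] - h2[1], central[2] - central[1])
  expect_gte(mean(skewed >= h2[1] & skewed <= h2[2]), 0.889)
})

test_that("Savage-Dickey ratios behave at and far from the null", {
  set.seed(2)
  # posterior identical to the prior: no evidence either way
  sd0 <- savage_dickey_bf(rnorm(20000, 0, 1), prior_sd = 1)
  expect_lt(sd0$bayes_factor, 1.1)
  # posterior far from zero: overwhelming evidence for the effect
  sd1 <- savage_dickey_bf(rnorm(20000, 3, 0.5), prior_sd = 1)
  expect_equal(sd1$direction, "for")
  expect_gte(sd1$bayes_factor, 1e4)
  # posterior concentrated at zero relative to a wide prior: against
  sd2 <- savage_dickey_bf(rnorm(20000, 0, 0.1), prior_sd = 3)
  expect_equal(sd2$direction, "against")
  expect_gt(sd2$bayes_factor, 5)
})

test_that("Savage-Dickey matches the analytic conjugate normal Bayes factor", {
  # y_i ~ N(theta, s^2), theta ~ N(0, tau^2): both the marginal-likelihood
  # ratio and the prior/posterior density ratio at 0 are closed-form
  # kept in the moderate-evidence regime: a Silverman-bandwidth KDE is
  # biased in the far tail, so agreement to 5% holds where the null lies
  # within the posterior bulk
  set.seed(3)
  for (r in 1:5) {
    n <- 10
    s <- 1
    tau <- 1
    theta_true <- runif(1, -0.25, 0.25)
    y <- rnorm(n, theta_true, s)
    v <- 1 / (1 / tau^2 + n / s^2)
    m <- v * sum(y) / s^2
    if (abs(m) / sqrt(v) > 2) next  # stay inside the KDE's accurate regime
    analytic <- dnorm(mean(y), 0, s / sqrt(n)) /
      dnorm(mean(y), 0, sqrt(tau^2 + s^2 / n))
    analytic_for <- 1 / analytic
    got <- savage_dickey_bf(rnorm(10000, m, sqrt(v)), prior_sd = tau)
    got_for <- got$bf_for
    expect_equal(got_for, analytic_for, tolerance = 0.05)
  }
})

test_that("Bayes factors are classified into the stated evidence bands", {
  expect_equal(classify_bf(1), "weak")
  expect_equal(classify_bf(2.9), "weak")
  expect_equal(classify_bf(3), "moderate")
  expect_equal(classify_bf(9.5), "moderate")
  expect_equal(classify_bf(10), "strong")
  expect_equal(classify_bf(29), "strong")
  expect_equal(classify_bf(68), "very strong")
  expect_equal(classify_bf(100), "very strong")
  expect_equal(classify_bf(101), "extreme")
  expect_error(classify_bf(0.5))
})

test_that("marginal contrasts back-transform exactly for fixed draws", {
  draws <- cbind("(Intercept)" = rep(log(2), 500),
                 "gsintermediate" = rep(0, 500),
                 "gslarge" = rep(log(4), 500))
  fit <- fake_fit(draws, family = "poisson")
  mc <- marginal_contrast(fit, "small", "large")
  expect_equal(mc$marginal_effect, 6)
  expect_equal(unname(mc$hdi), c(6, 6))
  # identical levels: exactly zero
  mc0 <- marginal_contrast(fit, "small", "intermediate")
  expect_equal(mc0$marginal_effect, 0)
  # the link's monotonicity is preserved in every draw
  set.seed(4)
  draws2 <- cbind("(Intercept)" = rnorm(2000),
                  "gsintermediate" = rnorm(2000),
                  "gslarge" = rnorm(2000))
  fit2 <- fake_fit(draws2, family = "poisson")
  mc2 <- marginal_contrast(fit2, "small", "large")
  expect_equal(mc2$draws > 0, draws2[, "gslarge"] > 0)
})

test_that("a fitted Poisson GLMM recovers a known group-size effect", {
  gb <- generate_behavior_table(
    list(family = "poisson", intercept = 1.5, b_intermediate = 0,
         b_large = 0.8, sigma_trial = 0.25),
    seed = 8
  )
  fit <- fit_glmm(gb$data, model_spec("response", "poisson"),
                  mcmc = list(chains = 2, iter = 2000, seed = 8))
  # link-scale HDI covers the simulated log-rate ratio
  h <- hdi(fit$draws[, "gslarge"], 0.89)
  expect_gt(0.8, h[1])
  expect_lt(0.8, h[2])
  ps <- posterior_summary(fit)
  expect_equal(nrow(ps), 3)
  expect_true(all(ps$bayes_factor >= 1))
  expect_true(all(ps$hdi_lo <= ps$marginal_effect &
                    ps$marginal_effect <= ps$hdi_hi))
  # strong simulated effect: evidence lands in favour
  expect_equal(ps$bf_direction[ps$contrast == "intermediate → large"], "for")
})

test_that("precondition and convergence failures are reported", {
  gb <- generate_behavior_table(
    list(family = "poisson", intercept = 1, b_intermediate = 0, b_large = 0),
    design = list(n_trials_per_size = 1, group_sizes = 5), seed = 9
  )
  expect_error(
    fit_glmm(gb$data, model_spec("response", "poisson")),
    "at least 2 trials"
  )
  gb2 <- generate_behavior_table(
    list(family = "poisson", intercept = 1, b_intermediate = 0, b_large = 0,
         sigma_trial = 0.2),
    seed = 10
  )
  fit1 <- fit_glmm(gb2$data, model_spec("response", "poisson"),
                   mcmc = list(chains = 1, iter = 500, seed = 1))
  expect_error(check_convergence(fit1), "at least 2 chains")
  fit2 <- fit_glmm(gb2$data, model_spec("response", "poisson"),
                   mcmc = list(chains = 2, iter = 3000, seed = 1))
  # a clean fit of this size passes the R-hat gate
  expect_silent(check_convergence(fit2, rhat_max = 1.05, ess_min = 50))
  expect_error(check_convergence(fit2, rhat_max = 0.999), "did not converge")
})

test_that("beta responses on the boundary are squeezed, not rejected", {
  gb <- generate_behavior_table(
    list(family = "beta", intercept = 0, b_intermediate = 0.3,
         b_large = -0.3, sigma_trial = 0.2, kappa = 8),
    seed = 11
  )
  gb$data$response[1:3] <- c(0, 1, 1)
  fit <- fit_glmm(gb$data, model_spec("response", "beta", context = "refuge"),
                  mcmc = list(chains = 1, iter = 800, seed = 2))
  expect_s3_class(fit, "shoal_glmm")
  ps <- posterior_summary(fit)
  expect_true(all(is.finite(ps$marginal_effect)))
})

test_that("the squared-exponential kernel has the right limits", {
  m <- 1:14
  # infinite length-scale: the smooth degenerates to a single offset
  k_flat <- gp_cov(m, amplitude = 2, lengthscale = 1e8)
  expect_lt(max(k_flat) - min(k_flat), 1e-6)
  # zero amplitude: no temporal structure at all
  k0 <- gp_cov(m, amplitude = 0, lengthscale = 3, jitter = 0)
  expect_equal(max(abs(k0)), 0)
  # a proper covariance: symmetric positive semi-definite
  k <- gp_cov(m, amplitude = 1.3, lengthscale = 2.5)
  expect_equal(k, t(k))
  expect_gte(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("the GP smooth improves one-step prediction on autocorrelated series", {
  # AR(1) series; closed-form GP conditioning with the package kernel vs a
  # constant (intercept-only) predictor, one-step-ahead log density
  set.seed(12)
  wins <- replicate(100, {
    n <- 14
    e <- as.numeric(arima.sim(list(ar = 0.7), n, sd = 0.5))
    train <- 1:(n - 1)
    K <- gp_cov(1:n, amplitude = sd(e[train]), lengthscale = 2) +
      diag(0.1, n)
    mu <- K[n, train] %*% solve(K[train, train], e[train])
    v <- K[n, n] - K[n, train] %*% solve(K[train, train], K[train, n])
    lp_gp <- dnorm(e[n], mu, sqrt(v), log = TRUE)
    lp_flat <- dnorm(e[n], mean(e[train]),
                     sd(e[train]) * sqrt(1 + 1 / (n - 1)), log = TRUE)
    lp_gp - lp_flat
  })
  expect_gt(mean(wins), 0)
})

test_that("shrinking the GP amplitude to zero recovers the plain GLMM", {
  gb <- generate_behavior_table(
    list(family = "poisson", intercept = 1.2, b_intermediate = 0.2,
         b_large = 0.5, sigma_trial = 0.2),
    seed = 13
  )
  d <- gb$data
  set.seed(13)
  d$minute_index <- sample.int(14, nrow(d), replace = TRUE)
  mcmc <- list(chains = 1, adapt = 500, burn = 500, iter = 4000, seed = 3)
  fit_plain <- fit_glmm(d, model_spec("response", "poisson"), mcmc)
  fit_gp0 <- fit_glmm(
    d, model_spec("response", "poisson", gp_time = TRUE,
                  priors = list(gp_amp_sd = 1e-6)),
    mcmc
  )
  w1 <- fit_plain$draws[, "gslarge"]
  w2 <- fit_gp0$draws[, "gslarge"]
  # Gaussian KL between the two contrast posteriors is tiny
  kl <- log(sd(w2) / sd(w1)) + (sd(w1)^2 + (mean(w1) - mean(w2))^2) /
    (2 * sd(w2)^2) - 0.5
  expect_lt(kl, 0.01)
  # and the GP function draws collapse to the kernel's jitter floor
  fcols <- grep("^f\\[", colnames(fit_gp0$draws))
  expect_lt(max(abs(fit_gp0$draws[, fcols])), 0.02)
})

test_that("the inspectors GLM estimates per-level log means", {
  meta <- tibble::tibble(trial_id = c("T1", "T2", "T3"),
                         group_size = c(5, 10, 20))
  groups <- tibble::tibble(
    trial_id = rep(c("T1", "T2", "T3"), each = 4),
    start_frame = 1L, end_frame = 2L, inspector_ids = list("F1"),
    n_inspectors = rep(2L, 12)
  )
  cf <- fit_inspectors_glm(groups, meta)
  expect_equal(cf$level, c("small", "intermediate", "large"))
  expect_equal(unname(cf$estimate), rep(log(2), 3), tolerance = 1e-6)

  # simulated Poisson party sizes recover their log means within 2 SE
  set.seed(14)
  mu <- c(2.5, 3.7, 5.5)
  groups2 <- tibble::tibble(
    trial_id = rep(c("T1", "T2", "T3"), each = 200),
    start_frame = 1L, end_frame = 2L, inspector_ids = list("F1"),
    n_inspectors = pmax(1L, as.integer(rpois(600, rep(mu, each = 200))))
  )
  cf2 <- fit_inspectors_glm(groups2, meta)
  expect_true(all(abs(cf2$estimate - log(mu)) < 2.5 * cf2$se + 0.05))

  # a level with no events cannot be estimated
  expect_error(
    fit_inspectors_glm(groups[groups$trial_id != "T3", ], meta),
    "singular fit"
  )
})
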