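#' Specify a Bayesian GLMM for a behaviour response
#'
#' Builds the model specification used by [fit_glmm()]: response family,
#' fixed effects (experimental group size as a three-level factor with
#' water temperature and mean fish length as covariates, optionally phase
#' and its interaction with group size), a trial-level random intercept,
#' an optional Gaussian-process smooth over the minute index, and the
#' weakly-informative prior scales.
#'
#' Default prior scales follow the analysis the pipeline reproduces:
#' Poisson models use N(0, 1) for coefficients and the random-intercept SD;
#' Beta models for inspection metrics use N(0, 3) for coefficients and SD
#' and N(0, 5) for the precision kappa; Beta models for refuge use and the
#' cohesion time series use N(0, 1) and N(0, 20); Gamma models use N(0, 1)
#' for the shape alpha, intercept and slopes. Scale-type parameters (SD,
#' kappa, alpha) are positive, so their normal priors are truncated at
#' zero (half-normal).
#'
#' @param response Name of the response column.
#' @param family `"poisson"`, `"beta"` or `"gamma"`.
#' @param context `"inspection"` or `"refuge"`: selects the Beta prior set
#'   (ignored for other families).
#' @param include_phase Add phase and group-size x phase interaction fixed
#'   effects (refuge and cohesion models).
#' @param gp_time Add a zero-mean Gaussian-process smooth over the minute
#'   index (squared-exponential kernel) to absorb temporal autocorrelation
#'   in the cohesion time series.
#' @param priors Optional named list overriding `b_sd`, `sigma_sd`,
#'   `kappa_sd`, `alpha_sd`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(response,
                       family = c("poisson", "beta", "gamma"),
                       context = c("inspection", "refuge"),
                       include_phase = FALSE,
                       gp_time = FALSE,
                       priors = NULL) {
  family <- match.arg(family)
  context <- match.arg(context)
  p <- switch(family,
    poisson = list(b_sd = 1, sigma_sd = 1),
    beta = if (context == "inspection") {
      list(b_sd = 3, sigma_sd = 3, kappa_sd = 5)
    } else {
      list(b_sd = 1, sigma_sd = 1, kappa_sd = 20)
    },
    gamma = list(b_sd = 1, sigma_sd = 1, alpha_sd = 1)
  )
  if (gp_time) {
    p$gp_amp_sd <- 1   # marginal SD of the temporal smooth (link scale)
    p$gp_ls_sd <- 4    # half-normal scale of the GP length-scale (minutes)
  }
  if (!is.null(priors)) p[names(priors)] <- priors
  structure(
    list(response = response, family = family, context = context,
         include_phase = include_phase, gp_time = gp_time, priors = p),
    class = "model_spec"
  )
}

group_size_factor <- function(group_size) {
  labels <- c("5" = "small", "10" = "intermediate", "20" = "large")
  f <- labels[as.character(group_size)]
  if (any(is.na(f))) stop("group_size must be 5, 10 or 20")
  factor(f, levels = c("small", "intermediate", "large"))
}

inv_link <- function(family) {
  switch(family,
    poisson = exp,
    gamma = exp,
    beta = function(eta) 1 / (1 + exp(-eta))
  )
}

# Squeeze proportions off the [0, 1] boundary (standard beta-regression
# transform): y' = (y (n - 1) + 0.5) / n.
squeeze_proportions <- function(y) {
  n <- sum(!is.na(y))
  (y * (n - 1) + 0.5) / n
}

# JAGS program for the GLMM. Trial-constant fixed effects are folded into
# the random-intercept mean (hierarchical centring, which mixes much better
# under Gibbs sampling than the offset parameterization); observation-level
# columns (phase terms) stay in the per-row predictor.
jags_model_string <- function(spec, has_varying) {
  lik <- switch(spec$family,
    poisson = "    y[i] ~ dpois(exp(eta[i]))",
    beta = paste0(
      "    mu[i] <- 1 / (1 + exp(-eta[i]))\n",
      "    y[i] ~ dbeta(mu[i] * kappa + 1.0E-6, (1 - mu[i]) * kappa + 1.0E-6)"
    ),
    gamma = paste0(
      "    mu[i] <- exp(eta[i])\n",
      "    y[i] ~ dgamma(alpha, alpha / mu[i])"
    )
  )
  gp_eta <- if (spec$gp_time) " + f[minute[i]]" else ""
  gp_block <- if (spec$gp_time) paste0(
    "  for (m in 1:M) { mu_f[m] <- 0 }\n",
    "  for (m in 1:M) {\n",
    "    for (mm in 1:M) {\n",
    "      Sig[m, mm] <- gp_amp^2 * exp(-0.5 * pow((m - mm) / gp_ls, 2)) + (m == mm) * 1.0E-6\n",
    "    }\n",
    "  }\n",
    "  Om[1:M, 1:M] <- inverse(Sig[1:M, 1:M])\n",
    "  f[1:M] ~ dmnorm(mu_f[], Om[, ])\n",
    "  gp_amp ~ dnorm(0, pow(gp_amp_sd, -2)) T(0,)\n",
    "  gp_ls ~ dnorm(0, pow(gp_ls_sd, -2)) T(0.5,)\n"
  ) else ""
  disp <- switch(spec$family,
    poisson = "",
    beta = "  kappa ~ dnorm(0, pow(kappa_sd, -2)) T(0,)\n",
    gamma = "  alpha ~ dnorm(0, pow(alpha_sd, -2)) T(0,)\n"
  )
  v_eta <- if (has_varying) " + inprod(Xv[i, ], beta_v[])" else ""
  v_prior <- if (has_varying) {
    "  for (k in 1:Pv) { beta_v[k] ~ dnorm(0, pow(b_sd, -2)) }\n"
  } else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    eta[i] <- a[trial[i]]", v_eta, gp_eta, "\n",
    lik, "\n",
    "  }\n",
    "  for (j in 1:J) {\n",
    "    a[j] ~ dnorm(inprod(Xt[j, ], beta_t[]), pow(sigma, -2))\n",
    "  }\n",
    "  for (k in 1:Pt) { beta_t[k] ~ dnorm(0, pow(b_sd, -2)) }\n",
    v_prior,
    "  sigma ~ dnorm(0, pow(sigma_sd, -2)) T(0,)\n",
    disp, gp_block,
    "}\n"
  )
}

#' Fit a Bayesian GLMM by MCMC
#'
#' Fits the specified model with a trial-level random intercept via Gibbs
#' sampling (JAGS). Fixed effects are experimental group size (three-level
#' factor, treatment coding with "small" as reference), water temperature
#' and mean fish length (both centred at their sample means), plus phase
#' and its interaction with group size when `spec$include_phase` is set.
#' Rows with missing response are dropped (e.g. distance metrics of fish
#' that never inspected). Beta responses on the [0, 1] boundary are
#' squeezed off it first.
#'
#' @param data A behaviour table: the response column plus `group_size`,
#'   `temperature_c`, `mean_length_mm`, `trial_id`, and `phase` /
#'   `minute_index` where the model requires them.
#' @param spec A [model_spec()].
#' @param mcmc Named list: `chains` (default 2), `adapt` (500), `burn`
#'   (500), `iter` post-warmup draws per chain (2000), `seed` (1).
#' @return A `shoal_glmm` object: posterior draw matrix (coefficients on
#'   the link scale, random-intercept SD `sigma`, dispersion, any GP
#'   terms), design metadata, and convergence diagnostics (split R-hat,
#'   effective sample sizes).
#' @export
fit_glmm <- function(data, spec, mcmc = list()) {
  mc <- utils::modifyList(
    list(chains = 2, adapt = 500, burn = 500, iter = 2000, seed = 1), mcmc
  )
  data <- data[!is.na(data[[spec$response]]), ]
  if (length(unique(data$trial_id)) < 2) {
    stop("at least 2 trials are required to fit the trial random intercept")
  }
  y <- data[[spec$response]]
  if (spec$family == "beta" && (any(y <= 0) || any(y >= 1))) {
    y <- squeeze_proportions(y)
  }
  if (spec$family == "poisson" && any(y < 0 | y != round(y))) {
    stop("poisson family requires non-negative integer response")
  }
  if (spec$family == "gamma" && any(y <= 0)) {
    stop("gamma family requires strictly positive response")
  }

  df <- data.frame(
    gs = group_size_factor(data$group_size),
    temp_c = data$temperature_c - mean(data$temperature_c),
    len_c = data$mean_length_mm - mean(data$mean_length_mm)
  )
  centers <- c(temperature_c = mean(data$temperature_c),
               mean_length_mm = mean(data$mean_length_mm))
  form <- ~ gs + temp_c + len_c
  if (spec$include_phase) {
    df$phase <- factor(data$phase, levels = c("before", "during"))
    form <- ~ gs * phase + temp_c + len_c
  }
  X <- stats::model.matrix(form, df)
  trial <- as.integer(factor(data$trial_id))
  J <- max(trial)

  # columns constant within trial go into the random-intercept mean
  varying <- vapply(seq_len(ncol(X)), function(k) {
    any(tapply(X[, k], trial, function(v) max(v) - min(v)) > 0)
  }, logical(1))
  first_row <- match(seq_len(J), trial)
  Xt <- X[first_row, !varying, drop = FALSE]
  Xv <- X[, varying, drop = FALSE]

  jdata <- list(
    y = y, Xt = Xt, Pt = ncol(Xt), N = nrow(X), trial = trial,
    J = J, b_sd = spec$priors$b_sd, sigma_sd = spec$priors$sigma_sd
  )
  monitors <- c("beta_t", "sigma")
  if (any(varying)) {
    jdata$Xv <- Xv
    jdata$Pv <- ncol(Xv)
    monitors <- c(monitors, "beta_v")
  }
  if (spec$family == "beta") {
    jdata$kappa_sd <- spec$priors$kappa_sd
    monitors <- c(monitors, "kappa")
  }
  if (spec$family == "gamma") {
    jdata$alpha_sd <- spec$priors$alpha_sd
    monitors <- c(monitors, "alpha")
  }
  if (spec$gp_time) {
    if (!"minute_index" %in% names(data)) {
      stop("gp_time models need a minute_index column")
    }
    jdata$minute <- as.integer(data$minute_index)
    jdata$M <- max(jdata$minute)
    jdata$gp_amp_sd <- spec$priors$gp_amp_sd
    jdata$gp_ls_sd <- spec$priors$gp_ls_sd
    monitors <- c(monitors, "f", "gp_amp", "gp_ls")
  }

  inits <- lapply(seq_len(mc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mc$seed %% 2000000L) * 1000L + ch)
  })
  model <- rjags::jags.model(
    textConnection(jags_model_string(spec, any(varying))),
    data = jdata, inits = inits, n.chains = mc$chains,
    n.adapt = mc$adapt, quiet = TRUE
  )
  stats::update(model, mc$burn, progress.bar = "none")
  samp <- rjags::coda.samples(model, monitors, n.iter = mc$iter,
                              progress.bar = "none")

  draws <- do.call(rbind, lapply(samp, as.matrix))
  colnames(draws)[grep("^beta_t\\[", colnames(draws))] <- colnames(Xt)
  if (any(varying)) {
    colnames(draws)[grep("^beta_v\\[", colnames(draws))] <- colnames(Xv)
  }

  rhat <- if (mc$chains >= 2) {
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (inherits(gd, "try-error")) NULL else stats::setNames(
      gd$psrf[, 1], colnames(draws)[seq_len(nrow(gd$psrf))]
    )
  } else NULL
  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) NULL)
  if (!is.null(ess) && length(ess) == ncol(draws)) {
    names(ess) <- colnames(draws)
  }

  structure(
    list(
      draws = draws, spec = spec, X_names = colnames(X),
      centers = centers, n_obs = nrow(X),
      n_trials = max(trial), mcmc = mc, rhat = rhat, ess = ess
    ),
    class = "shoal_glmm"
  )
}

#' @export
print.shoal_glmm <- function(x, ...) {
  cat(sprintf(
    "<shoal_glmm> %s (%s family), %d obs, %d trials, %d draws\n",
    x$spec$response, x$spec$family, x$n_obs, x$n_trials, nrow(x$draws)
  ))
  if (!is.null(x$rhat)) {
    cat(sprintf("  max split R-hat %.3f, min ESS %.0f\n",
                max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE)))
  }
  invisible(x)
}

#' Gate on MCMC convergence
#'
#' Errors, listing the offending R-hat values, when any monitored
#' parameter's split R-hat exceeds `rhat_max` or any effective sample size
#' falls below `ess_min`.
#'
#' @param fit A `shoal_glmm`.
#' @param rhat_max Maximum acceptable split R-hat. Default 1.01.
#' @param ess_min Minimum acceptable effective sample size. Default 400.
#' @return `fit`, invisibly, if diagnostics pass.
#' @export
check_convergence <- function(fit, rhat_max = 1.01, ess_min = 400) {
  if (is.null(fit$rhat)) {
    stop("convergence check needs at least 2 chains")
  }
  bad_r <- fit$rhat[!is.na(fit$rhat) & fit$rhat > rhat_max]
  bad_e <- fit$ess[!is.na(fit$ess) & fit$ess < ess_min]
  if (length(bad_r) || length(bad_e)) {
    stop(
      "MCMC did not converge: ",
      if (length(bad_r)) paste0("R-hat > ", rhat_max, ": ",
        paste(sprintf("%s=%.3f", names(bad_r), bad_r), collapse = ", ")),
      if (length(bad_r) && length(bad_e)) "; ",
      if (length(bad_e)) paste0("ESS < ", ess_min, ": ",
        paste(sprintf("%s=%.0f", names(bad_e), bad_e), collapse = ", "))
    )
  }
  invisible(fit)
}

#' Squared-exponential Gaussian-process covariance over minutes
#'
#' The kernel used by the time-series models' temporal smooth:
#' `K(m, m') = amplitude^2 exp(-(m - m')^2 / (2 lengthscale^2))`.
#'
#' @param minutes Integer vector of minute indices.
#' @param amplitude Marginal SD of the smooth.
#' @param lengthscale Correlation length in minutes.
#' @param jitter Diagonal stabiliser. Default 1e-9.
#' @return Covariance matrix.
#' @export
gp_cov <- function(minutes, amplitude, lengthscale, jitter = 1e-9) {
  d <- outer(minutes, minutes, "-")
  amplitude^2 * exp(-0.5 * (d / lengthscale)^2) + diag(jitter, length(minutes))
}

# Design row (on the X columns) for a group-size level at the reference
# covariates (sample-mean temperature and length, random intercept 0).
level_design <- function(fit, level, phase = NULL) {
  x0 <- stats::setNames(numeric(length(fit$X_names)), fit$X_names)
  x0["(Intercept)"] <- 1
  lev_col <- paste0("gs", level)
  if (lev_col %in% names(x0)) x0[lev_col] <- 1
  if (!is.null(phase) && phase == "during") {
    x0["phaseduring"] <- 1
    int_col <- paste0("gs", level, ":phaseduring")
    if (int_col %in% names(x0)) x0[int_col] <- 1
  }
  x0
}

# Link-scale draws of the linear predictor for a level, and the prior SD
# of an arbitrary contrast weight vector under independent N(0, b_sd).
eta_draws <- function(fit, x0) {
  as.numeric(fit$draws[, fit$X_names, drop = FALSE] %*% x0)
}

contrast_prior_sd <- function(fit, w) {
  # intercept cancels in any between-level contrast; all coefficients share
  # the same prior scale
  sqrt(sum((w * fit$spec$priors$b_sd)^2))
}

#' Highest density interval
#'
#' Narrowest interval containing a given fraction of the draws, found by a
#' sweep over the sorted sample; ties broken toward the lower interval.
#'
#' @param x Numeric draws.
#' @param prob Mass to cover. Default 0.89.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.89) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  lo <- seq_len(n - k)
  widths <- x[lo + k] - x[lo]
  i <- which.min(widths)  # which.min takes the first (lowest) on ties
  c(x[i], x[i + k])
}

#' Savage-Dickey density-ratio Bayes factor
#'
#' Evidence for a non-zero effect from the ratio of the prior density to
#' the posterior density of the effect at zero. The posterior density is a
#' Gaussian kernel density estimate of the draws (Silverman's rule-of-thumb
#' bandwidth) evaluated at zero; the prior is the induced normal prior of
#' the contrast. A ratio above one is evidence for the effect, below one
#' against it; the result is reported as a factor of at least one with a
#' direction flag.
#'
#' @param draws Posterior draws of the contrast on the link scale.
#' @param prior_sd SD of the contrast's (zero-mean normal) prior.
#' @param value Point null. Default 0.
#' @return List: `bayes_factor` (>= 1), `direction` (`"for"` /
#'   `"against"`), `bf_for` (the raw for-effect ratio), `capped` (TRUE when
#'   the posterior density at the null was numerically zero).
#' @export
savage_dickey_bf <- function(draws, prior_sd, value = 0) {
  stopifnot(length(draws) >= 100)
  bw <- stats::bw.nrd0(draws)
  post0 <- mean(stats::dnorm(value, mean = draws, sd = bw))
  prior0 <- stats::dnorm(value, 0, prior_sd)
  capped <- FALSE
  if (post0 <= 0 || !is.finite(post0) || prior0 / post0 > 1e6) {
    bf_for <- 1e6
    capped <- TRUE
  } else {
    bf_for <- prior0 / post0
  }
  if (bf_for >= 1) {
    list(bayes_factor = bf_for, direction = "for", bf_for = bf_for,
         capped = capped)
  } else {
    list(bayes_factor = 1 / bf_for, direction = "against", bf_for = bf_for,
         capped = capped)
  }
}

#' Verbal strength of a Bayes factor
#'
#' Jeffreys-style bands on a Bayes factor expressed as >= 1 (direction
#' carried separately): 1-3 weak, 3-10 moderate, 10-30 strong, 30-100 very
#' strong, above 100 extreme.
#'
#' @param bf Bayes factor, >= 1.
#' @return One of `"weak"`, `"moderate"`, `"strong"`, `"very strong"`,
#'   `"extreme"`.
#' @export
classify_bf <- function(bf) {
  stopifnot(bf >= 1)
  if (bf < 3) "weak"
  else if (bf < 10) "moderate"
  else if (bf < 30) "strong"
  else if (bf <= 100) "very strong"
  else "extreme"
}

#' Back-transformed marginal contrast between group-size levels
#'
#' Per posterior draw, evaluates the linear predictor of each level at the
#' reference covariates (sample-mean temperature and fish length, random
#' intercept zero, and — for phase models — the requested phase),
#' back-transforms through the inverse link, and differences them
#' (`to - from`). Returns the posterior median of the difference on the
#' response scale and its 89% highest density interval.
#'
#' @param fit A `shoal_glmm`.
#' @param from,to Group-size level labels (`"small"`, `"intermediate"`,
#'   `"large"`).
#' @param phase Optional phase (`"before"` / `"during"`) for models with
#'   phase interactions.
#' @param prob HDI mass. Default 0.89.
#' @return List: `marginal_effect`, `hdi` (length 2), `draws` (the
#'   response-scale difference draws).
#' @export
marginal_contrast <- function(fit, from, to, phase = NULL, prob = 0.89) {
  ilink <- inv_link(fit$spec$family)
  e_from <- ilink(eta_draws(fit, level_design(fit, from, phase)))
  e_to <- ilink(eta_draws(fit, level_design(fit, to, phase)))
  diff <- e_to - e_from
  list(marginal_effect = stats::median(diff), hdi = hdi(diff, prob),
       draws = diff)
}

#' Posterior summary table of group-size contrasts
#'
#' For each ordered pair of group-size levels (small to intermediate,
#' small to large, intermediate to large; within each phase for phase
#' models), reports the Savage-Dickey Bayes factor of the link-scale
#' contrast with its direction and verbal strength, and the
#' back-transformed 89% HDI and median marginal effect on the response
#' scale.
#'
#' @param fit A `shoal_glmm`.
#' @param prob HDI mass. Default 0.89.
#' @return A tibble with one row per contrast: `contrast`, `phase`,
#'   `bayes_factor`, `bf_direction`, `bf_strength`, `hdi_lo`, `hdi_hi`,
#'   `marginal_effect`.
#' @export
posterior_summary <- function(fit, prob = 0.89) {
  pairs <- list(c("small", "intermediate"), c("small", "large"),
                c("intermediate", "large"))
  phases <- if (fit$spec$include_phase) c("before", "during") else NA_character_
  rows <- list()
  for (ph in phases) {
    ph_arg <- if (is.na(ph)) NULL else ph
    for (pr in pairs) {
      x_from <- level_design(fit, pr[1], ph_arg)
      x_to <- level_design(fit, pr[2], ph_arg)
      w <- x_to - x_from
      link_draws <- eta_draws(fit, w)
      sd_bf <- savage_dickey_bf(link_draws, contrast_prior_sd(fit, w))
      mc <- marginal_contrast(fit, pr[1], pr[2], ph_arg, prob)
      rows[[length(rows) + 1]] <- tibble::tibble(
        contrast = paste(pr[1], "→", pr[2]),
        phase = ph,
        bayes_factor = sd_bf$bayes_factor,
        bf_direction = sd_bf$direction,
        bf_strength = classify_bf(sd_bf$bayes_factor),
        hdi_lo = mc$hdi[1],
        hdi_hi = mc$hdi[2],
        marginal_effect = mc$marginal_effect
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Poisson GLM of inspectors per group inspection
#'
#' Maximum-likelihood Poisson regression of the number of inspectors in
#' each merged group inspection on experimental group size alone, in the
#' no-intercept parameterization that yields one log-scale estimate per
#' group-size level, with Wald tests.
#'
#' @param groups Group-inspection tibble from [group_inspections()].
#' @param meta Trial metadata with `trial_id` and `group_size`.
#' @return A tibble: `level`, `estimate` (log scale), `se`, `z`,
#'   `p_value`, `mean_inspectors` (back-transformed estimate).
#' @export
fit_inspectors_glm <- function(groups, meta) {
  d <- dplyr::inner_join(groups, meta[, c("trial_id", "group_size")],
                         by = "trial_id")
  if (nrow(d) == 0) stop("no group inspections to model")
  d$gs <- group_size_factor(d$group_size)
  missing_levels <- setdiff(levels(d$gs), as.character(unique(d$gs)))
  if (length(missing_levels) > 0) {
    stop("singular fit: no group inspections in level(s) ",
         paste(missing_levels, collapse = ", "))
  }
  fit <- stats::glm(n_inspectors ~ 0 + gs, family = stats::poisson(), data = d)
  cf <- summary(fit)$coefficients
  tibble::tibble(
    level = sub("^gs", "", rownames(cf)),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    z = cf[, "z value"],
    p_value = cf[, "Pr(>|z|)"],
    mean_inspectors = exp(cf[, "Estimate"])
  )
}
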