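#' Conditional (profile) maximum-likelihood Weibull scale
#'
#' For a fixed shape `b`, the Weibull scale maximising the right-censored
#' likelihood has the closed form `(sum_i t_i^b / d)^(1/b)`, where the sum runs
#' over all records (events and censored) and `d` is the number of events.
#' It is obtained by solving the scale score equation, and is homogeneous of
#' degree one in the time unit. At `b = 1` it reduces to the exponential MLE
#' `total time at risk / events`.
#'
#' @param cohort A cohort tibble with at least one event.
#' @param shape Positive shape value.
#' @return The conditional scale estimate (same units as `os_months`).
#' @examples
#' profile_scale(clagm_cohort("A"), 1) # 187/4 = 46.75 months
#' @export
profile_scale <- function(cohort, shape) {
  cohort <- validate_cohort(cohort)
  check_positive(shape, "shape")
  d <- sum(cohort$event)
  if (d == 0) {
    abort("profile_scale needs at least one observed event.",
      class = "weibcohort_domain_error"
    )
  }
  lt <- log(cohort$os_months)
  ps <- power_sums(lt, shape)
  exp((log(ps$s0) + ps$shift - log(d)) / shape)
}

# profile log-likelihood for one shape value, using precomputed log-times,
# sum of event log-times A, and event count d. Uses the identity
# sum((t/eta_hat)^b) = d, so
#   l_p(b) = d log b + (b-1) A - d log(S_b / d) - d,  S_b = sum(t^b).
profile_loglik_impl <- function(b, lt, A, d) {
  ps <- power_sums(lt, b)
  d * log(b) + (b - 1) * A - d * (log(ps$s0) + ps$shift - log(d)) - d
}

#' Profile log-likelihood of the Weibull shape
#'
#' The joint right-censored Weibull log-likelihood with the scale replaced by
#' its conditional maximum [profile_scale()]. Its argmax equals the joint
#' MLE's shape, and its value at the MLE equals the joint maximised
#' log-likelihood. Vectorised over `shape`.
#'
#' @param cohort A cohort tibble with at least two observed events.
#' @param shape Positive shape value(s).
#' @return Numeric vector of profile log-likelihood values.
#' @examples
#' profile_loglik(clagm_cohort("A"), c(0.5, 0.7, 1))
#' @export
profile_loglik <- function(cohort, shape) {
  cohort <- validate_cohort(cohort)
  if (any(!is.finite(shape) | shape <= 0)) {
    abort("`shape` must be positive and finite.", class = "weibcohort_domain_error")
  }
  d <- sum(cohort$event)
  if (d < 2) {
    abort("profile_loglik needs at least two observed events.",
      class = "weibcohort_domain_error"
    )
  }
  lt <- log(cohort$os_months)
  A <- sum(lt[cohort$event])
  vapply(shape, profile_loglik_impl, numeric(1), lt = lt, A = A, d = d)
}

#' Prior specifications for the Weibull shape
#'
#' Priors over the shape parameter used by [posterior_quadrature()] and
#' [posterior_mcmc()]. `flat_prior()` is uniform on a bounded interval (the
#' package default, `(0, 10]`, makes the posterior proportional to the profile
#' likelihood); `gamma_prior()` and `lognormal_prior()` allow mildly
#' informative alternatives on the positive half-line.
#'
#' @param lower,upper Bounds of the flat prior; `0 <= lower < upper`.
#' @return A `prior_spec`: a list with `kind`, `parameters`, `support`,
#'   a vectorised `log_density` function, and a display `label`.
#' @examples
#' flat_prior()
#' gamma_prior(2, 2)
#' @export
flat_prior <- function(lower = 0, upper = 10) {
  if (!(lower >= 0 && upper > lower)) {
    abort("flat prior needs 0 <= lower < upper.", class = "weibcohort_domain_error")
  }
  new_prior(
    kind = "flat", parameters = c(lower = lower, upper = upper),
    support = c(lower, upper),
    log_density = function(b) ifelse(b > lower & b <= upper, -log(upper - lower), -Inf),
    label = sprintf("flat(%g, %g]", lower, upper)
  )
}

#' @rdname flat_prior
#' @param shape,rate Gamma prior parameters (mean `shape/rate`).
#' @export
gamma_prior <- function(shape, rate) {
  check_positive(shape, "shape")
  check_positive(rate, "rate")
  new_prior(
    kind = "gamma", parameters = c(shape = shape, rate = rate),
    support = c(0, Inf),
    log_density = function(b) stats::dgamma(b, shape = shape, rate = rate, log = TRUE),
    label = sprintf("gamma(shape = %g, rate = %g)", shape, rate)
  )
}

#' @rdname flat_prior
#' @param meanlog,sdlog Log-normal prior parameters.
#' @export
lognormal_prior <- function(meanlog = 0, sdlog = 1) {
  check_positive(sdlog, "sdlog")
  new_prior(
    kind = "lognormal", parameters = c(meanlog = meanlog, sdlog = sdlog),
    support = c(0, Inf),
    log_density = function(b) stats::dlnorm(b, meanlog = meanlog, sdlog = sdlog, log = TRUE),
    label = sprintf("lognormal(meanlog = %g, sdlog = %g)", meanlog, sdlog)
  )
}

new_prior <- function(kind, parameters, support, log_density, label) {
  structure(
    list(
      kind = kind, parameters = parameters, support = support,
      log_density = log_density, label = label
    ),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Shape prior:", x$label, "\n")
  invisible(x)
}

posterior_grid_range <- function(cohort, prior, grid_range) {
  if (!is.null(grid_range)) {
    stopifnot(length(grid_range) == 2, grid_range[1] > 0, grid_range[2] > grid_range[1])
    return(grid_range)
  }
  mle <- weibull_mle(cohort)$shape
  lo <- max(prior$support[1], mle / 100, 1e-4)
  hi <- if (is.finite(prior$support[2])) prior$support[2] else mle * 100
  c(lo, hi)
}

#' Posterior over the Weibull shape by deterministic quadrature
#'
#' Evaluates the (unnormalised) posterior `prior(shape) * exp(profile
#' log-likelihood)` on a regular grid, in log space, and normalises by the
#' trapezoid rule. Serves both as a fast posterior in its own right and as the
#' deterministic cross-check for the Metropolis sampler
#' ([posterior_mcmc()]).
#'
#' @param cohort A cohort tibble with at least two observed events.
#' @param prior A `prior_spec` (default [flat_prior()]).
#' @param grid_n Number of grid points (default 2001).
#' @param level Credibility level for the equal-tailed interval.
#' @param grid_range Optional c(lo, hi) overriding the automatic grid, which
#'   spans the prior support clipped to two decades around the MLE shape.
#'
#' @return A `shape_posterior` with `method = "quadrature"`, the `grid` and
#'   normalised `density`, posterior-median `point_estimate` and equal-tailed
#'   `cri` at `level`.
#' @examples
#' posterior_quadrature(clagm_cohort("A"))
#' @export
posterior_quadrature <- function(cohort, prior = flat_prior(), grid_n = 2001,
                                 level = 0.90, grid_range = NULL) {
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(prior, "prior_spec"), grid_n >= 50)
  rng <- posterior_grid_range(cohort, prior, grid_range)
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  lp <- prior$log_density(grid) + profile_loglik(cohort, grid)
  m <- max(lp[is.finite(lp)], -Inf)
  if (!is.finite(m)) {
    abort("posterior is numerically zero on the whole grid; widen `grid_range`.",
      class = "weibcohort_numeric_error"
    )
  }
  dens <- exp(lp - m)
  dens[!is.finite(dens)] <- 0
  z <- trapz(grid, dens)
  if (z <= 0) {
    abort("posterior mass underflowed on the grid.", class = "weibcohort_numeric_error")
  }
  dens <- dens / z
  qs <- grid_quantiles(grid, dens, c((1 - level) / 2, 0.5, (1 + level) / 2))
  new_shape_posterior(
    method = "quadrature", samples = NULL, grid = grid, density = dens,
    point_estimate = qs[2], cri = c(lo = qs[1], hi = qs[3]), level = level,
    prior = prior, seed = NA_integer_,
    diagnostics = list(grid_n = grid_n, grid_range = rng)
  )
}

grid_quantiles <- function(grid, density, probs) {
  n <- length(grid)
  cdf <- c(0, cumsum((density[-1] + density[-n]) / 2 * diff(grid)))
  cdf <- cdf / cdf[n]
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], grid[keep], xout = probs, ties = "ordered")$y
}

#' Posterior over the Weibull shape by random-walk Metropolis
#'
#' Single-chain random-walk Metropolis on the log-shape. The target is the
#' profile-likelihood posterior `prior(shape) * exp(profile log-likelihood)`,
#' with the Jacobian of the log transform included, so the chain samples the
#' same distribution that [posterior_quadrature()] integrates. Deterministic
#' given `seed`; the global RNG state is left untouched.
#'
#' @inheritParams posterior_quadrature
#' @param n_iter Total iterations (default 50000).
#' @param burn_in Iterations discarded from the start (default 5000).
#' @param proposal_sd Standard deviation of the Gaussian proposal on the log
#'   shape (default 0.3).
#' @param seed Integer seed; required, recorded in the result.
#'
#' @return A `shape_posterior` with `method = "mcmc"`, the retained `samples`,
#'   posterior-median `point_estimate`, equal-tailed `cri`, and
#'   `diagnostics` (acceptance rate, effective sample size). A warning is
#'   issued when the post-burn-in acceptance rate leaves `[0.05, 0.95]`.
#' @examples
#' post <- posterior_mcmc(clagm_cohort("A"), n_iter = 2000, burn_in = 500, seed = 1)
#' glance(post)
#' @export
posterior_mcmc <- function(cohort, prior = flat_prior(), n_iter = 50000,
                           burn_in = 5000, proposal_sd = 0.3, seed,
                           level = 0.90) {
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(prior, "prior_spec"))
  if (missing(seed)) {
    abort("`seed` is required for posterior_mcmc.", class = "weibcohort_config_error")
  }
  seed <- as.integer(seed)
  if (!(n_iter > burn_in && burn_in >= 0)) {
    abort("need n_iter > burn_in >= 0.", class = "weibcohort_config_error")
  }
  check_positive(proposal_sd, "proposal_sd")

  lt <- log(cohort$os_months)
  d <- sum(cohort$event)
  if (d < 2) {
    abort("posterior_mcmc needs at least two observed events.",
      class = "weibcohort_domain_error"
    )
  }
  A <- sum(lt[cohort$event])
  log_target <- function(lb) {
    b <- exp(lb)
    lp <- prior$log_density(b)
    if (!is.finite(lp)) return(-Inf)
    lp + profile_loglik_impl(b, lt, A, d) + lb
  }

  # start at the MLE shape clipped to the interior of the prior support
  b_start <- tryCatch(weibull_mle(cohort)$shape, error = function(e) 1)
  sup <- prior$support
  b_start <- min(max(b_start, sup[1] + 1e-6 * max(sup[1], 1)),
    if (is.finite(sup[2])) sup[2] * (1 - 1e-9) else b_start)
  if (!is.finite(log_target(log(b_start)))) b_start <- sqrt(max(sup[1], 0.01) * min(sup[2], 100))

  samples <- numeric(n_iter)
  n_acc_post <- 0L
  withr::with_seed(seed, {
    lb <- log(b_start)
    cur <- log_target(lb)
    steps <- rnorm(n_iter, 0, proposal_sd)
    logu <- log(runif(n_iter))
    for (i in seq_len(n_iter)) {
      prop <- lb + steps[i]
      cand <- log_target(prop)
      if (logu[i] < cand - cur) {
        lb <- prop
        cur <- cand
        if (i > burn_in) n_acc_post <- n_acc_post + 1L
      }
      samples[i] <- lb
    }
  })
  kept <- exp(samples[(burn_in + 1):n_iter])
  acc <- n_acc_post / (n_iter - burn_in)
  ess <- ess_acf(kept)
  if (acc < 0.05 || acc > 0.95) {
    warn(sprintf(
      "Metropolis acceptance rate %.3f outside [0.05, 0.95]; consider retuning proposal_sd.",
      acc
    ))
  }
  qs <- quantile(kept, c((1 - level) / 2, 0.5, (1 + level) / 2), names = FALSE)
  new_shape_posterior(
    method = "mcmc", samples = kept, grid = NULL, density = NULL,
    point_estimate = qs[2], cri = c(lo = qs[1], hi = qs[3]), level = level,
    prior = prior, seed = seed,
    diagnostics = list(
      acceptance_rate = acc, ess = ess,
      n_iter = n_iter, burn_in = burn_in, proposal_sd = proposal_sd
    )
  )
}

# effective sample size from the initial positive autocorrelation sequence
ess_acf <- function(x, lag_max = 1000) {
  n <- length(x)
  if (n < 10) return(NA_real_)
  rho <- as.numeric(acf(x, lag.max = min(lag_max, n - 1), plot = FALSE)$acf)[-1]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

new_shape_posterior <- function(method, samples, grid, density, point_estimate,
                                cri, level, prior, seed, diagnostics) {
  structure(
    list(
      method = method, samples = samples, grid = grid, density = density,
      point_estimate = point_estimate, cri = cri, level = level,
      prior = prior, seed = seed, diagnostics = diagnostics
    ),
    class = "shape_posterior"
  )
}

#' Summarise a posterior at a chosen credibility level
#'
#' Posterior median and equal-tailed credibility interval, recomputed at
#' `level` without mutating the posterior object. Also accepts a bare numeric
#' sample vector, in which case empirical quantiles are used.
#'
#' @param posterior A `shape_posterior`, or a numeric vector of samples.
#' @param level Credibility level in (0, 1).
#' @return A one-row tibble: `point_estimate`, `cri_lo`, `cri_hi`, `level`,
#'   `method`. A precision warning is issued when fewer than 1000 effective
#'   samples back the summary.
#' @export
summarize_posterior <- function(posterior, level = 0.90) {
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "weibcohort_domain_error")
  }
  probs <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  if (is.numeric(posterior)) {
    if (length(posterior) < 1000) {
      warn("fewer than 1000 samples; posterior summaries are imprecise.")
    }
    qs <- quantile(posterior, probs, names = FALSE)
    method <- "samples"
  } else if (inherits(posterior, "shape_posterior")) {
    if (identical(posterior$method, "quadrature")) {
      qs <- grid_quantiles(posterior$grid, posterior$density, probs)
    } else {
      ess <- posterior$diagnostics$ess
      if (is.finite(ess) && ess < 1000) {
        warn(sprintf("effective sample size %.0f < 1000; posterior summaries are imprecise.", ess))
      }
      qs <- quantile(posterior$samples, probs, names = FALSE)
    }
    method <- posterior$method
  } else {
    abort("`posterior` must be a shape_posterior or a numeric sample vector.",
      class = "weibcohort_domain_error"
    )
  }
  tibble::tibble(
    point_estimate = qs[2], cri_lo = qs[1], cri_hi = qs[3],
    level = level, method = method
  )
}

#' @describeIn posterior_quadrature Tidy one-row parameter summary.
#' @param x A `shape_posterior`.
#' @param ... Unused.
#' @export
tidy.shape_posterior <- function(x, ...) {
  tibble::tibble(
    term = "shape",
    estimate = x$point_estimate,
    conf.low = x$cri[["lo"]], conf.high = x$cri[["hi"]],
    level = x$level, method = x$method
  )
}

#' @describeIn posterior_quadrature Summary row including prior, seed and
#'   sampler diagnostics.
#' @export
glance.shape_posterior <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    point_estimate = x$point_estimate,
    cri_lo = x$cri[["lo"]], cri_hi = x$cri[["hi"]],
    level = x$level,
    prior = x$prior$label,
    seed = x$seed,
    n_samples = if (is.null(x$samples)) NA_integer_ else length(x$samples),
    ess = x$diagnostics$ess %||% NA_real_,
    acceptance_rate = x$diagnostics$acceptance_rate %||% NA_real_
  )
}

#' @describeIn posterior_quadrature Posterior density plot with the
#'   credibility interval marked.
#' @param object A `shape_posterior`.
#' @export
autoplot.shape_posterior <- function(object, ...) {
  if (identical(object$method, "quadrature")) {
    df <- tibble::tibble(shape = object$grid, density = object$density)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$shape, y = .data$density)) +
      ggplot2::geom_line()
  } else {
    df <- tibble::tibble(shape = object$samples)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$shape)) +
      ggplot2::geom_density()
  }
  p +
    ggplot2::geom_vline(
      xintercept = c(object$cri[["lo"]], object$point_estimate, object$cri[["hi"]]),
      linetype = c("dotted", "dashed", "dotted")
    ) +
    ggplot2::labs(
      x = "Weibull shape", y = "posterior density",
      title = sprintf(
        "Shape posterior (%s, %s), median %.3f, %d%% CrI [%.3f, %.3f]",
        object$method, object$prior$label, object$point_estimate,
        round(100 * object$level), object$cri[["lo"]], object$cri[["hi"]]
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.shape_posterior <- function(x, ...) {
  cat(sprintf(
    "Weibull shape posterior (%s; prior %s)\n  median = %.4f, %d%% CrI = [%.4f, %.4f]\n",
    x$method, x$prior$label, x$point_estimate,
    round(100 * x$level), x$cri[["lo"]], x$cri[["hi"]]
  ))
  if (identical(x$method, "mcmc")) {
    cat(sprintf(
      "  %d retained samples (seed %d), acceptance %.2f, ESS %.0f\n",
      length(x$samples), x$seed,
      x$diagnostics$acceptance_rate, x$diagnostics$ess
    ))
  }
  invisible(x)
}
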