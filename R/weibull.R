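#' Right-censored Weibull log-likelihood
#'
#' Log-likelihood of a two-parameter Weibull model with survival function
#' `S(t) = exp(-(t/scale)^shape)` for a right-censored cohort: observed deaths
#' contribute the log-density
#' `log(shape) - shape*log(scale) + (shape-1)*log(t) - (t/scale)^shape`,
#' censored records contribute the log-survival `-(t/scale)^shape`.
#'
#' @param cohort A cohort tibble (see [validate_cohort()]).
#' @param shape,scale Positive Weibull parameters (shape is dimensionless,
#'   scale is in the time units of `os_months`).
#'
#' @return The log-likelihood as a single number.
#' @examples
#' weibull_loglik(clagm_cohort("A"), shape = 1, scale = 46.75)
#' @export
weibull_loglik <- function(cohort, shape, scale) {
  cohort <- validate_cohort(cohort)
  check_positive(shape, "shape")
  check_positive(scale, "scale")
  t <- cohort$os_months
  te <- t[cohort$event]
  sum(log(shape) - shape * log(scale) + (shape - 1) * log(te)) -
    sum((t / scale)^shape)
}

check_positive <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
      class = "weibcohort_domain_error"
    )
  }
  invisible(x)
}

# Scaled power sums sum(t^b), sum(t^b log t), sum(t^b log^2 t), computed with a
# common exponential shift so they stay finite for extreme shape values.
power_sums <- function(lt, b) {
  z <- b * lt
  zm <- max(z)
  w <- exp(z - zm)
  list(s0 = sum(w), s1 = sum(w * lt), s2 = sum(w * lt^2), shift = zm)
}

# profile score and curvature in beta (see profile_loglik for the closed form)
profile_score <- function(b, lt, A, d) {
  ps <- power_sums(lt, b)
  g <- d / b + A - d * ps$s1 / ps$s0
  h <- -d / b^2 - d * (ps$s2 * ps$s0 - ps$s1^2) / ps$s0^2
  c(g = g, h = h)
}

#' Maximum-likelihood Weibull fit under right censoring
#'
#' Fits the two-parameter Weibull model to a right-censored cohort by maximum
#' likelihood. The scale is concentrated out in closed form
#' ([profile_scale()]), the profile log-likelihood is maximised over the shape
#' by golden-section/parabolic search followed by Newton polishing on the
#' analytic profile score, so the fitted shape is invariant to the time unit
#' of the data to near machine precision. Standard errors are delta-method
#' values from a central-difference numerical Hessian of the joint
#' log-likelihood at the optimum, and confidence intervals are log-scale Wald
#' intervals ([wald_ci_log()]).
#'
#' @param cohort A cohort tibble with at least two observed events.
#' @param init Optional starting shape value (a length-1 or length-2 numeric;
#'   only the shape component is used, the scale is profiled out).
#' @param tol Convergence tolerance on the profile score Newton step.
#' @param level Confidence level for the Wald intervals (default 0.90).
#'
#' @return A `weibull_fit` object: a list with `shape`, `scale`, `se_shape`,
#'   `se_scale`, `ci_shape`, `ci_scale`, `level`, `loglik`, `aic`, `n`,
#'   `n_events`, `n_censored`, `total_time`, `converged`, and the cohort used.
#'   See [tidy.weibull_fit()], [glance.weibull_fit()], [fit_report()].
#' @examples
#' fit <- weibull_mle(clagm_cohort("A"))
#' fit
#' tidy(fit)
#' classify_hazard(fit$shape)
#' @export
weibull_mle <- function(cohort, init = NULL, tol = 1e-10, level = 0.90) {
  cohort <- validate_cohort(cohort)
  t <- cohort$os_months
  e <- cohort$event
  d <- sum(e)
  if (d < 2) {
    abort("weibull_mle needs at least two observed events (likelihood is unbounded or the information matrix singular otherwise).",
      class = "weibcohort_domain_error"
    )
  }
  lt <- log(t)
  A <- sum(lt[e])
  lo <- log(1e-4)
  hi <- log(1e4)

  nprof <- function(lb) -profile_loglik_impl(exp(lb), lt, A, d)
  b0 <- if (!is.null(init)) {
    check_positive(init[1], "init")
    init[1]
  } else {
    exp(optimize(nprof, interval = c(lo, hi), tol = 1e-8)$minimum)
  }

  # Newton polish on the analytic profile score
  b <- b0
  converged <- FALSE
  for (i in 1:100) {
    sc <- profile_score(b, lt, A, d)
    if (!is.finite(sc[["g"]]) || !is.finite(sc[["h"]]) || sc[["h"]] >= 0) break
    step <- sc[["g"]] / sc[["h"]]
    b_new <- b - step
    # keep the iterate in the admissible range with damping
    while (b_new <= 0 && abs(step) > .Machine$double.eps) {
      step <- step / 2
      b_new <- b - step
    }
    if (abs(b_new - b) <= tol * max(b, 1e-8)) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  if (!is.finite(b) || b >= exp(hi) * 0.99 || b > 1e3) {
    abort("weibull_mle failed to converge: the shape estimate diverges (typical cause: all event times identical).",
      class = "weibcohort_convergence_error"
    )
  }
  shape <- unname(b)
  scale <- profile_scale(cohort, shape)
  ll <- weibull_loglik(cohort, shape, scale)

  # observed information from a central-difference Hessian of the joint
  # log-likelihood on the natural scale (relative step 1e-5)
  H <- joint_hessian(t, e, shape, scale)
  se <- c(NA_real_, NA_real_)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
    se <- sqrt(diag(V))
  } else {
    warn("observed information is singular; standard errors are NA.")
  }

  structure(
    list(
      shape = shape, scale = scale,
      se_shape = se[1], se_scale = se[2],
      ci_shape = wald_ci_log(shape, se[1], level),
      ci_scale = wald_ci_log(scale, se[2], level),
      level = level,
      loglik = ll, aic = 2 * 2 - 2 * ll,
      n = length(t), n_events = d, n_censored = length(t) - d,
      total_time = sum(t),
      converged = converged,
      cohort = cohort,
      label = paste(unique(cohort$group), collapse = "+")
    ),
    class = "weibull_fit"
  )
}

joint_hessian <- function(t, e, shape, scale) {
  te <- t[e]
  ll <- function(b, eta) {
    sum(log(b) - b * log(eta) + (b - 1) * log(te)) - sum((t / eta)^b)
  }
  h1 <- 1e-5 * shape
  h2 <- 1e-5 * scale
  H <- matrix(NA_real_, 2, 2)
  H[1, 1] <- (ll(shape + h1, scale) - 2 * ll(shape, scale) + ll(shape - h1, scale)) / h1^2
  H[2, 2] <- (ll(shape, scale + h2) - 2 * ll(shape, scale) + ll(shape, scale - h2)) / h2^2
  H[1, 2] <- H[2, 1] <- (
    ll(shape + h1, scale + h2) - ll(shape + h1, scale - h2) -
      ll(shape - h1, scale + h2) + ll(shape - h1, scale - h2)
  ) / (4 * h1 * h2)
  H
}

#' Log-scale Wald confidence interval for a positive parameter
#'
#' Interval `estimate * exp(-z*se/estimate)` to
#' `estimate * exp(+z*se/estimate)` with `z` the standard-normal quantile at
#' `(1+level)/2`: the Wald interval for the log-parameter, transformed back.
#' Symmetric on the log scale, always positive, and equal to the estimate when
#' `se = 0`.
#'
#' @param estimate Positive point estimate.
#' @param se Non-negative delta-method standard error (on the natural scale).
#' @param level Coverage level in (0, 1).
#'
#' @return Named numeric vector `c(lo, hi)`; `c(NA, NA)` if `se` is `NA`.
#' @examples
#' wald_ci_log(0.743, 0.262, 0.90)
#' @export
wald_ci_log <- function(estimate, se, level = 0.90) {
  if (length(estimate) != 1 || !is.finite(estimate) || estimate <= 0) {
    abort("`estimate` must be a single positive number.", class = "weibcohort_domain_error")
  }
  if (length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "weibcohort_domain_error")
  }
  if (is.na(se)) {
    return(c(lo = NA_real_, hi = NA_real_))
  }
  if (se < 0) abort("`se` must be non-negative.", class = "weibcohort_domain_error")
  z <- qnorm((1 + level) / 2)
  c(
    lo = estimate * exp(-z * se / estimate),
    hi = estimate * exp(+z * se / estimate)
  )
}

#' Classify the hazard regime implied by a Weibull shape
#'
#' A Weibull shape below 1 means a decreasing hazard over time (the "infant
#' mortality" phase: early deaths dominate), exactly 1 a constant hazard
#' (exponential survival, random causes), above 1 an increasing hazard
#' (aging/wear-out). The comparison is strict and uses the point estimate
#' only; interval statements are the caller's job using the CI or CrI.
#'
#' @param shape Positive shape value(s).
#' @return A factor with levels `decreasing`, `constant`, `increasing`.
#' @examples
#' classify_hazard(c(0.743, 1, 1.196))
#' @export
classify_hazard <- function(shape) {
  if (any(!is.finite(shape) | shape <= 0)) {
    abort("`shape` must be positive and finite.", class = "weibcohort_domain_error")
  }
  factor(
    ifelse(shape < 1, "decreasing", ifelse(shape > 1, "increasing", "constant")),
    levels = c("decreasing", "constant", "increasing")
  )
}

#' Weibull probability-plot coordinates with order-statistic bounds
#'
#' Coordinates for the classical Weibull plot used to judge whether censored
#' data follow a Weibull distribution. Each observed death is placed at
#' `x = log(t)` and `y = log(-log(1 - F))` with `F` the Benard median-rank
#' approximation `(r - 0.3)/(n + 0.4)` evaluated at Johnson-adjusted ranks
#' (the censoring-adjusted rank increments). Pointwise bounds come from the
#' exact beta distribution of the order statistics at the `(1 -/+ level)/2`
#' quantiles, mapped through the same `y` transform. On Weibull-consistent
#' data the fitted line passes through all the pointwise bounds.
#'
#' @param cohort A cohort tibble with at least one event.
#' @param level Bound level (default 0.90).
#'
#' @return A `weibull_plot` tibble with columns `time`, `rank` (adjusted),
#'   `median_rank`, `x`, `y`, `y_lo`, `y_hi`; attributes `n`, `d`, `level`.
#' @examples
#' weibull_plot_points(clagm_cohort("A"))
#' @export
weibull_plot_points <- function(cohort, level = 0.90) {
  cohort <- validate_cohort(cohort)
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "weibcohort_domain_error")
  }
  # events before censored at tied times: tied censored remain at risk
  ord <- order(cohort$os_months, -cohort$event)
  t <- cohort$os_months[ord]
  e <- cohort$event[ord]
  n <- length(t)
  d <- sum(e)
  if (d == 0) {
    out <- tibble::tibble(
      time = numeric(), rank = numeric(), median_rank = numeric(),
      x = numeric(), y = numeric(), y_lo = numeric(), y_hi = numeric()
    )
    return(structure(out, n = n, d = 0L, level = level,
      class = c("weibull_plot", class(out))
    ))
  }
  r_prev <- 0
  ranks <- numeric(0)
  times <- numeric(0)
  for (k in seq_len(n)) {
    if (e[k]) {
      inc <- (n + 1 - r_prev) / (n + 2 - k)
      r_prev <- r_prev + inc
      ranks <- c(ranks, r_prev)
      times <- c(times, t[k])
    }
  }
  mr <- (ranks - 0.3) / (n + 0.4)
  alpha <- (1 - level) / 2
  f_lo <- qbeta(alpha, ranks, n - ranks + 1)
  f_hi <- qbeta(1 - alpha, ranks, n - ranks + 1)
  ytrans <- function(p) log(-log(1 - p))
  out <- tibble::tibble(
    time = times, rank = ranks, median_rank = mr,
    x = log(times), y = ytrans(mr),
    y_lo = ytrans(f_lo), y_hi = ytrans(f_hi)
  )
  structure(out, n = n, d = as.integer(d), level = level,
    class = c("weibull_plot", class(out))
  )
}

#' @describeIn weibull_mle Per-parameter tidy summary (term, estimate,
#'   std.error, conf.low, conf.high).
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(
    term = c("shape", "scale"),
    estimate = c(x$shape, x$scale),
    std.error = c(x$se_shape, x$se_scale),
    conf.low = c(x$ci_shape[["lo"]], x$ci_scale[["lo"]]),
    conf.high = c(x$ci_shape[["hi"]], x$ci_scale[["hi"]])
  )
}

#' @describeIn weibull_mle One-row model summary.
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, events = x$n_events, censored = x$n_censored,
    total_time = x$total_time,
    logLik = x$loglik, AIC = x$aic,
    level = x$level, converged = x$converged
  )
}

#' Flat single-row fit report
#'
#' The fit flattened to one row with self-describing column names (the bound
#' columns carry the interval level, e.g. `shape_lo90`), convenient for
#' side-by-side comparison across cohorts and for CSV export.
#'
#' @param fit A `weibull_fit`.
#' @return A one-row tibble with columns `shape`, `shape_lo<level>`,
#'   `shape_hi<level>`, `shape_se`, the same four for `scale`, then `n`,
#'   `events`, `censored`, `total_time`, `aic`, `loglik`.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  lv <- round(100 * fit$level)
  out <- tibble::tibble(
    shape = fit$shape,
    shape_lo = fit$ci_shape[["lo"]], shape_hi = fit$ci_shape[["hi"]],
    shape_se = fit$se_shape,
    scale = fit$scale,
    scale_lo = fit$ci_scale[["lo"]], scale_hi = fit$ci_scale[["hi"]],
    scale_se = fit$se_scale,
    n = fit$n, events = fit$n_events, censored = fit$n_censored,
    total_time = fit$total_time, aic = fit$aic, loglik = fit$loglik
  )
  names(out)[names(out) == "shape_lo"] <- sprintf("shape_lo%d", lv)
  names(out)[names(out) == "shape_hi"] <- sprintf("shape_hi%d", lv)
  names(out)[names(out) == "scale_lo"] <- sprintf("scale_lo%d", lv)
  names(out)[names(out) == "scale_hi"] <- sprintf("scale_hi%d", lv)
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "Right-censored Weibull fit (%s): N = %d, events = %d, censored = %d\n",
    x$label, x$n, x$n_events, x$n_censored
  ))
  lv <- round(100 * x$level)
  cat(sprintf(
    "  shape  %8.4f  [%s%% CI %.4f, %.4f]  se %.4f  (%s hazard)\n",
    x$shape, lv, x$ci_shape[["lo"]], x$ci_shape[["hi"]], x$se_shape,
    as.character(classify_hazard(x$shape))
  ))
  cat(sprintf(
    "  scale  %8.4f  [%s%% CI %.4f, %.4f]  se %.4f\n",
    x$scale, lv, x$ci_scale[["lo"]], x$ci_scale[["hi"]], x$se_scale
  ))
  cat(sprintf(
    "  total time at risk = %g, log-likelihood = %.4f, AIC = %.5f%s\n",
    x$total_time, x$loglik, x$aic,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}

#' @describeIn weibull_mle Weibull probability plot of the fitted cohort with
#'   pointwise order-statistic bounds and the fitted line.
#' @param object A `weibull_fit`.
#' @export
autoplot.weibull_fit <- function(object, ...) {
  pts <- weibull_plot_points(object$cohort, level = object$level)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$y_lo, ymax = .data$y_hi),
      alpha = 0.2
    ) +
    ggplot2::geom_abline(
      slope = object$shape,
      intercept = -object$shape * log(object$scale),
      linetype = "dashed"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log time", y = "log(-log(1 - F))",
      title = sprintf(
        "Weibull plot (%s), shape = %.3f, %d%% bounds",
        object$label, object$shape, round(100 * object$level)
      )
    ) +
    ggplot2::theme_minimal()
}
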