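#' Simulate a right-censored Weibull cohort
#'
#' Draws event times from a Weibull distribution by inversion,
#' `scale * (-log U)^(1/shape)` with `U` uniform, so the generator is fully
#' specified by R's seeded uniform stream (Mersenne-Twister via `set.seed`).
#' Censoring mechanisms: `"none"` (all deaths observed), `"admin"`
#' (administrative cut-off at `cens_time`: records with a later true event
#' time are censored at the cut-off), `"uniform"` (an independent
#' `Uniform(cens_range)` censoring time per subject; the observed time is the
#' minimum and the event flag records whether death came first).
#'
#' Presets mirroring the packaged MPAL cohort are useful for end-to-end
#' checks: a "Group-A-like" cohort is `n = 8, shape = 0.75, scale = 50` with
#' administrative censoring at 40, a "Group-B-like" cohort `n = 8,
#' shape = 1.2, scale = 22`.
#'
#' @param n Number of subjects.
#' @param shape,scale Positive Weibull parameters (scale in months).
#' @param censoring `"none"`, `"admin"`, or `"uniform"`.
#' @param cens_time Administrative cut-off (required for `"admin"`).
#' @param cens_range Length-2 vector `c(lo, hi)`, `0 <= lo < hi` (required for
#'   `"uniform"`).
#' @param seed Integer seed; required. The global RNG state is left untouched.
#' @param group Group label stored in the cohort (default `"SIM"`).
#'
#' @return A cohort tibble with columns `patient_id`, `group`, `os_months`,
#'   `event`, `response` (all `"UNKNOWN"`).
#' @examples
#' simulate_cohort(8, shape = 0.75, scale = 50, censoring = "admin",
#'   cens_time = 40, seed = 1)
#' @export
simulate_cohort <- function(n, shape, scale,
                            censoring = c("none", "admin", "uniform"),
                            cens_time = NULL, cens_range = NULL,
                            seed, group = "SIM") {
  censoring <- match.arg(censoring)
  if (!(is.numeric(n) && length(n) == 1 && n >= 1)) {
    abort("`n` must be a single integer >= 1.", class = "weibcohort_config_error")
  }
  n <- as.integer(n)
  check_positive(shape, "shape")
  check_positive(scale, "scale")
  if (missing(seed)) {
    abort("`seed` is required for simulate_cohort.", class = "weibcohort_config_error")
  }
  if (censoring == "admin") {
    if (is.null(cens_time)) {
      abort("`cens_time` is required for administrative censoring.",
        class = "weibcohort_config_error"
      )
    }
    check_positive(cens_time, "cens_time")
  }
  if (censoring == "uniform") {
    if (is.null(cens_range) || length(cens_range) != 2 ||
      !(cens_range[1] >= 0 && cens_range[2] > cens_range[1])) {
      abort("`cens_range` must be c(lo, hi) with 0 <= lo < hi.",
        class = "weibcohort_config_error"
      )
    }
  }

  withr::with_seed(as.integer(seed), {
    t_event <- scale * (-log(runif(n)))^(1 / shape)
    if (censoring == "none") {
      os <- t_event
      event <- rep(TRUE, n)
    } else if (censoring == "admin") {
      event <- t_event <= cens_time
      os <- pmin(t_event, cens_time)
    } else {
      c_i <- runif(n, cens_range[1], cens_range[2])
      event <- t_event <= c_i
      os <- pmin(t_event, c_i)
    }
  })
  validate_cohort(tibble::tibble(
    patient_id = sprintf("S%04d", seq_len(n)),
    group = group,
    os_months = os,
    event = event,
    response = "UNKNOWN"
  ))
}

#' Parameter-recovery experiment for the Weibull MLE
#'
#' Simulates `reps` independent cohorts from known parameters, fits each with
#' [weibull_mle()], and summarises how well the estimator recovers the truth:
#' mean estimate, bias, root-mean-square error, and the fraction of Wald
#' intervals (at `level`) covering the true value, per parameter. Validates
#' the inferential machinery applied to very small cohorts (fits that fail or
#' do not converge are excluded and counted).
#'
#' @inheritParams simulate_cohort
#' @param reps Number of replicate cohorts (>= 2).
#' @param base_seed Integer; replicate `i` uses seed `base_seed + i - 1`.
#' @param level Confidence level for the coverage assessment (default 0.90).
#'
#' @return A tibble with one row per parameter (`shape`, `scale`): `truth`,
#'   `mean_estimate`, `bias`, `rmse`, `coverage`, `n_fits`, `n_failed`.
#' @examples
#' recovery_experiment(n = 30, shape = 1.5, scale = 10, reps = 10, base_seed = 1)
#' @export
recovery_experiment <- function(n, shape, scale,
                                censoring = c("none", "admin", "uniform"),
                                cens_time = NULL, cens_range = NULL,
                                reps, base_seed, level = 0.90) {
  censoring <- match.arg(censoring)
  if (!(is.numeric(reps) && length(reps) == 1 && reps >= 2)) {
    abort("`reps` must be >= 2.", class = "weibcohort_config_error")
  }
  fits <- purrr::map(seq_len(reps), function(i) {
    cohort <- simulate_cohort(
      n, shape, scale,
      censoring = censoring,
      cens_time = cens_time, cens_range = cens_range,
      seed = as.integer(base_seed) + i - 1L
    )
    tryCatch(
      {
        fit <- weibull_mle(cohort, level = level)
        if (!fit$converged) NULL else fit
      },
      error = function(e) NULL
    )
  })
  ok <- !purrr::map_lgl(fits, is.null)
  n_failed <- sum(!ok)
  fits <- fits[ok]
  if (length(fits) == 0) {
    abort("no replicate produced a converged fit.", class = "weibcohort_convergence_error")
  }
  est <- tibble::tibble(
    shape_hat = purrr::map_dbl(fits, "shape"),
    scale_hat = purrr::map_dbl(fits, "scale"),
    cover_shape = purrr::map_lgl(fits, function(f) {
      !anyNA(f$ci_shape) && f$ci_shape[["lo"]] <= shape && shape <= f$ci_shape[["hi"]]
    }),
    cover_scale = purrr::map_lgl(fits, function(f) {
      !anyNA(f$ci_scale) && f$ci_scale[["lo"]] <= scale && scale <= f$ci_scale[["hi"]]
    })
  )
  summary_row <- function(param, truth, hat, cover) {
    tibble::tibble(
      parameter = param, truth = truth,
      mean_estimate = mean(hat),
      bias = mean(hat) - truth,
      rmse = sqrt(mean((hat - truth)^2)),
      coverage = mean(cover),
      n_fits = length(hat), n_failed = n_failed
    )
  }
  dplyr::bind_rows(
    summary_row("shape", shape, est$shape_hat, est$cover_shape),
    summary_row("scale", scale, est$scale_hat, est$cover_scale)
  )
}
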