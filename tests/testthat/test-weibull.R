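test_that("censored log-likelihood matches closed forms and a term-by-term oracle", {
  expect_equal(weibull_loglik(make_cohort(1, TRUE), shape = 1, scale = 1), -1)
  expect_equal(weibull_loglik(make_cohort(2, FALSE), shape = 1, scale = 1), -2)

  a <- clagm_cohort("A")
  fit <- weibull_mle(a)
  expect_equal(
    weibull_loglik(a, fit$shape, fit$scale),
    loglik_oracle(a$os_months, a$event, fit$shape, fit$scale),
    tolerance = 1e-12
  )

  expect_error(weibull_loglik(a, -1, 10), class = "weibcohort_domain_error")
  expect_error(weibull_loglik(a, 1, 0), class = "weibcohort_domain_error")
})

test_that("MLE agrees with the general-purpose survival oracle on the fixtures", {
  for (g in c("A", "B")) {
    cohort <- clagm_cohort(g)
    fit <- weibull_mle(cohort)
    oracle <- survreg_shape_scale(cohort)
    expect_equal(fit$shape, oracle[["shape"]], tolerance = 1e-7)
    expect_equal(fit$scale, oracle[["scale"]], tolerance = 1e-7)
    expect_true(fit$converged)
    expect_equal(fit$loglik, weibull_loglik(cohort, fit$shape, fit$scale))
  }
})

test_that("MLE agrees with the oracle to 4 significant figures on random censored cohorts", {
  withr::with_seed(99, {
    specs <- replicate(20, list(
      n = sample(10:60, 1),
      shape = runif(1, 0.5, 3),
      scale = runif(1, 5, 60)
    ), simplify = FALSE)
  })
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    cohort <- simulate_cohort(s$n, s$shape, s$scale,
      censoring = "admin", cens_time = s$scale * 1.5, seed = 1000 + i
    )
    if (sum(cohort$event) < 3) next
    fit <- weibull_mle(cohort)
    oracle <- survreg_shape_scale(cohort)
    expect_equal(fit$shape, oracle[["shape"]], tolerance = 1e-4)
    expect_equal(fit$scale, oracle[["scale"]], tolerance = 1e-4)
  }
})

test_that("shape is recovered from a large uncensored sample", {
  cohort <- simulate_cohort(500, shape = 1.5, scale = 10, seed = 7)
  fit <- weibull_mle(cohort)
  # 3 Monte-Carlo standard errors of the estimator
  expect_lt(abs(fit$shape - 1.5), 3 * fit$se_shape)
  expect_lt(abs(fit$scale - 10), 3 * fit$se_scale)
})

test_that("fits are invariant to the time unit up to the scale factor", {
  for (g in c("A", "B")) {
    cohort <- clagm_cohort(g)
    fit <- weibull_mle(cohort)
    scaled <- dplyr::mutate(cohort, os_months = os_months * 30.44)
    fit_s <- weibull_mle(scaled)
    expect_equal(fit$shape, fit_s$shape, tolerance = 1e-10)
    expect_equal(fit_s$scale, fit$scale * 30.44, tolerance = 1e-9)
    expect_identical(classify_hazard(fit$shape), classify_hazard(fit_s$shape))
    # log-likelihood shifts by -d*log(c): the density Jacobian of the unit change
    d <- sum(cohort$event)
    expect_equal(fit_s$loglik, fit$loglik - d * log(30.44), tolerance = 1e-8)
  }
})

test_that("profiled fit reduces to the exponential MLE when the shape is pinned at 1", {
  withr::with_seed(31, {
    for (i in 1:5) {
      cohort <- make_cohort(rweibull(12, 1, 10) + 0.01, runif(12) < 0.6)
      if (sum(cohort$event) < 1) next
      expect_equal(
        profile_scale(cohort, 1),
        sum(cohort$os_months) / sum(cohort$event),
        tolerance = 1e-12
      )
    }
  })
})

test_that("reported se/CI pair is internally consistent and AIC follows from the log-likelihood", {
  fits <- list(weibull_mle(clagm_cohort("A")), weibull_mle(clagm_cohort("B")))
  for (i in 1:3) {
    cohort <- simulate_cohort(25, shape = 0.9, scale = 30,
      censoring = "uniform", cens_range = c(5, 80), seed = 400 + i
    )
    fits <- c(fits, list(weibull_mle(cohort)))
  }
  for (fit in fits) {
    expect_identical(fit$ci_shape, wald_ci_log(fit$shape, fit$se_shape, fit$level))
    expect_identical(fit$ci_scale, wald_ci_log(fit$scale, fit$se_scale, fit$level))
    expect_equal(fit$aic, 4 - 2 * fit$loglik)
    expect_true(fit$ci_shape[["lo"]] < fit$shape && fit$shape < fit$ci_shape[["hi"]])
  }
})

test_that("log-scale Wald interval has the stated closed form", {
  ci <- wald_ci_log(0.743, 0.262, 0.90)
  z <- qnorm(0.95)
  expect_equal(unname(ci), 0.743 * exp(c(-1, 1) * z * 0.262 / 0.743), tolerance = 1e-12)
  expect_equal(round(ci[["lo"]], 3), 0.416)
  expect_equal(round(ci[["hi"]], 3), 1.327)

  expect_equal(wald_ci_log(5, 0, 0.9), c(lo = 5, hi = 5))
  narrow <- wald_ci_log(2, 0.5, 0.5)
  wide <- wald_ci_log(2, 0.5, 0.95)
  expect_true(wide[["lo"]] < narrow[["lo"]] && narrow[["hi"]] < wide[["hi"]])
  expect_error(wald_ci_log(-1, 0.5, 0.9), class = "weibcohort_domain_error")
})

test_that("degenerate inputs are refused with informative errors", {
  expect_error(
    weibull_mle(make_cohort(c(5, 7, 9), c(TRUE, FALSE, FALSE))),
    "two observed events",
    class = "weibcohort_domain_error"
  )
  expect_error(
    weibull_mle(make_cohort(c(5, 5, 5), rep(TRUE, 3))),
    class = "weibcohort_convergence_error"
  )
})

test_that("hazard-phase classification is a strict comparison with 1", {
  expect_equal(
    as.character(classify_hazard(c(0.743, 1, 1.196))),
    c("decreasing", "constant", "increasing")
  )
  expect_error(classify_hazard(0), class = "weibcohort_domain_error")
})

test_that("median ranks follow Benard's approximation on a complete sample", {
  pts <- weibull_plot_points(make_cohort(c(3, 1, 4, 2, 5), rep(TRUE, 5)))
  expect_equal(pts$median_rank, ((1:5) - 0.3) / 5.4, tolerance = 1e-12)
  expect_equal(pts$time, 1:5)
  expect_equal(pts$x, log(1:5))
})

test_that("Weibull-plot slope estimates the shape on uncensored Weibull data", {
  cohort <- simulate_cohort(200, shape = 2, scale = 1, seed = 12)
  pts <- weibull_plot_points(cohort)
  slope <- unname(coef(lm(y ~ x, data = pts))[2])
  expect_lt(abs(slope - 2), 0.3)
})

test_that("event points and the plot's regression line stay inside the 90% bounds", {
  cohort <- clagm_cohort("A")
  pts <- weibull_plot_points(cohort, level = 0.90)
  expect_equal(nrow(pts), 4)
  # every plotted death lies within its pointwise order-statistic bounds
  expect_true(all(pts$y_lo < pts$y & pts$y < pts$y_hi))
  # and the straight line the plot fits through them stays inside the band
  line_y <- predict(lm(y ~ x, data = pts))
  expect_true(all(line_y >= pts$y_lo & line_y <= pts$y_hi))

  empty <- weibull_plot_points(make_cohort(c(2, 3), c(FALSE, FALSE)))
  expect_equal(nrow(empty), 0)
})

test_that("tidy/glance/fit_report expose the fit in broom-style tables", {
  fit <- weibull_mle(clagm_cohort("A"))
  td <- tidy(fit)
  expect_equal(td$term, c("shape", "scale"))
  expect_equal(td$estimate, c(fit$shape, fit$scale))
  gl <- glance(fit)
  expect_equal(gl$events, 4)
  expect_equal(gl$AIC, fit$aic)
  fr <- fit_report(fit)
  expect_named(fr, c(
    "shape", "shape_lo90", "shape_hi90", "shape_se",
    "scale", "scale_lo90", "scale_hi90", "scale_se",
    "n", "events", "censored", "total_time", "aic", "loglik"
  ))
  expect_equal(fr$total_time, 187)
})
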