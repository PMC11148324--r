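test_that("conditional scale has the closed form and its homogeneity", {
  a <- clagm_cohort("A")
  expect_equal(profile_scale(a, 1), 187 / 4) # total time at risk / events
  expect_equal(profile_scale(make_cohort(8, TRUE), 2), 8)

  scaled <- dplyr::mutate(a, os_months = os_months * 3.7)
  for (b in c(0.4, 1, 2.3)) {
    expect_equal(profile_scale(scaled, b), 3.7 * profile_scale(a, b), tolerance = 1e-12)
  }
  expect_error(
    profile_scale(make_cohort(c(2, 3), c(FALSE, FALSE)), 1),
    class = "weibcohort_domain_error"
  )
})

test_that("profile log-likelihood peaks at the joint MLE and is unimodal on the fixtures", {
  for (g in c("A", "B")) {
    cohort <- clagm_cohort(g)
    fit <- weibull_mle(cohort)
    grid <- seq(0.05, 10, by = 0.001)
    ll <- profile_loglik(cohort, grid)
    expect_equal(grid[which.max(ll)], fit$shape, tolerance = 1e-3)
    expect_equal(profile_loglik(cohort, fit$shape), fit$loglik, tolerance = 1e-10)
    # single sign change of the finite differences = unimodal
    signs <- sign(diff(ll))
    expect_equal(sum(diff(signs[signs != 0]) != 0), 1)
  }
})

test_that("profile-MLE equivalence holds on random synthetic cohorts", {
  for (i in 1:20) {
    cohort <- simulate_cohort(
      n = 15 + i, shape = 0.5 + i / 10, scale = 20,
      censoring = "admin", cens_time = 35, seed = 600 + i
    )
    if (sum(cohort$event) < 3) next
    fit <- weibull_mle(cohort)
    opt <- optimize(function(b) profile_loglik(cohort, b),
      interval = c(0.05, 20), maximum = TRUE, tol = 1e-9
    )
    expect_equal(fit$shape, opt$maximum, tolerance = 1e-5)
  }
})

test_that("quadrature posterior under a flat prior peaks at the MLE and integrates to one", {
  for (g in c("A", "B")) {
    cohort <- clagm_cohort(g)
    post <- posterior_quadrature(cohort)
    step <- diff(post$grid[1:2])
    expect_lt(abs(post$grid[which.max(post$density)] - weibull_mle(cohort)$shape), step + 1e-12)
    expect_equal(trapz(post$grid, post$density), 1, tolerance = 1e-6)
    expect_true(post$cri[["lo"]] < post$point_estimate &&
      post$point_estimate < post$cri[["hi"]])
  }
})

test_that("quadrature summaries are stable under grid refinement", {
  a <- clagm_cohort("A")
  p1 <- posterior_quadrature(a, grid_n = 2001)
  p2 <- posterior_quadrature(a, grid_n = 4001)
  expect_lt(abs(p1$cri[["lo"]] - p2$cri[["lo"]]), 1e-3)
  expect_lt(abs(p1$cri[["hi"]] - p2$cri[["hi"]]), 1e-3)
  expect_lt(abs(p1$point_estimate - p2$point_estimate), 1e-3)
})

test_that("a near-degenerate flat prior pins the posterior to its support", {
  post <- posterior_quadrature(clagm_cohort("A"),
    prior = flat_prior(1.999, 2.001), grid_range = c(1.99, 2.01)
  )
  expect_equal(post$point_estimate, 2, tolerance = 1e-3)
})

test_that("Metropolis sampling is deterministic given the seed", {
  a <- clagm_cohort("A")
  p1 <- posterior_mcmc(a, n_iter = 3000, burn_in = 500, seed = 123)
  p2 <- posterior_mcmc(a, n_iter = 3000, burn_in = 500, seed = 123)
  expect_identical(p1$samples, p2$samples)
  p3 <- posterior_mcmc(a, n_iter = 3000, burn_in = 500, seed = 124)
  expect_false(identical(p1$samples, p3$samples))
  expect_error(posterior_mcmc(a, n_iter = 100, burn_in = 200, seed = 1),
    class = "weibcohort_config_error"
  )
})

test_that("the sampler reproduces the quadrature posterior on both fixtures", {
  for (g in c("A", "B")) {
    cohort <- clagm_cohort(g)
    post <- posterior_mcmc(cohort, seed = 42)
    quad <- posterior_quadrature(cohort)
    expect_lt(abs(post$point_estimate - quad$point_estimate), 0.02)
    expect_lt(tv_distance(post$samples, quad$grid, quad$density), 0.05)
    expect_gt(post$diagnostics$ess, 1000)
  }
})

test_that("an ill-tuned proposal triggers the acceptance-rate diagnostic warning", {
  expect_warning(
    posterior_mcmc(clagm_cohort("A"),
      n_iter = 2000, burn_in = 200,
      proposal_sd = 60, seed = 5
    ),
    "acceptance rate"
  )
})

test_that("posterior summaries are quantile-based, level-monotone, and non-mutating", {
  withr::with_seed(21, x <- rnorm(50000))
  s <- summarize_posterior(x, level = 0.90)
  expect_equal(s$point_estimate, 0, tolerance = 0.05)
  expect_equal(s$cri_lo, qnorm(0.05), tolerance = 0.05)
  expect_equal(s$cri_hi, qnorm(0.95), tolerance = 0.05)

  withr::with_seed(22, sym <- 2 + (rnorm(20000)) * 0.1)
  expect_equal(summarize_posterior(sym)$point_estimate, 2, tolerance = 0.01)

  post <- posterior_mcmc(clagm_cohort("A"), seed = 42)
  before <- post$cri
  s50 <- summarize_posterior(post, level = 0.50)
  s95 <- summarize_posterior(post, level = 0.95)
  expect_true(s50$cri_lo > s95$cri_lo && s50$cri_hi < s95$cri_hi)
  expect_identical(post$cri, before)

  expect_warning(summarize_posterior(rnorm(200)), "imprecise")
})

test_that("with more data the flat-prior posterior concentrates on the truth", {
  res <- lapply(c(50, 500), function(n) {
    cohort <- simulate_cohort(n, shape = 1.4, scale = 12, seed = 800 + n)
    posterior_quadrature(cohort)
  })
  err <- vapply(res, function(p) abs(p$point_estimate - 1.4), numeric(1))
  width <- vapply(res, function(p) diff(unname(p$cri)), numeric(1))
  expect_lt(err[2], 0.15)
  expect_lt(width[2], width[1])
  expect_lt(width[2], 0.35)
})

test_that("summaries carry the prior specification used", {
  g1 <- glance(posterior_quadrature(clagm_cohort("A"), prior = flat_prior()))
  g2 <- glance(posterior_quadrature(clagm_cohort("A"), prior = gamma_prior(2, 2)))
  expect_match(g1$prior, "flat")
  expect_match(g2$prior, "gamma")
  expect_false(isTRUE(all.equal(g1$point_estimate, g2$point_estimate)))
})
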