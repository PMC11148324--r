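# quick cohort constructor for hand-built cases
make_cohort <- function(t, e, group = "X", response = "UNKNOWN") {
  validate_cohort(tibble::tibble(
    patient_id = sprintf("%s%03d", group, seq_along(t)),
    group = group,
    os_months = t,
    event = e,
    response = response
  ))
}

# total-variation distance between a sample histogram and a quadrature density,
# both discretised on `bins` equal-width cells spanning the quadrature grid.
# The bin count is part of the definition: with very fine bins the Monte-Carlo
# noise of the histogram dominates the comparison.
tv_distance <- function(samples, grid, density, bins = 50) {
  br <- seq(min(grid), max(grid), length.out = bins + 1)
  h <- hist(pmin(pmax(samples, br[1]), br[bins + 1]), breaks = br, plot = FALSE)$counts
  h <- h / sum(h)
  mids <- (br[-1] + br[-(bins + 1)]) / 2
  q <- approx(grid, density, xout = mids, rule = 2)$y
  q <- q / sum(q)
  0.5 * sum(abs(h - q))
}

# independent term-by-term right-censored Weibull log-likelihood
# (kept deliberately naive: one term per record)
loglik_oracle <- function(t, e, shape, scale) {
  total <- 0
  for (i in seq_along(t)) {
    total <- total + if (e[i]) {
      log(shape) - shape * log(scale) + (shape - 1) * log(t[i]) - (t[i] / scale)^shape
    } else {
      -(t[i] / scale)^shape
    }
  }
  total
}

# independent MLE oracle via survreg's Weibull AFT parameterisation
survreg_shape_scale <- function(cohort) {
  sr <- survival::survreg(survival::Surv(os_months, event) ~ 1, data = cohort)
  c(shape = 1 / sr$scale, scale = unname(exp(coef(sr))))
}
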