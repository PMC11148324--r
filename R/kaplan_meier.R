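#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate of a right-censored cohort.
#' Censored observations tied with an event time are counted as at risk for
#' that event (the standard tie convention: censoring happens just after the
#' deaths). The curve is recorded at every distinct event time; a cohort with
#' no events yields an empty curve (survival identically 1).
#'
#' @param cohort A cohort tibble (see [validate_cohort()]).
#' @param label Optional label stored with the curve.
#'
#' @return A `km_curve` tibble with columns `event_time`, `at_risk`,
#'   `n_events`, `survival`, and attributes `n` (cohort size), `d` (total
#'   events), `label`.
#' @examples
#' km <- km_estimate(clagm_cohort("A"))
#' km
#' km_median(km) # 9 months
#' @export
km_estimate <- function(cohort, label = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(label)) label <- paste(unique(cohort$group), collapse = "+")
  d <- sum(cohort$event)
  if (d == 0) {
    curve <- tibble::tibble(
      event_time = numeric(), at_risk = integer(),
      n_events = integer(), survival = numeric()
    )
  } else {
    sf <- survival::survfit(
      survival::Surv(os_months, event) ~ 1,
      data = cohort, conf.type = "none"
    )
    keep <- sf$n.event > 0
    curve <- tibble::tibble(
      event_time = sf$time[keep],
      at_risk = as.integer(sf$n.risk[keep]),
      n_events = as.integer(sf$n.event[keep]),
      survival = sf$surv[keep]
    )
  }
  structure(curve,
    n = nrow(cohort), d = d, label = label,
    class = c("km_curve", class(curve))
  )
}

#' Kaplan-Meier median survival time
#'
#' The smallest event time at which the product-limit survival estimate drops
#' to 0.5 or below. Undefined (`NA`) when the curve never reaches 0.5, e.g.
#' under heavy censoring.
#'
#' @param curve A `km_curve` from [km_estimate()], or a cohort tibble (the
#'   curve is then computed first).
#' @return The median time, or `NA_real_` if undefined.
#' @export
km_median <- function(curve) {
  if (!inherits(curve, "km_curve")) curve <- km_estimate(curve)
  hit <- curve$survival <= 0.5 + 1e-12
  if (!any(hit)) {
    return(NA_real_)
  }
  min(curve$event_time[hit])
}

#' @describeIn km_estimate One-row curve summary.
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    events = attr(x, "d"),
    censored = attr(x, "n") - attr(x, "d"),
    median = km_median(x),
    label = attr(x, "label")
  )
}

#' @describeIn km_estimate Step-function plot of the survival curve.
#' @param object A `km_curve`.
#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- tibble::tibble(
    time = c(0, object$event_time),
    survival = c(1, object$survival)
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Time (months)", y = "Survival probability",
      title = paste("Kaplan-Meier estimate,", attr(object, "label"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier curve (%s): n = %d, events = %d, median = %s\n",
    attr(x, "label"), attr(x, "n"), attr(x, "d"),
    format(km_median(x))
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
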