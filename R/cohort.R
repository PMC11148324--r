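#' Response categories recognised in a cohort table
#'
#' Induction-response labels used throughout the package: complete remission
#' (`CR`), CR with partial hematologic recovery (`CRh`), partial response
#' (`PR`), refractory disease (`REFRACTORY`), and `UNKNOWN` for records whose
#' response was never assessed (simulated cohorts, minimal user data).
#'
#' @export
response_levels <- c("CR", "CRh", "PR", "REFRACTORY", "UNKNOWN")

#' MPAL cohort treated with CLAG-M
#'
#' Packaged per-patient survival records of a 16-patient mixed-phenotype acute
#' leukemia (MPAL) registry cohort treated with the CLAG-M regimen: Group A
#' received CLAG-M as first-line induction (overall survival measured from
#' diagnosis), Group B as salvage therapy (survival measured from CLAG-M
#' administration). Times are in whole months as recorded; the `event` flag is
#' `TRUE` when death was observed and `FALSE` for patients alive at last
#' follow-up (right-censored).
#'
#' @param group `"A"`, `"B"`, or `"ALL"` (both groups).
#'
#' @return A cohort tibble with columns `patient_id`, `group`, `os_months`,
#'   `event`, `response`, `death_cause`.
#'
#' @examples
#' clagm_cohort("A")
#' dplyr::count(clagm_cohort("ALL"), group, event)
#' @export
clagm_cohort <- function(group = c("ALL", "A", "B")) {
  group <- match.arg(group)
  a <- tibble::tibble(
    patient_id = sprintf("A%d", 1:8),
    group = "A",
    os_months = c(131, 15, 8, 9, 10, 6, 3, 5),
    event = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    response = c("CR", "CRh", "CRh", "CRh", "CR", "CR", "PR", "PR"),
    death_cause = c(
      NA, NA, "bleeding in course of GvHD", "sepsis in course of GvHD",
      "relapse", "relapse", NA, NA
    )
  )
  b <- tibble::tibble(
    patient_id = sprintf("B%d", 1:8),
    group = "B",
    os_months = c(28, 23, 23, 2, 11, 23, 9, 20),
    event = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    response = c(
      "CR", "CR", "CR", "REFRACTORY", "REFRACTORY", "CR",
      "REFRACTORY", "REFRACTORY"
    ),
    death_cause = c(
      "infection", "relapse", "infection", "refractory disease",
      NA, NA, "refractory disease", "relapse"
    )
  )
  out <- switch(group, A = a, B = b, ALL = dplyr::bind_rows(a, b))
  validate_cohort(out)
}

#' Validate and normalise a cohort data frame
#'
#' Checks the invariants every analysis function relies on: required columns
#' present, positive finite follow-up times, a logical (or 0/1) event
#' indicator, unique patient identifiers, and known response labels. Rows are
#' reported by number in error messages.
#'
#' @param cohort A data frame with at least `os_months` and `event`;
#'   `patient_id`, `group` and `response` are filled with defaults if absent.
#' @param time_col,event_col Column names holding follow-up time and the death
#'   indicator.
#'
#' @return The cohort as a tibble with canonical columns.
#' @export
validate_cohort <- function(cohort, time_col = "os_months", event_col = "event") {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame.")
  cohort <- tibble::as_tibble(cohort)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(cohort)) {
      abort(sprintf("required column `%s` is missing from the cohort.", col),
        class = "weibcohort_config_error"
      )
    }
  }
  if (!identical(time_col, "os_months")) names(cohort)[names(cohort) == time_col] <- "os_months"
  if (!identical(event_col, "event")) names(cohort)[names(cohort) == event_col] <- "event"

  t <- cohort$os_months
  if (!is.numeric(t)) {
    abort("`os_months` must be numeric.", class = "weibcohort_validation_error")
  }
  bad <- which(!is.finite(t) | t <= 0)
  if (length(bad)) {
    abort(
      sprintf(
        "`os_months` must be positive and finite; offending row(s): %s.",
        paste(bad, collapse = ", ")
      ),
      class = "weibcohort_validation_error"
    )
  }
  cohort$event <- parse_event(cohort$event)

  if (!"patient_id" %in% names(cohort)) {
    cohort$patient_id <- sprintf("P%03d", seq_len(nrow(cohort)))
  }
  cohort$patient_id <- as.character(cohort$patient_id)
  dup <- duplicated(cohort$patient_id)
  if (any(dup)) {
    abort(
      sprintf(
        "duplicate patient_id value(s): %s.",
        paste(unique(cohort$patient_id[dup]), collapse = ", ")
      ),
      class = "weibcohort_validation_error"
    )
  }
  if (!"group" %in% names(cohort)) cohort$group <- "ALL"
  cohort$group <- as.character(cohort$group)
  if (!"response" %in% names(cohort)) cohort$response <- "UNKNOWN"
  cohort$response <- as.character(cohort$response)
  unknown <- setdiff(unique(cohort$response), response_levels)
  if (length(unknown)) {
    abort(
      sprintf(
        "unrecognised response label(s): %s (known: %s).",
        paste(unknown, collapse = ", "), paste(response_levels, collapse = ", ")
      ),
      class = "weibcohort_validation_error"
    )
  }
  if (nrow(cohort) < 1) abort("cohort must contain at least one record.",
    class = "weibcohort_validation_error"
  )
  front <- intersect(c("patient_id", "group", "os_months", "event", "response"), names(cohort))
  dplyr::relocate(cohort, dplyr::all_of(front))
}

parse_event <- function(x) {
  if (is.logical(x)) {
    if (anyNA(x)) abort("`event` contains missing values.", class = "weibcohort_validation_error")
    return(x)
  }
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      abort("numeric `event` must be 0/1.", class = "weibcohort_validation_error")
    }
    return(x == 1)
  }
  if (is.character(x)) {
    lut <- c(
      "true" = TRUE, "t" = TRUE, "1" = TRUE, "yes" = TRUE, "dead" = TRUE,
      "false" = FALSE, "f" = FALSE, "0" = FALSE, "no" = FALSE, "alive" = FALSE
    )
    v <- lut[tolower(trimws(x))]
    if (anyNA(v)) {
      abort(
        sprintf(
          "cannot parse `event` value(s): %s.",
          paste(unique(x[is.na(v)]), collapse = ", ")
        ),
        class = "weibcohort_validation_error"
      )
    }
    return(unname(v))
  }
  abort("`event` must be logical, 0/1, or a recognisable string.",
    class = "weibcohort_validation_error"
  )
}

#' Read a cohort from a CSV file
#'
#' Reads a comma-separated file (header row required, UTF-8) into a validated
#' cohort tibble. Registry exports with arbitrary column names are supported
#' through `column_map`.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping canonical names to
#'   file columns, e.g. `c(os_months = "fu_time", event = "died")`.
#'
#' @return A cohort tibble (see [validate_cohort()]); row order is preserved.
#' @examples
#' path <- system.file("extdata", "clagm_cohort.csv", package = "weibcohort")
#' read_cohort_csv(path)
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "weibcohort_config_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src)) {
      abort(
        sprintf(
          "column_map refers to column(s) absent from %s: %s.",
          path, paste(missing_src, collapse = ", ")
        ),
        class = "weibcohort_config_error"
      )
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  validate_cohort(raw)
}

#' Tabulate treatment response and the overall response rate
#'
#' Counts records per response category and computes the overall response rate
#' (ORR) as the percentage of patients whose response falls in
#' `responder_set` (default: partial response or better, i.e. CR, CRh, PR).
#'
#' @param cohort A cohort tibble; no record may have response `UNKNOWN`.
#' @param responder_set Character vector of categories counted as responders.
#'
#' @return A `response_summary` tibble with one row per observed category
#'   (`response`, `n`, `responder`) and attributes `n_total`, `n_responders`,
#'   `orr` (percent); see [glance.response_summary()].
#' @examples
#' tabulate_response(clagm_cohort("ALL"))
#' glance(tabulate_response(clagm_cohort("A"), responder_set = c("CR", "CRh")))
#' @export
tabulate_response <- function(cohort, responder_set = c("CR", "CRh", "PR")) {
  cohort <- validate_cohort(cohort)
  if (any(cohort$response == "UNKNOWN")) {
    abort("cohort contains UNKNOWN response(s); response tabulation needs assessed responses.",
      class = "weibcohort_validation_error"
    )
  }
  responder_set <- match.arg(responder_set, response_levels, several.ok = TRUE)
  counts <- cohort |>
    dplyr::count(response = factor(.data$response, levels = response_levels),
      .drop = FALSE, name = "n"
    ) |>
    dplyr::filter(.data$n > 0 | as.character(.data$response) %in% responder_set) |>
    dplyr::mutate(
      response = as.character(.data$response),
      responder = .data$response %in% responder_set
    )
  n_total <- nrow(cohort)
  n_resp <- sum(cohort$response %in% responder_set)
  structure(counts,
    n_total = n_total, n_responders = n_resp,
    orr = 100 * n_resp / n_total, responder_set = responder_set,
    class = c("response_summary", class(counts))
  )
}

#' @describeIn tabulate_response One-row summary: `n`, `responders`, `orr`.
#' @param x A `response_summary`.
#' @param ... Unused.
#' @export
glance.response_summary <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n_total"),
    responders = attr(x, "n_responders"),
    orr = attr(x, "orr")
  )
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf(
    "Response summary: %d/%d responders (ORR %.1f%%; responder set: %s)\n",
    attr(x, "n_responders"), attr(x, "n_total"), attr(x, "orr"),
    paste(attr(x, "responder_set"), collapse = ", ")
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Sample median
#'
#' Plain sample median: the central order statistic for odd `n`, the midpoint
#' of the two central order statistics for even `n`. Distinct from the
#' Kaplan-Meier median ([km_median()]), which accounts for censoring; both are
#' reported because with heavy small-sample censoring they can differ a lot.
#'
#' @param values Non-empty numeric vector.
#' @return The median as a single number.
#' @examples
#' sample_median(clagm_cohort("B")$os_months) # 21.5
#' @export
sample_median <- function(values) {
  if (length(values) == 0) {
    abort("`values` must be non-empty.", class = "weibcohort_validation_error")
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort("`values` must be numeric without missing values.",
      class = "weibcohort_validation_error"
    )
  }
  median(values)
}
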