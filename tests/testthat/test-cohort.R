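test_that("packaged cohort reproduces the published per-group bookkeeping", {
  a <- clagm_cohort("A")
  b <- clagm_cohort("B")
  all <- clagm_cohort("ALL")

  expect_equal(nrow(a), 8)
  expect_equal(sum(a$event), 4)
  expect_equal(a$os_months, c(131, 15, 8, 9, 10, 6, 3, 5))
  expect_equal(a$response, c("CR", "CRh", "CRh", "CRh", "CR", "CR", "PR", "PR"))

  expect_equal(nrow(b), 8)
  expect_equal(sum(b$event), 6)
  expect_equal(b$os_months, c(28, 23, 23, 2, 11, 23, 9, 20))
  expect_equal(
    b$response,
    c("CR", "CR", "CR", "REFRACTORY", "REFRACTORY", "CR", "REFRACTORY", "REFRACTORY")
  )

  expect_equal(nrow(all), 16)
  expect_equal(sum(all$event), 10)
  expect_equal(all, dplyr::bind_rows(a, b))
})

test_that("response tabulation computes ORR and conserves counts", {
  rs_all <- tabulate_response(clagm_cohort("ALL"))
  expect_equal(attr(rs_all, "orr"), 75)
  expect_equal(attr(rs_all, "n_responders"), 12)
  expect_equal(sum(rs_all$n), 16)

  rs_cr <- tabulate_response(clagm_cohort("A"), responder_set = c("CR", "CRh"))
  expect_equal(attr(rs_cr, "n_responders"), 6)
  expect_equal(attr(rs_cr, "orr"), 75)

  g <- glance(tabulate_response(clagm_cohort("B"), responder_set = "CR"))
  expect_equal(g$responders, 4)
  expect_equal(g$orr, 50)

  everything <- setdiff(response_levels, "UNKNOWN")
  expect_equal(attr(tabulate_response(clagm_cohort("ALL"), everything), "orr"), 100)

  unknown <- make_cohort(c(3, 4), c(TRUE, FALSE))
  expect_error(tabulate_response(unknown), class = "weibcohort_validation_error")
})

test_that("cohort CSV reader round-trips the packaged data and validates input", {
  path <- system.file("extdata", "clagm_cohort.csv", package = "weibcohort")
  from_csv <- read_cohort_csv(path)
  fixture <- clagm_cohort("ALL")
  expect_equal(from_csv$os_months, fixture$os_months)
  expect_equal(from_csv$event, fixture$event)
  expect_equal(from_csv$response, fixture$response)
  expect_equal(from_csv$patient_id, fixture$patient_id)

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,os_months,event", "p1,5,1", "p2,8,0"), tmp)
  small <- read_cohort_csv(tmp)
  expect_equal(nrow(small), 2)
  expect_equal(small$event, c(TRUE, FALSE))

  writeLines(c("patient_id,os_months,event", "p1,0,1", "p2,8,0"), tmp)
  expect_error(read_cohort_csv(tmp), "row", class = "weibcohort_validation_error")

  writeLines(c("patient_id,os_months,event", "p1,5,1", "p1,8,0"), tmp)
  expect_error(read_cohort_csv(tmp), "duplicate", class = "weibcohort_validation_error")

  writeLines(c("patient_id,months,event", "p1,5,1"), tmp)
  expect_error(read_cohort_csv(tmp), class = "weibcohort_config_error")
  mapped <- read_cohort_csv(tmp, column_map = c(os_months = "months"))
  expect_equal(mapped$os_months, 5)

  expect_error(read_cohort_csv(tempfile()), class = "weibcohort_config_error")
})

test_that("cohort validation normalises event encodings and rejects bad rows", {
  df <- tibble::tibble(os_months = c(1, 2), event = c("yes", "no"))
  expect_equal(validate_cohort(df)$event, c(TRUE, FALSE))
  df01 <- tibble::tibble(os_months = c(1, 2), event = c(1, 0))
  expect_equal(validate_cohort(df01)$event, c(TRUE, FALSE))
  expect_error(
    validate_cohort(tibble::tibble(os_months = c(1, -2), event = c(1, 0))),
    "2", class = "weibcohort_validation_error"
  )
  expect_error(
    validate_cohort(tibble::tibble(os_months = 1, event = "maybe")),
    class = "weibcohort_validation_error"
  )
})

test_that("sample median matches order-statistic definition and ignores input order", {
  expect_equal(sample_median(clagm_cohort("B")$os_months), 21.5)
  expect_equal(sample_median(7), 7)
  expect_equal(sample_median(c(1, 2, 3, 4)), 2.5)
  expect_error(sample_median(numeric()), class = "weibcohort_validation_error")

  withr::with_seed(11, {
    for (i in 1:20) {
      x <- runif(sample(3:15, 1), 0, 100)
      expect_identical(sample_median(x), sample_median(sample(x)))
    }
  })
})
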