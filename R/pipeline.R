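#' Run the full small-cohort survival analysis and write a report bundle
#'
#' Orchestrates, per group: response tabulation (when responses are assessed),
#' the Kaplan-Meier curve with KM and sample medians, the right-censored
#' Weibull MLE report, Weibull probability-plot coordinates, and the
#' profile-likelihood shape posterior (Metropolis sampler cross-checked
#' against quadrature), plus the hazard-phase classification. When at least
#' two groups are analysed, the overlapping index between the first two
#' groups' shape posteriors is computed. All artifacts are written to
#' `output_dir` together with `manifest.json`, which records the inputs,
#' seeds, prior, and settings needed to reproduce every number. Any stage
#' failure aborts with the stage name and removes the partial outputs.
#'
#' @param input `"A"`, `"B"`, `"ALL"` (the packaged MPAL cohort) or a path to
#'   a cohort CSV (see [read_cohort_csv()]).
#' @param output_dir Directory for the report bundle (created if needed).
#' @param groups Group labels to analyse (default: all groups in the input).
#' @param level Confidence/credibility level (default 0.90).
#' @param prior A `prior_spec` for the shape posterior (default [flat_prior()]).
#' @param n_iter,burn_in,proposal_sd Metropolis settings (see
#'   [posterior_mcmc()]).
#' @param seed Integer seed; group `i` uses `seed + i - 1`. Required.
#' @param time_unit_factor Days per month used only for display columns
#'   (default 30.44); model quantities stay in the input time unit.
#' @param column_map Optional column mapping passed to [read_cohort_csv()].
#'
#' @return Invisibly, a list with the `manifest` and the fitted objects
#'   (`fits`, `posteriors`, `km`, `overlap`).
#' @examples
#' \donttest{
#' out <- run_pipeline("ALL", output_dir = tempfile("bundle"),
#'   n_iter = 4000, burn_in = 1000, seed = 1)
#' names(out$manifest$groups)
#' }
#' @export
run_pipeline <- function(input = "ALL", output_dir, groups = NULL,
                         level = 0.90, prior = flat_prior(),
                         n_iter = 50000, burn_in = 5000, proposal_sd = 0.3,
                         seed, time_unit_factor = 30.44, column_map = NULL) {
  if (missing(seed)) {
    abort("`seed` is required for run_pipeline.", class = "weibcohort_config_error")
  }
  seed <- as.integer(seed)
  if (!(level > 0 && level < 1)) {
    abort("`level` must be in (0, 1).", class = "weibcohort_config_error")
  }
  check_positive(time_unit_factor, "time_unit_factor")

  cohort <- if (is.character(input) && input %in% c("A", "B", "ALL")) {
    clagm_cohort(input)
  } else {
    read_cohort_csv(input, column_map = column_map)
  }
  if (is.null(groups)) groups <- unique(cohort$group)
  missing_groups <- setdiff(groups, unique(cohort$group))
  if (length(missing_groups)) {
    abort(sprintf("group(s) not in input: %s", paste(missing_groups, collapse = ", ")),
      class = "weibcohort_config_error"
    )
  }

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character()
  stage <- "setup"
  emit_csv <- function(df, file) {
    path <- file.path(output_dir, file)
    readr::write_csv(df, path)
    created <<- c(created, path)
    file
  }
  emit_json <- function(x, file) {
    path <- file.path(output_dir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    created <<- c(created, path)
    file
  }

  result <- tryCatch(
    {
      manifest <- list(
        package = "weibcohort",
        version = as.character(packageVersion("weibcohort")),
        input = if (input %in% c("A", "B", "ALL")) paste0("fixture:", input) else input,
        level = level,
        prior = prior$label,
        mcmc = list(
          n_iter = n_iter, burn_in = burn_in,
          proposal_sd = proposal_sd, base_seed = seed
        ),
        time_unit_factor = time_unit_factor,
        groups = list(),
        files = character()
      )
      fits <- list()
      posts <- list()
      kms <- list()

      for (i in seq_along(groups)) {
        g <- groups[i]
        seed_g <- seed + i - 1L
        sub <- dplyr::filter(cohort, .data$group == g)
        ginfo <- list(n = nrow(sub), events = sum(sub$event), seed = seed_g)

        stage <- sprintf("response tabulation (group %s)", g)
        if (!any(sub$response == "UNKNOWN")) {
          rs <- tabulate_response(sub)
          manifest$files <- c(manifest$files, emit_csv(
            tibble::as_tibble(rs), sprintf("group_%s_response.csv", g)
          ))
          ginfo$orr <- attr(rs, "orr")
          ginfo$responders <- attr(rs, "n_responders")
        }

        stage <- sprintf("Kaplan-Meier estimation (group %s)", g)
        km <- km_estimate(sub, label = g)
        kms[[g]] <- km
        manifest$files <- c(manifest$files, emit_csv(
          tibble::as_tibble(km), sprintf("group_%s_km.csv", g)
        ))
        ginfo$km_median <- km_median(km)
        ginfo$sample_median <- sample_median(sub$os_months)

        stage <- sprintf("Weibull MLE (group %s)", g)
        fit <- weibull_mle(sub, level = level)
        fits[[g]] <- fit
        report <- fit_report(fit)
        report$scale_days <- fit$scale * time_unit_factor
        manifest$files <- c(manifest$files, emit_csv(
          report, sprintf("group_%s_weibull_fit.csv", g)
        ))
        ginfo$shape <- fit$shape
        ginfo$scale <- fit$scale
        ginfo$hazard <- as.character(classify_hazard(fit$shape))

        stage <- sprintf("Weibull plot coordinates (group %s)", g)
        manifest$files <- c(manifest$files, emit_csv(
          tibble::as_tibble(weibull_plot_points(sub, level = level)),
          sprintf("group_%s_weibull_plot.csv", g)
        ))

        stage <- sprintf("shape posterior (group %s)", g)
        post <- posterior_mcmc(sub,
          prior = prior, n_iter = n_iter, burn_in = burn_in,
          proposal_sd = proposal_sd, seed = seed_g, level = level
        )
        quad <- posterior_quadrature(sub, prior = prior, level = level)
        posts[[g]] <- post
        manifest$files <- c(manifest$files, emit_csv(
          tibble::tibble(shape = post$samples),
          sprintf("group_%s_posterior_samples.csv", g)
        ))
        manifest$files <- c(manifest$files, emit_json(
          list(
            mcmc = as.list(glance(post)),
            quadrature = as.list(glance(quad)),
            median_disagreement = abs(post$point_estimate - quad$point_estimate)
          ),
          sprintf("group_%s_posterior.json", g)
        ))
        ginfo$posterior_median <- post$point_estimate
        ginfo$cri <- unname(post$cri)

        manifest$groups[[g]] <- ginfo
      }

      overlap <- NULL
      if (length(groups) >= 2) {
        stage <- sprintf("overlap (%s vs %s)", groups[1], groups[2])
        overlap <- overlap_index(
          posts[[groups[1]]]$samples, posts[[groups[2]]]$samples
        )
        manifest$files <- c(manifest$files, emit_json(
          as.list(glance(overlap)), "overlap.json"
        ))
        manifest$overlap <- list(
          groups = groups[1:2], oi = overlap$oi, one_minus_oi = overlap$one_minus_oi
        )
      }

      stage <- "manifest"
      emit_json(manifest, "manifest.json")
      list(manifest = manifest, fits = fits, posteriors = posts, km = kms, overlap = overlap)
    },
    error = function(e) {
      suppressWarnings(file.remove(created[file.exists(created)]))
      abort(sprintf("pipeline failed at stage [%s]: %s", stage, conditionMessage(e)),
        class = "weibcohort_pipeline_error"
      )
    }
  )
  invisible(result)
}

cli_usage <- function() {
  paste(
    "usage: weibcohort <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  report    full pipeline          --input A|B|ALL|file.csv --out DIR --seed INT",
    "            [--level F --iters N --burn-in N --proposal-sd F --prior-upper F --config FILE]",
    "  fit       Weibull MLE            --input ... [--out FILE.csv --level F]",
    "  km        Kaplan-Meier curve     --input ... [--out FILE.csv]",
    "  bayes     shape posterior (MCMC) --input ... --seed INT [--iters N --burn-in N]",
    "  overlap   posterior overlap of the first two groups --input ... --seed INT",
    "  simulate  synthetic cohort       --n INT --shape F --scale F --seed INT",
    "            [--censoring none|admin|uniform --cens-time F --cens-range LO,HI --out FILE.csv]",
    "",
    "Config files are flat `key: value` lines; command-line flags take precedence.",
    sep = "\n"
  )
}

parse_cli <- function(args) {
  if (length(args) == 0) return(NULL)
  cmd <- args[1]
  args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      abort(sprintf("unexpected argument: %s", a), class = "weibcohort_usage_error")
    }
    a <- sub("^--", "", a)
    if (grepl("=", a, fixed = TRUE)) {
      key <- sub("=.*$", "", a)
      val <- sub("^[^=]*=", "", a)
    } else {
      key <- a
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        abort(sprintf("flag --%s needs a value", key), class = "weibcohort_usage_error")
      }
      val <- args[i + 1]
      i <- i + 1
    }
    opts[[gsub("-", "_", key)]] <- val
    i <- i + 1
  }
  list(cmd = cmd, opts = opts)
}

read_flat_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "weibcohort_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    if (!grepl(":", l, fixed = TRUE)) {
      abort(sprintf("config line is not `key: value`: %s", l),
        class = "weibcohort_config_error"
      )
    }
    key <- gsub("-", "_", trimws(sub(":.*$", "", l)))
    out[[key]] <- trimws(sub("^[^:]*:", "", l))
  }
  out
}

#' Command-line entry point
#'
#' Thin argv-level interface over the package functions, used by the
#' `inst/cli/weibcohort.R` wrapper script. Subcommands: `report` (full
#' pipeline), `fit`, `km`, `bayes`, `overlap`, `simulate`. Stochastic
#' subcommands require `--seed`. A `--config` file of flat `key: value` lines
#' supplies defaults; explicit flags win. Logs go to standard error.
#'
#' @param args Character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly: 0 on success, 1 on a runtime
#'   failure, 2 on a usage error.
#' @examples
#' cohort_cli(c("fit", "--input", "A"))
#' @export
cohort_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_cli(args), error = function(e) e)
  if (is.null(parsed)) {
    message(cli_usage())
    return(invisible(2L))
  }
  if (inherits(parsed, "error")) {
    message("error: ", conditionMessage(parsed), "\n\n", cli_usage())
    return(invisible(2L))
  }
  cmd <- parsed$cmd
  opts <- parsed$opts
  if (!cmd %in% c("report", "fit", "km", "bayes", "overlap", "simulate")) {
    message("unknown subcommand: ", cmd, "\n\n", cli_usage())
    return(invisible(2L))
  }
  if (!is.null(opts$config)) {
    cfg <- tryCatch(read_flat_config(opts$config), error = function(e) e)
    if (inherits(cfg, "error")) {
      message("error: ", conditionMessage(cfg))
      return(invisible(1L))
    }
    for (key in names(cfg)) if (is.null(opts[[key]])) opts[[key]] <- cfg[[key]]
  }
  if (cmd %in% c("report", "bayes", "overlap", "simulate") && is.null(opts$seed)) {
    message(sprintf("error: --seed is required for `%s`\n\n%s", cmd, cli_usage()))
    return(invisible(2L))
  }

  num <- function(x, default = NULL) if (is.null(x)) default else as.numeric(x)
  status <- tryCatch(
    {
      switch(cmd,
        report = {
          out_dir <- opts$out %||% "weibcohort_report"
          prior <- flat_prior(upper = num(opts$prior_upper, 10))
          run_pipeline(
            input = opts$input %||% "ALL", output_dir = out_dir,
            level = num(opts$level, 0.90), prior = prior,
            n_iter = num(opts$iters, 50000), burn_in = num(opts$burn_in, 5000),
            proposal_sd = num(opts$proposal_sd, 0.3),
            seed = as.integer(opts$seed)
          )
          message("report bundle written to ", out_dir)
        },
        fit = {
          cohort <- cli_cohort(opts)
          report <- fit_report(weibull_mle(cohort, level = num(opts$level, 0.90)))
          cli_emit(report, opts$out)
        },
        km = {
          cohort <- cli_cohort(opts)
          cli_emit(tibble::as_tibble(km_estimate(cohort)), opts$out)
        },
        bayes = {
          cohort <- cli_cohort(opts)
          post <- posterior_mcmc(cohort,
            n_iter = num(opts$iters, 50000), burn_in = num(opts$burn_in, 5000),
            proposal_sd = num(opts$proposal_sd, 0.3),
            seed = as.integer(opts$seed), level = num(opts$level, 0.90)
          )
          cat(jsonlite::toJSON(as.list(glance(post)), auto_unbox = TRUE, digits = NA), "\n")
        },
        overlap = {
          cohort <- cli_cohort(opts)
          gs <- unique(cohort$group)
          if (length(gs) < 2) {
            abort("overlap needs an input with at least two groups.",
              class = "weibcohort_config_error"
            )
          }
          seed <- as.integer(opts$seed)
          posts <- lapply(seq_len(2), function(i) {
            posterior_mcmc(dplyr::filter(cohort, .data$group == gs[i]),
              n_iter = num(opts$iters, 50000), burn_in = num(opts$burn_in, 5000),
              seed = seed + i - 1L
            )
          })
          ov <- overlap_index(posts[[1]]$samples, posts[[2]]$samples)
          cat(jsonlite::toJSON(as.list(glance(ov)), auto_unbox = TRUE, digits = NA), "\n")
        },
        simulate = {
          cens_range <- if (!is.null(opts$cens_range)) {
            as.numeric(strsplit(opts$cens_range, ",")[[1]])
          }
          cohort <- simulate_cohort(
            n = num(opts$n), shape = num(opts$shape), scale = num(opts$scale),
            censoring = opts$censoring %||% "none",
            cens_time = num(opts$cens_time), cens_range = cens_range,
            seed = as.integer(opts$seed)
          )
          cli_emit(cohort, opts$out)
        }
      )
      0L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(status)
}

cli_cohort <- function(opts) {
  input <- opts$input %||% "ALL"
  cohort <- if (input %in% c("A", "B", "ALL")) {
    clagm_cohort(input)
  } else {
    read_cohort_csv(input)
  }
  if (!is.null(opts$group)) cohort <- dplyr::filter(cohort, .data$group == opts$group)
  cohort
}

cli_emit <- function(df, out) {
  if (is.null(out)) {
    cat(readr::format_csv(df))
  } else {
    readr::write_csv(df, out)
    message("written to ", out)
  }
}
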