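# End-to-end orchestration: data (read or simulate) -> reach graph -> MGS ->
# inclusion filter -> analysis table -> mixed models, collinearity
# diagnostics and likelihood-ratio comparisons -> report.

# run `expr`, prefixing any error with the pipeline stage that raised it
.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full mating-group / sex-allocation analysis
#'
#' Accepts a CSV path, a validated individuals data frame, or a
#' [generator_config()] (in which case a synthetic population is generated
#' first). Builds the penis-reach graph on all individuals, derives MGSm and
#' MGSf, applies the inclusion filter, assembles the analysis table, fits the
#' four response models (testis + seminal vesicles, penis, ovary, sex
#' allocation), computes predictor VIFs and the MGSm-MGSf correlation, and
#' compares each full model against the model without MGSf by likelihood
#' ratio.
#'
#' @param input CSV path, individuals `data.frame`, or `generator_config`.
#' @param config A [study_config()] controlling reach and inclusion.
#' @param out_dir Optional directory; when given, writes the individuals CSV
#'   (for generated data), analysis table, edge list, model report, and a
#'   stage-stamped run log there.
#' @param responses Responses to model (default all four).
#' @return An object of class `run_report`.
#' @export
run_analysis <- function(input, config = study_config(), out_dir = NULL,
                         responses = c("testis_sv", "penis", "ovary",
                                       "sex_allocation")) {
  responses <- match.arg(responses, several.ok = TRUE)
  log_lines <- character()
  log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
  }

  truth <- NULL
  generated <- FALSE
  records <- .with_stage("input", {
    if (inherits(input, "generator_config")) {
      generated <- TRUE
      sim <- generate_population(input)
      truth <- sim$truth
      log("generated %d individuals on %d shells (seed %d, mode %s)",
          nrow(sim$records), input$n_shells, input$seed, input$mode)
      sim$records
    } else if (is.character(input)) {
      r <- read_individuals(input, config)
      log("read %d individuals from %s", nrow(r), input)
      r
    } else {
      assert_valid_records(input)
      log("received %d individuals in memory", nrow(input))
      input
    }
  })

  graph <- .with_stage("mating_graph", build_mating_graph(records, config))
  mgs <- .with_stage("mating_graph", compute_mgs(graph))
  log("built mating graph: %d directed edges on %d shells",
      nrow(graph$edges), length(unique(records$shell_id)))

  flags <- .with_stage("inclusion_filter",
                       apply_inclusion_filter(records, mgs, config))
  n_input <- nrow(records)
  n_isolated <- sum(grepl("isolated", flags$exclusion_reason))
  n_missing <- sum(grepl("missing_organ", flags$exclusion_reason))
  log("inclusion filter: %d input, %d excluded isolated, %d excluded with missing organs",
      n_input, n_isolated, n_missing)

  table <- .with_stage("allocation",
                       build_analysis_table(records, flags, config))
  log("analysis table: %d individuals on %d shells", nrow(table),
      length(unique(table$shell_id)))

  descriptives <- .with_stage("allocation", list(
    n_input = n_input,
    n_excluded_isolated = n_isolated,
    n_excluded_missing_organ = n_missing,
    n_analyzed = nrow(table),
    n_shells = length(unique(table$shell_id)),
    penis_length_range_cm = range(records$penis_length_cm),
    operculum_weight_range_mg = range(table$body_weight_mg),
    testis_sv_range_mg = range(table$male_variable_mg),
    penis_weight_range_mg = range(table$male_fixed_mg),
    ovary_range_mg = range(table$female_variable_mg),
    mgs_m_range = range(table$mgs_m),
    mgs_f_range = range(table$mgs_f),
    mean_penis_fraction_pct = mean(
      penis_fraction_of_male_output(table$male_fixed_mg,
                                    table$male_variable_mg))
  ))

  fits <- .with_stage("inference", {
    stats::setNames(lapply(responses, function(r) fit_lmm(table, r)),
                    responses)
  })
  vifs <- .with_stage("inference", vif(table))
  mgs_correlation <- .with_stage("inference",
                                 pearson_r(table$mgs_m, table$mgs_f))
  lrts <- .with_stage("inference", {
    stats::setNames(lapply(responses, function(r) {
      reduced <- fit_lmm(table, r, fixed = c("mgs_m", "body_weight"))
      likelihood_ratio_test(fits[[r]], reduced)
    }), responses)
  })
  log("fitted %d mixed models; VIF max %.3f; MGSm-MGSf r = %.3f",
      length(fits), max(vifs), mgs_correlation$r)

  report <- structure(
    list(
      config = config,
      seed = if (generated) input$seed else config$seed,
      generated = generated,
      truth = truth,
      descriptives = descriptives,
      fits = fits,
      vif = vifs,
      mgs_correlation = mgs_correlation,
      lrt_mgs_f = lrts,
      table = table,
      graph = graph,
      flags = flags,
      log = log_lines
    ),
    class = "run_report"
  )

  if (!is.null(out_dir)) {
    .with_stage("output", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (generated) {
        write_individuals(records, file.path(out_dir, "individuals.csv"))
        write_truth(truth, file.path(out_dir, "truth.json"))
      }
      write_analysis_table(table, file.path(out_dir, "analysis_table.csv"))
      write_edge_list(graph, file.path(out_dir, "edge_list.csv"))
      utils::write.csv(
        flags, file.path(out_dir, "mgs.csv"), row.names = FALSE, quote = FALSE
      )
      write_model_report(report, file.path(out_dir, "model_report.csv"))
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    })
  }
  report
}

#' Write the model-report CSV of a run
#'
#' One row per (response, term): estimate, standard error, p-value, plus the
#' fitting criterion -- structurally parallel to a published LMM coefficient
#' table.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  rows <- lapply(names(report$fits), function(r) {
    co <- report$fits[[r]]$coefficients
    data.frame(response = r, co, criterion = report$fits[[r]]$criterion,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  d <- x$descriptives
  cat("Mating-group / sex-allocation analysis\n")
  cat(sprintf("  %d individuals analyzed of %d (%d isolated, %d missing organs) on %d shells\n",
              d$n_analyzed, d$n_input, d$n_excluded_isolated,
              d$n_excluded_missing_organ, d$n_shells))
  cat(sprintf("  MGSm range %d-%d, MGSf range %d-%d; MGSm-MGSf r = %.3f\n",
              d$mgs_m_range[1], d$mgs_m_range[2], d$mgs_f_range[1],
              d$mgs_f_range[2], x$mgs_correlation$r))
  cat(sprintf("  VIF: %s\n",
              paste(sprintf("%s %.3f", names(x$vif), x$vif),
                    collapse = ", ")))
  cat(sprintf("  mean penis share of male output: %.2f%%\n",
              d$mean_penis_fraction_pct))
  for (r in names(x$fits)) {
    print(x$fits[[r]])
    lrt <- x$lrt_mgs_f[[r]]
    cat(sprintf("  LRT vs model without MGSf: chi-square = %.3f, df = %d, p = %.3g\n",
                lrt$chi_square, lrt$df, lrt$p))
  }
  invisible(x)
}

#' Replicated simulate-and-refit recovery experiment
#'
#' Repeatedly generates a population from `gen_config` (seeds derived from
#' the master seed), runs the full pipeline, and summarizes how well the
#' fitted fixed effects recover the generating coefficients: mean and SD of
#' the estimates, bias, and coverage of nominal 95% Wald intervals.
#'
#' @param gen_config A [generator_config()]; its `seed` is the master seed.
#' @param replicates Number of replicates (>= 1).
#' @param responses Responses to track; defaults to the responses with exact
#'   linear generating truth in the configured mode (`sex_allocation`,
#'   `ovary`, `penis` for allocation-level data; the three organs for
#'   organ-level data).
#' @return An object of class `recovery_summary`: data frame with one row
#'   per (response, term) and columns truth, mean_estimate, sd_estimate,
#'   bias, se_of_mean, coverage_95, plus attributes `replicates` and
#'   `n_failed`.
#' @export
run_recovery <- function(gen_config = generator_config(), replicates = 100,
                         responses = NULL) {
  stopifnot(inherits(gen_config, "generator_config"), replicates >= 1)
  if (is.null(responses)) {
    responses <- if (gen_config$mode == "allocation_level") {
      c("sex_allocation", "ovary", "penis")
    } else {
      c("testis_sv", "penis", "ovary")
    }
  }
  master <- gen_config$seed
  estimates <- list()
  n_failed <- 0L
  for (i in seq_len(replicates)) {
    cfg <- gen_config
    cfg$seed <- as.integer((master + i) %% .Machine$integer.max)
    rep_result <- tryCatch({
      report <- run_analysis(cfg, config = cfg$study, responses = responses)
      do.call(rbind, lapply(responses, function(r) {
        co <- report$fits[[r]]$coefficients
        data.frame(replicate = i, response = r, co,
                   stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      warning(sprintf("replicate %d failed and was excluded: %s", i,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(rep_result)) n_failed <- n_failed + 1L
    else estimates[[length(estimates) + 1L]] <- rep_result
  }
  if (length(estimates) == 0) stop("every recovery replicate failed")
  est <- do.call(rbind, estimates)

  truth_of <- function(response, term) {
    beta <- gen_config$coefficients[[response]]
    unname(beta[[term]])
  }
  keys <- unique(est[, c("response", "term")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- est[est$response == keys$response[k] & est$term == keys$term[k], ]
    tr <- truth_of(keys$response[k], keys$term[k])
    covered <- abs(sub$estimate - tr) <= 1.96 * sub$se
    data.frame(
      response = keys$response[k],
      term = keys$term[k],
      truth = tr,
      mean_estimate = mean(sub$estimate),
      sd_estimate = stats::sd(sub$estimate),
      bias = mean(sub$estimate) - tr,
      se_of_mean = stats::sd(sub$estimate) / sqrt(nrow(sub)),
      coverage_95 = mean(covered),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows),
            replicates = replicates, n_failed = n_failed,
            class = c("recovery_summary", "data.frame"))
}
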