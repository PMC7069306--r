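# Mixed-model inference on the analysis table.
#
# Each response (testis + seminal vesicles, penis, ovary, sex allocation) is
# modeled as a linear mixed model with fixed effects MGSm + MGSf + body
# weight, no interactions, and a random intercept per substrate shell.
# Coefficient tables use the restricted-likelihood fit (the conventional
# lme4/lmerTest default); likelihood-ratio comparisons refit both models by
# plain maximum likelihood. The criterion used is recorded in every fit.

# analysis-table column backing each response / predictor term
.response_columns <- c(
  testis_sv = "male_variable_mg",
  penis = "male_fixed_mg",
  ovary = "female_variable_mg",
  sex_allocation = "sex_allocation"
)
.predictor_columns <- c(
  mgs_m = "mgs_m",
  mgs_f = "mgs_f",
  body_weight = "body_weight_mg"
)

#' Fit a shell random-intercept linear mixed model
#'
#' Fits `response ~ MGSm + MGSf + body weight + (1 | shell)` (or a subset of
#' those fixed effects) with `lmerTest`, returning fixed coefficients with
#' standard errors and Satterthwaite p-values, the shell and residual
#' variance components, and the log-likelihood under the criterion used.
#'
#' @param table An `analysis_table` (or data frame with the same columns).
#' @param response One of `"testis_sv"`, `"penis"`, `"ovary"`,
#'   `"sex_allocation"`.
#' @param fixed Character vector of fixed-effect terms to include, a subset
#'   of `c("mgs_m", "mgs_f", "body_weight")`.
#' @param reml Fit by restricted maximum likelihood (default, for coefficient
#'   tables) or plain maximum likelihood (for likelihood-ratio comparisons).
#' @return An object of class `lmm_fit`: response name, `coefficients` data
#'   frame (term, estimate, se, df, p), `shell_var`, `residual_var`,
#'   `logLik`, `criterion`, `n_obs`, `n_shells`, fitting warnings, and the
#'   underlying `lmerMod`.
#' @export
fit_lmm <- function(table,
                    response = c("sex_allocation", "testis_sv", "penis",
                                 "ovary"),
                    fixed = c("mgs_m", "mgs_f", "body_weight"),
                    reml = TRUE) {
  response <- match.arg(response)
  stopifnot(nrow(table) > 0, all(fixed %in% names(.predictor_columns)),
            length(fixed) >= 1)
  resp_col <- .response_columns[[response]]
  pred_cols <- .predictor_columns[fixed]
  n_shells <- length(unique(table$shell_id))
  if (n_shells < 2) {
    stop("random intercept unidentifiable with a single shell")
  }
  X <- as.matrix(cbind(1, as.data.frame(table)[, pred_cols, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect predictors are perfectly collinear")
  }
  d <- data.frame(
    .y = as.data.frame(table)[[resp_col]],
    shell_id = factor(table$shell_id),
    as.data.frame(table)[, pred_cols, drop = FALSE]
  )
  form <- stats::as.formula(paste(
    ".y ~", paste(pred_cols, collapse = " + "), "+ (1 | shell_id)"
  ))
  warns <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = d, REML = reml),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  sm <- suppressMessages(summary(fit))
  co <- sm$coefficients
  term <- c("intercept", fixed)
  coefficients <- data.frame(
    term = term,
    estimate = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    df = if ("df" %in% colnames(co)) unname(co[, "df"]) else NA_real_,
    p = unname(co[, ncol(co)]),
    stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      response = response,
      coefficients = coefficients,
      shell_var = vc$vcov[vc$grp == "shell_id"],
      residual_var = vc$vcov[vc$grp == "Residual"],
      logLik = as.numeric(stats::logLik(fit)),
      criterion = if (reml) "REML" else "ML",
      n_obs = nrow(d),
      n_shells = n_shells,
      fixed = fixed,
      warnings = warns,
      model = fit
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s ~ %s + (1 | shell)   [%s]\n",
              x$response, paste(x$fixed, collapse = " + "), x$criterion))
  cat(sprintf("  n = %d individuals on %d shells\n", x$n_obs, x$n_shells))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  shell variance %.4g, residual variance %.4g, logLik %.3f\n",
              x$shell_var, x$residual_var, x$logLik))
  if (length(x$warnings) > 0) {
    cat("  fitting warnings:", length(x$warnings), "\n")
  }
  invisible(x)
}

#' Coefficients of an lmm_fit as a named vector
#'
#' @param object An `lmm_fit`.
#' @param ... Unused.
#' @return Named numeric vector (`intercept` plus fitted terms).
#' @export
coef.lmm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of determination
#' of an ordinary least-squares regression (with intercept) of predictor j on
#' the remaining predictors. Values above 10 conventionally flag harmful
#' collinearity. A perfectly collinear predictor is reported as `Inf`.
#'
#' @param table Data frame holding the predictor columns.
#' @param predictors Character vector (length >= 2) of predictor column
#'   names; defaults to the analysis-table predictors.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(table, predictors = c("mgs_m", "mgs_f", "body_weight_mg")) {
  stopifnot(length(predictors) >= 2, all(predictors %in% names(table)))
  d <- as.data.frame(table)[, predictors, drop = FALSE]
  for (p in predictors) {
    if (stats::var(d[[p]]) == 0) {
      stop("predictor '", p, "' has zero variance")
    }
  }
  out <- stats::setNames(numeric(length(predictors)), predictors)
  for (p in predictors) {
    form <- stats::as.formula(paste0(
      "`", p, "` ~ ", paste0("`", setdiff(predictors, p), "`",
                             collapse = " + ")
    ))
    # a perfectly collinear predictor triggers lm's perfect-fit warning;
    # that case is reported as an infinite VIF below, so silence it here
    r2 <- suppressWarnings(summary(stats::lm(form, data = d))$r.squared)
    out[p] <- if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Pearson product-moment correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return List with `r`, `p` (two-sided, t-based), and `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Likelihood-ratio statistic from two log-likelihoods
#'
#' `chi_square = 2 (logLik_full - logLik_reduced)`, floored at 0 with a
#' warning when the optimizer left the full model below the reduced one, and
#' an upper-tail chi-square p-value.
#'
#' @param logLik_full,logLik_reduced Log-likelihoods of the nested pair.
#' @param df Difference in number of fixed-effect parameters.
#' @return List with `chi_square`, `df`, `p`.
#' @export
lrt_from_loglik <- function(logLik_full, logLik_reduced, df) {
  stopifnot(df >= 1)
  chi <- 2 * (logLik_full - logLik_reduced)
  if (chi < 0) {
    warning("negative likelihood-ratio statistic floored at 0 ",
            "(optimizer failure?)")
    chi <- 0
  }
  list(chi_square = chi, df = as.integer(df),
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested mixed models
#'
#' The reduced model's fixed effects must be a strict subset of the full
#' model's, on the same data and random structure. Both models are refit by
#' plain maximum likelihood before comparison (restricted likelihoods of
#' models with different fixed effects are not comparable).
#'
#' @param full,reduced `lmm_fit` objects for the same response and data.
#' @return List with `chi_square`, `df`, `p`, and the ML log-likelihoods
#'   `logLik_full`, `logLik_reduced`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (!identical(full$response, reduced$response) ||
      full$n_obs != reduced$n_obs || full$n_shells != reduced$n_shells) {
    stop("models must be fitted to the same response and data")
  }
  if (!all(reduced$fixed %in% full$fixed) ||
      length(reduced$fixed) >= length(full$fixed)) {
    stop("reduced model's fixed effects must be a strict subset of ",
         "the full model's")
  }
  ml_full <- if (full$criterion == "REML") lme4::refitML(full$model)
             else full$model
  ml_reduced <- if (reduced$criterion == "REML") lme4::refitML(reduced$model)
                else reduced$model
  ll_f <- as.numeric(stats::logLik(ml_full))
  ll_r <- as.numeric(stats::logLik(ml_reduced))
  res <- lrt_from_loglik(ll_f, ll_r, length(full$fixed) - length(reduced$fixed))
  c(res, list(logLik_full = ll_f, logLik_reduced = ll_r))
}

#' Marginal regression line of a fitted (or published) model
#'
#' The partial-prediction line of one predictor with the others held at
#' chosen values: slope is the varied predictor's coefficient, intercept is
#' the model intercept plus the held predictors' contributions. This is how
#' the study's sex-allocation-versus-MGS figures are drawn (other MGS at its
#' modal value, body weight at its mean).
#'
#' @param fit An `lmm_fit`, or a named numeric coefficient vector with an
#'   `intercept` element (e.g. one entry of [default_coefficient_sets()]).
#' @param vary Name of the predictor on the x axis.
#' @param held Named numeric vector/list giving the value of every other
#'   predictor in the fit.
#' @return An object of class `marginal_line`: `slope`, `intercept`, `vary`,
#'   `held`.
#' @export
marginal_line <- function(fit, vary, held) {
  cf <- if (inherits(fit, "lmm_fit")) coef(fit) else unlist(fit)
  stopifnot(is.numeric(cf), "intercept" %in% names(cf))
  terms <- setdiff(names(cf), "intercept")
  if (!vary %in% terms) stop("'", vary, "' is not a predictor of this fit")
  others <- setdiff(terms, vary)
  held <- unlist(held)
  missing_held <- setdiff(others, names(held))
  if (length(missing_held) > 0) {
    stop("held values missing for: ", paste(missing_held, collapse = ", "))
  }
  intercept <- unname(cf["intercept"] + sum(cf[others] * held[others]))
  structure(
    list(slope = unname(cf[vary]), intercept = intercept, vary = vary,
         held = held[others]),
    class = "marginal_line"
  )
}

#' @export
print.marginal_line <- function(x, ...) {
  cat(sprintf("y = %.4f x %+.4f   (x = %s; held: %s)\n", x$slope,
              x$intercept, x$vary,
              paste(sprintf("%s = %g", names(x$held), x$held),
                    collapse = ", ")))
  invisible(x)
}

#' Sign stability between simple and multiple regressions
#'
#' Collinearity diagnostic: for each predictor, compares the sign of its
#' coefficient in the full mixed model against a single-predictor mixed model
#' of the same response. Sign flips suggest collinearity distorting the
#' multiple regression.
#'
#' @param table An `analysis_table`.
#' @param response Response name as in [fit_lmm()].
#' @return Data frame with columns term, estimate_simple, estimate_multiple,
#'   stable.
#' @export
sign_stability <- function(table, response = "sex_allocation") {
  full <- fit_lmm(table, response)
  cf_full <- coef(full)
  terms <- setdiff(names(cf_full), "intercept")
  rows <- lapply(terms, function(tm) {
    simple <- fit_lmm(table, response, fixed = tm)
    est_s <- coef(simple)[tm]
    data.frame(term = tm, estimate_simple = unname(est_s),
               estimate_multiple = unname(cf_full[tm]),
               stable = sign(est_s) == sign(cf_full[tm]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
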