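# noiseless fixture: responses are exact linear functions of the predictors
zero_noise_table <- function(mode, seed) {
  pop <- generate_population(zero_noise_config(mode, seed = seed))
  stopifnot(pop$truth$n_truncated == 0L, pop$truth$n_clipped == 0L)
  list(table = build_analysis_table(pop$records, pop$truth$mgs),
       truth = pop$truth)
}

test_that("noiseless organ data returns the generating coefficients exactly", {
  fx <- zero_noise_table("organ_level", seed = 102)
  for (resp in c("testis_sv", "penis", "ovary")) {
    fit <- fit_lmm(fx$table, resp)
    beta <- fx$truth$coefficients[[resp]]
    expect_equal(unname(coef(fit)),
                 unname(beta[c("intercept", "mgs_m", "mgs_f",
                               "body_weight")]),
                 tolerance = 1e-6)
    expect_lt(fit$shell_var, 1e-8)  # boundary estimate of the zero variance
  }
})

test_that("noiseless allocation data returns the generating coefficients exactly", {
  fx <- zero_noise_table("allocation_level", seed = 101)
  fit <- fit_lmm(fx$table, "sex_allocation")
  beta <- fx$truth$coefficients$sex_allocation
  expect_equal(unname(coef(fit)),
               unname(beta[c("intercept", "mgs_m", "mgs_f", "body_weight")]),
               tolerance = 1e-6)
})

test_that("fit_lmm reports SEs, p-values, variance components, and criterion", {
  cfg <- generator_config(n_shells = 25, mode = "allocation_level",
                          seed = 61)
  pop <- suppressWarnings(generate_population(cfg))
  tab <- build_analysis_table(pop$records, pop$truth$mgs)
  fit <- fit_lmm(tab, "sex_allocation")
  expect_s3_class(fit, "lmm_fit")
  expect_identical(fit$coefficients$term,
                   c("intercept", "mgs_m", "mgs_f", "body_weight"))
  expect_true(all(fit$coefficients$se > 0))
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
  expect_gte(fit$shell_var, 0)
  expect_gt(fit$residual_var, 0)
  expect_identical(fit$criterion, "REML")
  expect_identical(fit$n_obs, nrow(tab))

  ml <- fit_lmm(tab, "sex_allocation", reml = FALSE)
  expect_identical(ml$criterion, "ML")

  one_shell <- tab[tab$shell_id == tab$shell_id[1], ]
  expect_error(fit_lmm(one_shell, "sex_allocation"), "single shell")

  collinear <- tab
  collinear$body_weight_mg <- 2 * collinear$mgs_m
  expect_error(fit_lmm(collinear, "sex_allocation"), "collinear")
})

test_that("VIF follows its closed form 1/(1 - R^2)", {
  # exactly orthogonal predictors
  d <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(d, c("a", "b"))), c(1, 1))

  # two predictors with sample correlation exactly 0.75
  set.seed(71)
  z1 <- scale(rnorm(200))[, 1]
  z2 <- residuals(lm(rnorm(200) ~ z1))
  z2 <- z2 / sd(z2)
  d2 <- data.frame(x = z1, y = 0.75 * z1 + sqrt(1 - 0.75^2) * z2)
  expect_equal(unname(cor(d2$x, d2$y)), 0.75, tolerance = 1e-10)
  expect_equal(unname(vif(d2, c("x", "y"))),
               rep(1 / (1 - 0.5625), 2), tolerance = 1e-8)

  # degenerate cases
  d2$dup <- d2$x
  expect_identical(unname(vif(d2, c("x", "dup"))), c(Inf, Inf))
  d2$const <- 1
  expect_error(vif(d2, c("x", "const")), "zero variance")
})

test_that("VIF is never below 1 and matches car::vif on a fitted model", {
  skip_if_not_installed("car")
  set.seed(72)
  pop <- suppressWarnings(
    generate_population(generator_config(n_shells = 20, seed = 72))
  )
  tab <- build_analysis_table(pop$records, pop$truth$mgs)
  ours <- vif(tab)
  expect_true(all(ours >= 1))
  lm_fit <- lm(sex_allocation ~ mgs_m + mgs_f + body_weight_mg,
               data = as.data.frame(tab))
  theirs <- car::vif(lm_fit)
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-8)
})

test_that("Pearson correlation handles the textbook cases", {
  x <- c(0.4, 1.1, 2.5, 3.0, 4.2)
  out <- pearson_r(x, 2 * x + 1)
  expect_equal(out$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(c(0, 1, 2), c(0, 1, 0))$r, 0)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  # two-sided t-based p agrees with the closed form
  set.seed(73)
  a <- rnorm(30); b <- rnorm(30)
  out <- pearson_r(a, b)
  tt <- out$r * sqrt(28 / (1 - out$r^2))
  expect_equal(out$p, 2 * pt(-abs(tt), 28))
})

test_that("the likelihood-ratio closed form reproduces the reported statistic", {
  out <- lrt_from_loglik(-10.0, -11.9345, 1)
  expect_equal(out$chi_square, 3.869)
  expect_equal(round(out$p, 3), 0.049)

  same <- lrt_from_loglik(-5, -5, 1)
  expect_identical(same$chi_square, 0)
  expect_identical(same$p, 1)
  expect_warning(neg <- lrt_from_loglik(-6, -5, 1), "floored")
  expect_identical(neg$chi_square, 0)
})

test_that("nested mixed models are compared by ML refits", {
  pop <- suppressWarnings(
    generate_population(generator_config(n_shells = 25, seed = 74,
                                         mode = "allocation_level"))
  )
  tab <- build_analysis_table(pop$records, pop$truth$mgs)
  full <- fit_lmm(tab, "sex_allocation")
  reduced <- fit_lmm(tab, "sex_allocation", fixed = c("mgs_m", "body_weight"))
  out <- likelihood_ratio_test(full, reduced)
  expect_identical(out$df, 1L)
  expect_gte(out$chi_square, 0)
  expect_equal(out$chi_square,
               2 * (out$logLik_full - out$logLik_reduced))
  # lme4's own anova on the ML refits is the independent check
  ref <- anova(lme4::refitML(full$model), lme4::refitML(reduced$model))
  expect_equal(out$chi_square, ref$Chisq[2], tolerance = 1e-6)
  expect_equal(out$p, ref$`Pr(>Chisq)`[2], tolerance = 1e-6)

  expect_error(likelihood_ratio_test(reduced, full), "strict subset")
  other <- fit_lmm(tab, "ovary", fixed = c("mgs_m", "body_weight"))
  expect_error(likelihood_ratio_test(full, other), "same response")
})

test_that("marginal lines are partial predictions at held covariate values", {
  cs <- default_coefficient_sets()$sex_allocation
  l_m <- marginal_line(cs, "mgs_m", c(mgs_f = 3, body_weight = 1014.18))
  expect_equal(l_m$slope, 0.0089)
  expect_equal(round(l_m$intercept, 4), 0.0632)
  l_f <- marginal_line(cs, "mgs_f", c(mgs_m = 3, body_weight = 1014.18))
  expect_equal(l_f$slope, -0.0083)
  expect_equal(round(l_f$intercept, 4), 0.1148)

  at_zero <- marginal_line(cs, "mgs_m", c(mgs_f = 0, body_weight = 0))
  expect_equal(at_zero$intercept, cs[["intercept"]])
  expect_error(marginal_line(cs, "mgs_m", c(mgs_f = 3)), "held values")
  expect_error(marginal_line(cs, "not_a_term", c(mgs_f = 3)),
               "not a predictor")

  # works identically on a fitted model
  fx <- zero_noise_table("allocation_level", seed = 101)
  fit <- fit_lmm(fx$table, "sex_allocation")
  l_fit <- marginal_line(fit, "mgs_m", c(mgs_f = 3, body_weight = 1014.18))
  expect_equal(l_fit$slope, 0.0089, tolerance = 1e-6)
  expect_equal(l_fit$intercept, 0.06322, tolerance = 1e-4)
})

test_that("sign stability compares simple against multiple regressions", {
  pop <- suppressWarnings(
    generate_population(generator_config(n_shells = 25, seed = 75,
                                         mode = "allocation_level"))
  )
  tab <- build_analysis_table(pop$records, pop$truth$mgs)
  out <- sign_stability(tab, "sex_allocation")
  expect_identical(out$term, c("mgs_m", "mgs_f", "body_weight"))
  expect_type(out$stable, "logical")
})
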