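test_that("design matrices carry the nested covariate encodings", {
  cfg <- cohort_config(n_participants = 40, seed = 8)
  analysis <- make_analysis(cfg)
  d1 <- build_design(analysis, model = 1)
  expect_identical(colnames(d1$X), c("(Intercept)", "z1", "z2"))
  d5 <- build_design(analysis, model = 5)
  expect_equal(ncol(d5$X), 14L)  # intercept + 2 ilr + 11 covariates
  expect_true(all(c("bmi_under", "bmi_over", "med_diabetes") %in%
                    colnames(d5$X)))
  # ratio outcomes drop ICV from the covariate list
  analysis$right_hipp_ratio <- analysis$right_hipp_mm3 / analysis$icv_mm3
  d5r <- build_design(analysis, model = 5, outcome = "right_hipp_ratio")
  expect_false("icv_mm3" %in% colnames(d5r$X))
  expect_equal(ncol(d5r$X), 13L)
  # listwise exclusion of incomplete cases is counted
  analysis$age_years[3] <- NA
  d2 <- build_design(analysis, model = 2)
  expect_equal(d2$n_dropped, 1L)
  expect_equal(nrow(d2$X), 39L)
})

test_that("fit_ols matches the normal-equations oracle and lm", {
  set.seed(12)
  n <- 60
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = runif(n),
             x3 = rbinom(n, 1, 0.4))
  y <- drop(X %*% c(2, -1.5, 3, 0.5)) + rnorm(n, 0, 0.7)
  fit <- fit_ols(X, y)
  # brute-force normal equations
  beta_ne <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients, drop(beta_ne), tolerance = 1e-8,
               ignore_attr = TRUE)
  # lm as the independent reference for inference
  ref <- lm(y ~ x1 + x2 + x3, data = as.data.frame(X[, -1]))
  s <- summary(ref)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(s$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(fit$p), unname(s$coefficients[, 4]),
               tolerance = 1e-10)
  ci <- confint(ref)
  expect_equal(unname(fit$ci_lower), unname(ci[, 1]), tolerance = 1e-10)
  expect_equal(unname(fit$ci_upper), unname(ci[, 2]), tolerance = 1e-10)
  # noiseless outcome: exact interpolation
  fit0 <- fit_ols(X, drop(X %*% c(1, 2, 3, 4)))
  expect_lt(max(abs(fit0$residuals)), 1e-10)
  expect_equal(unname(fit0$coefficients), c(1, 2, 3, 4), tolerance = 1e-10)
  # duplicated column: explicit rank-deficiency error naming the culprit
  expect_error(fit_ols(cbind(X, x1_copy = X[, "x1"]), y),
               "collinear.*x1_copy")
})

test_that("constant covariates surface as rank deficiency", {
  cfg <- cohort_config(n_participants = 30, seed = 13, prop_male = 1)
  analysis <- make_analysis(cfg)
  expect_error(fit_pivot_models(analysis, model = 2), "collinear")
})

test_that("pivot refits are one model: invariant fits, zero-sum betas", {
  cfg <- cohort_config(n_participants = 120, seed = 17)
  analysis <- make_analysis(cfg)
  for (m in c(1, 3, 5)) {
    pm <- fit_pivot_models(analysis, model = m)
    f <- lapply(pm$fits, function(x) x$fit$fitted)
    expect_lt(max(abs(f$sb - f$mvpa)), 1e-8)
    expect_lt(max(abs(f$lpa - f$mvpa)), 1e-8)
    betas <- vapply(pm$fits, `[[`, numeric(1), "beta_z1")
    expect_lt(abs(sum(betas)), 1e-8)
    # log-contrast vector sums to zero and reproduces each pivot beta
    a <- unclass(pm$log_contrast)
    expect_lt(abs(sum(a)), 1e-8)
    expect_equal(sqrt(3 / 2) * a[["mvpa"]], betas[["mvpa"]],
                 tolerance = 1e-8)
  }
})

test_that("relabelling two behaviours permutes the reported betas", {
  cfg <- cohort_config(n_participants = 90, seed = 23)
  analysis <- make_analysis(cfg)
  pm <- fit_pivot_models(analysis, model = 2)
  swapped <- analysis
  swapped$sb <- analysis$lpa
  swapped$lpa <- analysis$sb
  pm_s <- fit_pivot_models(swapped, model = 2)
  expect_equal(pm_s$fits$sb$beta_z1, pm$fits$lpa$beta_z1,
               tolerance = 1e-10)
  expect_equal(pm_s$fits$lpa$beta_z1, pm$fits$sb$beta_z1,
               tolerance = 1e-10)
  expect_equal(pm_s$fits$mvpa$beta_z1, pm$fits$mvpa$beta_z1,
               tolerance = 1e-10)
})

test_that("the model suite covers all outcomes and scales ratio betas", {
  cfg <- cohort_config(n_participants = 100, seed = 29)
  analysis <- make_analysis(cfg)
  suite <- run_model_suite(analysis)
  # 5 models x 3 pivots x (2 volume + 2 ratio outcomes)
  expect_equal(nrow(suite), 60L)
  expect_equal(sum(suite$outcome_type == "volume"), 30L)
  expect_equal(sum(suite$outcome_type == "ratio"), 30L)
  # constant ICV: ratio betas are the volume betas divided by ICV
  const <- analysis
  const$icv_mm3 <- 1.4e6
  s1 <- run_model_suite(const, models = 1)
  vol <- s1[s1$outcome_type == "volume" & s1$side == "right", ]
  rat <- s1[s1$outcome_type == "ratio" & s1$side == "right", ]
  expect_equal(rat$beta, vol$beta / 1.4e6, tolerance = 1e-10)
  # the formatted table writes one row per outcome x model
  path <- tempfile(fileext = ".tsv")
  write_coefficient_table(suite, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 20L)
  expect_true(all(c("mvpa_beta_ci", "mvpa_p") %in% names(tab)))
})

test_that("a confounded generator separates crude from adjusted betas", {
  cfg <- cohort_config(n_participants = 400, seed = 37,
                       age_confounding = 0.4)
  analysis <- make_analysis(cfg)
  crude <- fit_pivot_models(analysis, 1)$fits$mvpa$beta_z1
  adjusted <- fit_pivot_models(analysis, 5)$fits$mvpa$beta_z1
  # age lowers volume and raises z1 here, so the crude MVPA beta is pulled
  # below the adjusted one
  expect_lt(crude, adjusted)
})
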