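# Compositional multiple linear regression: pivot ilr coordinates plus
# nested covariate sets, refit with each behaviour pivot-first so that one
# interpretable z1 coefficient is reported per behaviour, plus the
# basis-free log-contrast representation used for reallocation prediction.

#' Covariate sets of the nested adjustment models
#'
#' Model 1 is unadjusted; model 2 adds sex, age and intracranial volume;
#' model 3 adds education; model 4 adds BMI category, smoking and heavy
#' alcohol use; model 5 adds the three medication flags. Ratio outcomes
#' (volume / ICV) drop ICV from the covariate list.
#'
#' @param model Integer 1-5.
#' @param ratio_outcome If `TRUE`, exclude `icv_mm3`.
#' @return Character vector of design-coded covariate names.
#' @export
model_covariates <- function(model, ratio_outcome = FALSE) {
  if (!model %in% 1:5) stop("model must be 1, 2, 3, 4 or 5")
  sets <- list(
    character(0),
    c("sex_male", "age_years", "icv_mm3"),
    "education_13y",
    c("bmi_under", "bmi_over", "smoker", "alcohol_heavy"),
    c("med_hypertension", "med_dyslipidemia", "med_diabetes"))
  covs <- unlist(sets[seq_len(model)])
  if (ratio_outcome) covs <- setdiff(covs, "icv_mm3")
  covs
}

# The three pivot orderings used for reporting: each behaviour first, the
# remaining two completing the basis cyclically. The z1 coefficient is
# invariant to the order of the trailing pair.
pivot_orders <- function() {
  list(sb = c("sb", "lpa", "mvpa"),
       lpa = c("lpa", "mvpa", "sb"),
       mvpa = c("mvpa", "sb", "lpa"))
}

#' Assemble the design matrix and outcome vector for one model
#'
#' @param data Analysis table with composition columns `sb`, `lpa`, `mvpa`
#'   (strictly positive, closed), the outcome column, and either `bmi_cat`
#'   or the `bmi_under`/`bmi_over` indicators plus the other design-coded
#'   covariates required by the model.
#' @param model Adjustment level 1-5 (see [model_covariates()]).
#' @param pivot_order Pivot ordering for the ilr columns.
#' @param outcome Outcome column name; a name containing `"ratio"` selects
#'   the ICV-free covariate set.
#' @return A list: `X` (with intercept, `z1`, `z2`, covariates), `y`,
#'   `n_dropped` (incomplete rows excluded listwise), `pivot_order`.
#' @export
build_design <- function(data, model, pivot_order = c("mvpa", "sb", "lpa"),
                         outcome = "right_hipp_mm3") {
  ratio <- grepl("ratio", outcome)
  covs <- model_covariates(model, ratio_outcome = ratio)
  if (!outcome %in% names(data)) stop("missing outcome column ", outcome)
  d <- data
  if (any(c("bmi_under", "bmi_over") %in% covs) && !"bmi_under" %in% names(d)) {
    if (!"bmi_cat" %in% names(d)) stop("need bmi_cat or bmi indicators")
    d$bmi_under <- as.integer(d$bmi_cat == "under")
    d$bmi_over <- as.integer(d$bmi_cat == "over")
  }
  missing_cols <- setdiff(covs, names(d))
  if (length(missing_cols))
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "))
  used <- c(behaviour_parts(), covs, outcome)
  cc <- stats::complete.cases(d[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  z <- ilr_pivot(d[, behaviour_parts()], pivot_order)
  X <- cbind(`(Intercept)` = 1, z)
  if (length(covs))
    X <- cbind(X, as.matrix(d[, covs, drop = FALSE]))
  list(X = X, y = d[[outcome]], n_dropped = n_dropped,
       pivot_order = pivot_order)
}

#' Ordinary least squares with classical t inference
#'
#' QR-based least squares with the unbiased residual variance, two-sided
#' t-based p-values and 95% t-intervals. Rank deficiency is an error that
#' names the offending columns.
#'
#' @param X Design matrix (including intercept).
#' @param y Outcome vector.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A list of class `ols_fit`: `coefficients`, `se`, `t`, `p`,
#'   `ci_lower`, `ci_upper`, `sigma`, `df_residual`, `fitted`, `residuals`,
#'   `vcov`, `n`.
#' @export
fit_ols <- function(X, y, conf_level = 0.95) {
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (n <= p) stop("need more observations (", n, ") than columns (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)
  Rinv <- backsolve(R, diag(p))
  xtx_inv <- tcrossprod(Rinv)[order(qx$pivot), order(qx$pivot), drop = FALSE]
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(coefficients = coef, se = se, t = tval, p = pval,
                 ci_lower = coef - crit * se, ci_upper = coef + crit * se,
                 sigma = sqrt(sigma2), df_residual = df, fitted = fitted,
                 residuals = res, vcov = vcov, n = n),
            class = "ols_fit")
}

#' Fit one model with every behaviour pivot-first
#'
#' Refits the same compositional regression three times, once per pivot
#' behaviour, so each behaviour gets an interpretable `z1` coefficient (its
#' share relative to the geometric mean of the other two). The three fits
#' are the same model in rotated bases: fitted values are verified to
#' agree, and the three `z1` coefficients sum to zero by construction.
#'
#' @inheritParams build_design
#' @return A list of class `pivot_models`: `fits` (per behaviour: pivot
#'   order, `beta_z1`, CI, p, the full `ols_fit`), `log_contrast` (the
#'   basis-free [log_contrast()] vector of the composition effect), `n`,
#'   `n_dropped`, `model`, `outcome`.
#' @export
fit_pivot_models <- function(data, model, outcome = "right_hipp_mm3") {
  fits <- list()
  fitted_ref <- NULL
  n_dropped <- NA_integer_
  for (behaviour in names(pivot_orders())) {
    ord <- pivot_orders()[[behaviour]]
    des <- build_design(data, model, ord, outcome)
    fit <- fit_ols(des$X, des$y)
    if (is.null(fitted_ref)) {
      fitted_ref <- fit$fitted
      n_dropped <- des$n_dropped
    } else if (max(abs(fit$fitted - fitted_ref)) > 1e-6 * max(1, stats::sd(des$y)))
      stop("pivot orderings disagree on fitted values; design is unstable")
    fits[[behaviour]] <- list(
      behaviour = behaviour, pivot_order = ord,
      beta_z1 = unname(fit$coefficients["z1"]),
      ci_lower = unname(fit$ci_lower["z1"]),
      ci_upper = unname(fit$ci_upper["z1"]),
      p = unname(fit$p["z1"]), fit = fit)
  }
  mv <- fits$mvpa$fit
  lc <- log_contrast_from_pivot(
    beta_z1 = mv$coefficients[["z1"]], beta_z2 = mv$coefficients[["z2"]],
    pivot_order = pivot_orders()$mvpa)
  structure(list(fits = fits, log_contrast = lc, n = mv$n,
                 n_dropped = n_dropped, model = model, outcome = outcome),
            class = "pivot_models")
}

#' @export
print.pivot_models <- function(x, ...) {
  cat(sprintf("Compositional regression: %s, model %d (n = %d)\n",
              x$outcome, x$model, x$n))
  for (f in x$fits)
    cat(sprintf("  %-4s z1 beta %8.1f  (%.1f to %.1f)  p = %.3f\n",
                toupper(f$behaviour), f$beta_z1, f$ci_lower, f$ci_upper,
                f$p))
  invisible(x)
}

#' Run the full suite of nested models and outcomes
#'
#' Fits models 1-5 for the right and left volumes and, optionally, for the
#' volume/ICV ratio outcomes (betas on the ratio scale; multiply by 1e6 for
#' display). Ratio outcomes are derived on the fly from the volume and
#' `icv_mm3` columns.
#'
#' @param data Analysis table (see [build_design()]) including `icv_mm3`
#'   when `include_ratio = TRUE`.
#' @param models Integer vector of adjustment levels (default 1:5).
#' @param sides Outcome sides, subset of `c("right", "left")`.
#' @param include_ratio Also fit the volume/ICV sensitivity outcomes.
#' @return A data.frame with one row per (outcome type, side, model,
#'   pivot): `outcome_type`, `side`, `model`, `pivot`, `beta`, `ci_lower`,
#'   `ci_upper`, `p`, `n`.
#' @export
run_model_suite <- function(data, models = 1:5, sides = c("right", "left"),
                            include_ratio = TRUE) {
  d <- data
  specs <- list()
  for (s in sides)
    specs[[length(specs) + 1L]] <-
      list(type = "volume", side = s, col = paste0(s, "_hipp_mm3"))
  if (include_ratio) {
    if (!"icv_mm3" %in% names(d)) stop("icv_mm3 required for ratio outcomes")
    for (s in sides) {
      col <- paste0(s, "_hipp_ratio")
      d[[col]] <- d[[paste0(s, "_hipp_mm3")]] / d$icv_mm3
      specs[[length(specs) + 1L]] <- list(type = "ratio", side = s, col = col)
    }
  }
  rows <- list()
  for (sp in specs) for (m in models) {
    pm <- fit_pivot_models(d, m, sp$col)
    for (f in pm$fits)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome_type = sp$type, side = sp$side, model = m,
        pivot = f$behaviour, beta = f$beta_z1, ci_lower = f$ci_lower,
        ci_upper = f$ci_upper, p = f$p, n = pm$n)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a model-suite table in publication layout
#'
#' One row per (outcome, model); per behaviour a "beta (low-high)" column
#' and a p column. Volume betas are in mm^3 to 1 decimal; ratio betas are
#' scaled to 1e-6 units.
#'
#' @param suite Output of [run_model_suite()].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(suite, path) {
  fmt <- function(b, lo, hi, scale)
    sprintf("%.1f (%.1f to %.1f)", b * scale, lo * scale, hi * scale)
  keys <- unique(suite[, c("outcome_type", "side", "model")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- suite[suite$outcome_type == k$outcome_type &
                   suite$side == k$side & suite$model == k$model, ]
    scale <- if (k$outcome_type == "ratio") 1e6 else 1
    out <- data.frame(outcome = paste(k$side, "hippocampal",
                                      if (k$outcome_type == "ratio")
                                        "volume/ICV (beta x 1e-6)"
                                      else "volume (mm^3)"),
                      model = k$model, n = sub$n[1L])
    for (b in behaviour_parts()) {
      r <- sub[sub$pivot == b, ]
      out[[paste0(b, "_beta_ci")]] <- fmt(r$beta, r$ci_lower, r$ci_upper,
                                          scale)
      out[[paste0(b, "_p")]] <- sprintf("%.3f", r$p)
    }
    out
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
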