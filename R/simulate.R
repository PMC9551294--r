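# Synthetic cohort generator. Emulates an older-adult accelerometer + MRI
# study: covariate marginals, a logistic-normal time-use composition whose
# log-ratio dispersion matches the published variation matrix, hippocampal
# volumes generated from a compositional linear model with known ground
# truth, and epoch-level MET streams whose screened minutes recover the
# intended daily minutes exactly.

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the marginal structure of the study population this
#' package's pipeline is designed for: 485 community-dwelling adults aged
#' 65-84 (47% male), mean wear time 887.5 (SD 109.4) min/day over 7 days, a
#' compositional centre of 50.5% SB / 44.9% LPA / 4.6% MVPA with pairwise
#' log-ratio variances (SB-LPA, SB-MVPA, LPA-MVPA) = (0.26, 1.19, 0.76),
#' and right/left hippocampal volumes of mean 3687.7/3522.1 mm^3 (SD
#' 420.3/391.1) generated from MVPA-first pivot coordinates with true
#' `beta_z1` 57.1 (right) and 17.5 (left) mm^3 per ilr unit.
#'
#' Derived quantities: `ilr_mean` is the pivot image of `mean_composition`;
#' `ilr_cov` is obtained by mapping the target variation matrix to the clr
#' covariance (`Sigma = -G T G / 2`, `G` the centring projector) and
#' rotating it into the pivot basis; `outcome_intercept` is set so the
#' expected outcome equals `outcome_mean`; `noise_sd` absorbs the variance
#' the linear predictor does not explain, so the marginal outcome SD matches
#' `outcome_sd`.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; streams for covariates, outcomes and epochs
#'   use `seed`, `seed + 1`, `seed + 2`.
#' @param prop_male,prop_education,prop_bmi_under,prop_bmi_over,prop_smoker,prop_alcohol
#'   Marginal probabilities of the binary/categorical covariates.
#' @param prop_med Named probabilities for the hypertension, dyslipidemia
#'   and diabetes medication flags.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated to
#'   `age_range`.
#' @param icv_mean,icv_sd Intracranial volume (mm^3).
#' @param mean_composition Compositional centre (closed, SB/LPA/MVPA).
#' @param variation Target pairwise log-ratio variances, named
#'   `sb_lpa`, `sb_mvpa`, `lpa_mvpa`.
#' @param ilr_mean,ilr_cov Optional overrides of the derived pivot-scale
#'   location/covariance (MVPA-first ordering). `ilr_cov` must be symmetric
#'   positive semi-definite.
#' @param beta_z1,beta_z2 True pivot-coordinate effects (mm^3 per ilr
#'   unit), named `right`/`left`; `beta_z2` defaults are the orthogonal
#'   contrasts implied by the same fitted models as the `beta_z1` defaults.
#' @param covariate_effects Named mm^3 effects of the design-coded
#'   covariates.
#' @param outcome_mean,outcome_sd Target marginal outcome moments (mm^3).
#' @param outcome_intercept,noise_sd Optional overrides of the derived
#'   intercept and residual SD (named `right`/`left`).
#' @param days_per_participant Accelerometer days per participant.
#' @param wear_mean,wear_sd Between-participant distribution of habitual
#'   daily wear time (minutes), clipped to a feasible range.
#' @param wear_daily_sd Within-participant day-to-day SD of wear time
#'   (minutes).
#' @param age_confounding Confounding knob: shift of `z1` (ilr units) per
#'   SD of age; 0 (default) makes covariates independent of the
#'   composition.
#' @param start_date First accelerometer day.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 485L,
                          seed = 1L,
                          prop_male = 0.47,
                          age_mean = 73.3, age_sd = 5.5,
                          age_range = c(65, 84),
                          icv_mean = 1432369, icv_sd = 152092,
                          prop_education = 0.196,
                          prop_bmi_under = 0.082, prop_bmi_over = 0.177,
                          prop_smoker = 0.085, prop_alcohol = 0.045,
                          prop_med = c(hypertension = 0.456,
                                       dyslipidemia = 0.344,
                                       diabetes = 0.095),
                          mean_composition = c(sb = 0.505, lpa = 0.449,
                                               mvpa = 0.046),
                          variation = c(sb_lpa = 0.26, sb_mvpa = 1.19,
                                        lpa_mvpa = 0.76),
                          ilr_mean = NULL, ilr_cov = NULL,
                          beta_z1 = c(right = 57.1, left = 17.5),
                          beta_z2 = c(right = -6.7, left = -50.4),
                          covariate_effects = c(
                            sex_male = 40, age_years = -20, icv_mm3 = 0.0015,
                            education_13y = 20, bmi_under = -40,
                            bmi_over = -20, smoker = -50, alcohol_heavy = -30,
                            med_hypertension = -20, med_dyslipidemia = -10,
                            med_diabetes = -40),
                          outcome_mean = c(right = 3687.7, left = 3522.1),
                          outcome_sd = c(right = 420.3, left = 391.1),
                          outcome_intercept = NULL, noise_sd = NULL,
                          days_per_participant = 7L,
                          wear_mean = 887.5, wear_sd = 109.4,
                          wear_daily_sd = 60,
                          age_confounding = 0,
                          start_date = as.Date("2017-10-02")) {
  if (n_participants < 1L) stop("n_participants must be >= 1")
  probs <- c(prop_male, prop_education, prop_bmi_under, prop_bmi_over,
             prop_smoker, prop_alcohol, prop_med,
             prop_bmi_under + prop_bmi_over)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean_composition <- close_composition(mean_composition)[1L, ]

  if (is.null(ilr_mean))
    ilr_mean <- drop(ilr_pivot(mean_composition))
  if (is.null(ilr_cov))
    ilr_cov <- ilr_cov_from_variation(variation)
  if (!isTRUE(all.equal(ilr_cov, t(ilr_cov), tolerance = 1e-10)))
    stop("ilr_cov must be symmetric")
  ev <- eigen(ilr_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("ilr_cov must be positive semi-definite")

  meta <- covariate_moments(prop_male, age_mean, age_sd, icv_mean, icv_sd,
                            prop_education, prop_bmi_under, prop_bmi_over,
                            prop_smoker, prop_alcohol, prop_med)
  eff <- covariate_effects[meta$names]
  if (anyNA(eff)) stop("covariate_effects must name: ",
                       paste(meta$names, collapse = ", "))
  cov_mean_contrib <- sum(eff * meta$means)
  cov_var <- sum(eff^2 * meta$vars) -
    2 * eff["bmi_under"] * eff["bmi_over"] * prop_bmi_under * prop_bmi_over

  sides <- c("right", "left")
  b <- rbind(z1 = beta_z1[sides], z2 = beta_z2[sides])
  z_mean_contrib <- drop(crossprod(b, ilr_mean))
  z_var <- vapply(sides, function(s) drop(t(b[, s]) %*% ilr_cov %*% b[, s]),
                  numeric(1))
  if (is.null(outcome_intercept))
    outcome_intercept <- outcome_mean[sides] - z_mean_contrib -
      cov_mean_contrib
  if (is.null(noise_sd)) {
    resid_var <- outcome_sd[sides]^2 - z_var - cov_var
    if (any(resid_var < 0))
      warning("explained variance exceeds target outcome variance; ",
              "noise_sd floored at 1")
    noise_sd <- sqrt(pmax(resid_var, 1))
  }

  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    prop_male = prop_male, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, icv_mean = icv_mean, icv_sd = icv_sd,
    prop_education = prop_education, prop_bmi_under = prop_bmi_under,
    prop_bmi_over = prop_bmi_over, prop_smoker = prop_smoker,
    prop_alcohol = prop_alcohol, prop_med = prop_med,
    mean_composition = mean_composition, variation = variation,
    ilr_mean = ilr_mean, ilr_cov = ilr_cov,
    beta_z1 = beta_z1[sides], beta_z2 = beta_z2[sides],
    covariate_effects = eff,
    outcome_mean = outcome_mean[sides], outcome_sd = outcome_sd[sides],
    outcome_intercept = outcome_intercept, noise_sd = noise_sd,
    days_per_participant = as.integer(days_per_participant),
    wear_mean = wear_mean, wear_sd = wear_sd,
    wear_daily_sd = wear_daily_sd,
    age_confounding = age_confounding, start_date = start_date),
    class = "cohort_config")
}

# Map target pairwise log-ratio variances to the pivot-basis covariance:
# the clr covariance is Sigma = -(1/2) G T G with G the centring projector,
# then rotate into the MVPA-first pivot basis.
ilr_cov_from_variation <- function(variation) {
  need <- c("sb_lpa", "sb_mvpa", "lpa_mvpa")
  if (!all(need %in% names(variation)))
    stop("variation must name ", paste(need, collapse = ", "))
  Tm <- matrix(0, 3L, 3L, dimnames = list(behaviour_parts(), behaviour_parts()))
  Tm["sb", "lpa"] <- Tm["lpa", "sb"] <- variation[["sb_lpa"]]
  Tm["sb", "mvpa"] <- Tm["mvpa", "sb"] <- variation[["sb_mvpa"]]
  Tm["lpa", "mvpa"] <- Tm["mvpa", "lpa"] <- variation[["lpa_mvpa"]]
  G <- diag(3L) - 1 / 3
  sigma_clr <- -0.5 * G %*% Tm %*% G
  V <- pivot_basis()
  structure(t(V) %*% sigma_clr %*% V,
            dimnames = list(c("z1", "z2"), c("z1", "z2")))
}

# Means and variances of the design-coded covariates implied by a config;
# the bmi_under/bmi_over cross-covariance is handled by the caller.
covariate_moments <- function(p_male, age_mean, age_sd, icv_mean, icv_sd,
                              p_edu, p_bu, p_bo, p_smoke, p_alc, p_med) {
  nm <- c("sex_male", "age_years", "icv_mm3", "education_13y", "bmi_under",
          "bmi_over", "smoker", "alcohol_heavy", "med_hypertension",
          "med_dyslipidemia", "med_diabetes")
  p <- c(p_male, NA, NA, p_edu, p_bu, p_bo, p_smoke, p_alc,
         p_med[["hypertension"]], p_med[["dyslipidemia"]],
         p_med[["diabetes"]])
  means <- ifelse(is.na(p), c(NA, age_mean, icv_mean, rep(NA, 8)), p)
  vars <- ifelse(is.na(p), c(NA, age_sd^2, icv_sd^2, rep(NA, 8)),
                 p * (1 - p))
  list(names = nm, means = stats::setNames(means, nm),
       vars = stats::setNames(vars, nm))
}

#' Generate a synthetic cohort: covariates and ground-truth compositions
#'
#' Covariates are drawn from the configured marginals; time-use
#' compositions are logistic-normal, sampled on the MVPA-first pivot scale
#' and mapped back through [ilr_inverse()]. With `age_confounding != 0`,
#' standardised age shifts the `z1` location, inducing confounding for
#' stress tests.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `covariates` (one row per
#'   participant: id, design-coded covariates, `bmi_cat`, ICV) and `truth`
#'   (id, true `z1`, `z2`, and the true closed composition).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  id <- sprintf("P%04d", seq_len(n))

  sex_male <- stats::rbinom(n, 1L, config$prop_male)
  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                         config$age_range[1L]), config$age_range[2L]))
  education <- stats::rbinom(n, 1L, config$prop_education)
  bmi_cat <- sample(c("under", "normal", "over"), n, replace = TRUE,
                    prob = c(config$prop_bmi_under,
                             1 - config$prop_bmi_under - config$prop_bmi_over,
                             config$prop_bmi_over))
  smoker <- stats::rbinom(n, 1L, config$prop_smoker)
  alcohol <- stats::rbinom(n, 1L, config$prop_alcohol)
  med_ht <- stats::rbinom(n, 1L, config$prop_med[["hypertension"]])
  med_dl <- stats::rbinom(n, 1L, config$prop_med[["dyslipidemia"]])
  med_db <- stats::rbinom(n, 1L, config$prop_med[["diabetes"]])
  icv <- round(stats::rnorm(n, config$icv_mean, config$icv_sd))

  es <- eigen(config$ilr_cov, symmetric = TRUE)
  L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), 2L)
  z <- matrix(stats::rnorm(2L * n), n, 2L) %*% t(L)
  z <- sweep(z, 2L, config$ilr_mean, "+")
  z[, 1L] <- z[, 1L] +
    config$age_confounding * (age - config$age_mean) / config$age_sd
  colnames(z) <- c("z1", "z2")
  comp <- ilr_inverse(z)

  covariates <- data.frame(
    participant_id = id, sex_male = sex_male, age_years = age,
    education_13y = education, bmi_cat = factor(bmi_cat,
      levels = c("normal", "under", "over")),
    smoker = smoker, alcohol_heavy = alcohol,
    med_hypertension = med_ht, med_dyslipidemia = med_dl,
    med_diabetes = med_db, icv_mm3 = icv)
  truth <- data.frame(participant_id = id, z1 = z[, "z1"], z2 = z[, "z2"],
                      sb = comp[, "sb"], lpa = comp[, "lpa"],
                      mvpa = comp[, "mvpa"])
  structure(list(covariates = covariates, truth = truth, config = config),
            class = "cohort")
}

# Design-coded covariate matrix in the order of covariate_effects.
covariate_design <- function(covariates) {
  cbind(sex_male = covariates$sex_male,
        age_years = covariates$age_years,
        icv_mm3 = covariates$icv_mm3,
        education_13y = covariates$education_13y,
        bmi_under = as.integer(covariates$bmi_cat == "under"),
        bmi_over = as.integer(covariates$bmi_cat == "over"),
        smoker = covariates$smoker,
        alcohol_heavy = covariates$alcohol_heavy,
        med_hypertension = covariates$med_hypertension,
        med_dyslipidemia = covariates$med_dyslipidemia,
        med_diabetes = covariates$med_diabetes)
}

#' Generate hippocampal-volume outcomes from the ground truth
#'
#' Right and left volumes are
#' `intercept + beta_z1 * z1 + beta_z2 * z2 + covariate effects + noise`,
#' with `z` the true MVPA-first pivot coordinates.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config Optional config override (defaults to the cohort's own).
#' @return A data.frame: `participant_id`, `right_hipp_mm3`,
#'   `left_hipp_mm3`, and the noiseless linear predictors
#'   `linpred_right_mm3`, `linpred_left_mm3`.
#' @export
generate_outcomes <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "cohort"))
  if (!identical(cohort$covariates$participant_id,
                 cohort$truth$participant_id))
    stop("covariates and ground truth are not aligned by participant id")
  set.seed(config$seed + 1L)
  n <- nrow(cohort$covariates)
  X <- covariate_design(cohort$covariates)
  cov_part <- drop(X %*% config$covariate_effects[colnames(X)])
  z <- as.matrix(cohort$truth[, c("z1", "z2")])
  out <- data.frame(participant_id = cohort$covariates$participant_id)
  for (s in c("right", "left")) {
    lp <- config$outcome_intercept[[s]] +
      drop(z %*% c(config$beta_z1[[s]], config$beta_z2[[s]])) + cov_part
    out[[paste0("linpred_", s, "_mm3")]] <- lp
    out[[paste0(s, "_hipp_mm3")]] <- lp +
      stats::rnorm(n, 0, config$noise_sd[[s]])
  }
  out[, c("participant_id", "right_hipp_mm3", "left_hipp_mm3",
          "linpred_right_mm3", "linpred_left_mm3")]
}

# Integer apportionment of `total` minutes across parts by largest
# remainder; deterministic, sums exactly to total.
apportion_minutes <- function(p, total) {
  raw <- p / sum(p) * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Build one day of epoch-level MET values with stated minutes per band
#'
#' Constructs a 1440-epoch day containing exactly `minutes[band]` worn
#' epochs in each intensity band, arranged in shuffled bouts, with the
#' remaining epochs as zero-signal (non-wear) runs split into a leading and
#' a trailing block. Processing the day with [summarize_day()] recovers
#' `minutes` exactly, because zero-MET epochs never count as wear.
#'
#' @param minutes Named integer minutes `c(sb=, lpa=, mvpa=)`, summing to
#'   at most 1440.
#' @param max_bout Longest bout per band, minutes.
#' @param met_range Per-band MET sampling ranges (values are rounded to the
#'   0.1 MET resolution typical of consumer devices, staying within band).
#' @return Numeric vector of 1440 MET values.
#' @export
simulate_day_epochs <- function(minutes,
                                max_bout = c(sb = 45L, lpa = 30L, mvpa = 15L),
                                met_range = list(sb = c(0.9, 1.5),
                                                 lpa = c(1.6, 2.9),
                                                 mvpa = c(3.0, 5.9))) {
  minutes <- minutes[behaviour_parts()]
  if (anyNA(minutes) || any(minutes < 0) || any(minutes != round(minutes)))
    stop("minutes must be named non-negative integers for sb, lpa, mvpa")
  wear <- sum(minutes)
  if (wear > EPOCHS_PER_DAY)
    stop("daily minutes (", wear, ") exceed ", EPOCHS_PER_DAY)
  bouts_band <- character(0)
  bouts_len <- integer(0)
  for (band in behaviour_parts()) {
    m <- minutes[[band]]
    if (m == 0L) next
    k <- ceiling(m / max_bout[[band]])
    len <- rep(m %/% k, k)
    extra <- m - sum(len)
    if (extra > 0L) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
    bouts_band <- c(bouts_band, rep(band, k))
    bouts_len <- c(bouts_len, len)
  }
  if (length(bouts_len)) {
    ord <- sample.int(length(bouts_len))
    bouts_band <- bouts_band[ord]
    bouts_len <- bouts_len[ord]
    mets <- vapply(bouts_band, function(b)
      round(stats::runif(1L, met_range[[b]][1L], met_range[[b]][2L]), 1L),
      numeric(1))
    worn <- rep(mets, bouts_len)
  } else {
    worn <- numeric(0)
  }
  nonwear <- EPOCHS_PER_DAY - wear
  lead <- ceiling(nonwear / 2)
  c(numeric(lead), worn, numeric(nonwear - lead))
}

#' Generate epoch-level accelerometer streams for a cohort
#'
#' Each participant contributes `days_per_participant` days. A habitual
#' wear level is drawn per participant (`wear_mean`, `wear_sd`) and daily
#' wear varies around it (`wear_daily_sd`), clipped to 600-1380 min so
#' every simulated day is valid; daily band minutes apportion the
#' participant's true composition over that wear time, and
#' [simulate_day_epochs()] lays the minutes out as bouted MET values.
#'
#' @inheritParams generate_outcomes
#' @return A list: `epochs` (data.table `participant_id`, `date`,
#'   `epoch_index`, `met_value`) and `daily_truth` (data.table of intended
#'   per-day minutes: `participant_id`, `date`, `sb_min`, `lpa_min`,
#'   `mvpa_min`, `wear_min`).
#' @export
generate_epochs <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "cohort"))
  set.seed(config$seed + 2L)
  n <- nrow(cohort$truth)
  days <- config$days_per_participant
  dates <- config$start_date + seq_len(days) - 1L
  met_list <- vector("list", n * days)
  truth_rows <- vector("list", n * days)
  k <- 0L
  for (i in seq_len(n)) {
    comp <- c(sb = cohort$truth$sb[i], lpa = cohort$truth$lpa[i],
              mvpa = cohort$truth$mvpa[i])
    habitual <- pmin(pmax(
      stats::rnorm(1L, config$wear_mean, config$wear_sd), 620), 1360)
    wear_d <- round(pmin(pmax(
      stats::rnorm(days, habitual, config$wear_daily_sd), 600), 1380))
    for (d in seq_len(days)) {
      mins <- apportion_minutes(comp, wear_d[d])
      k <- k + 1L
      met_list[[k]] <- simulate_day_epochs(mins)
      truth_rows[[k]] <- data.frame(
        participant_id = cohort$truth$participant_id[i], date = dates[d],
        sb_min = mins[["sb"]], lpa_min = mins[["lpa"]],
        mvpa_min = mins[["mvpa"]], wear_min = as.integer(wear_d[d]))
    }
  }
  epochs <- data.table::data.table(
    participant_id = rep(rep(cohort$truth$participant_id, each = days),
                         each = EPOCHS_PER_DAY),
    date = rep(rep(dates, n), each = EPOCHS_PER_DAY),
    epoch_index = rep(seq_len(EPOCHS_PER_DAY) - 1L, n * days),
    met_value = unlist(met_list, use.names = FALSE))
  list(epochs = epochs,
       daily_truth = data.table::rbindlist(truth_rows))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d participants x %d days (seed %d)\n",
              x$n_participants, x$days_per_participant, x$seed))
  cat(sprintf("  compositional centre: SB %.1f%% / LPA %.1f%% / MVPA %.1f%%\n",
              100 * x$mean_composition[["sb"]],
              100 * x$mean_composition[["lpa"]],
              100 * x$mean_composition[["mvpa"]]))
  cat(sprintf("  true beta_z1 (MVPA pivot): right %.1f, left %.1f mm^3/ilr\n",
              x$beta_z1[["right"]], x$beta_z1[["left"]]))
  cat(sprintf("  residual SD: right %.1f, left %.1f mm^3\n",
              x$noise_sd[["right"]], x$noise_sd[["left"]]))
  invisible(x)
}
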