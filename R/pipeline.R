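# End-to-end orchestration: ingestion (synthetic or CSV), accelerometer
# screening, composition building, descriptives, variation matrix, the
# nested model suite, and the reallocation curve, with an auditable JSON
# run log of exclusion counts and configuration.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] for synthetic input, or `NULL` when
#'   reading CSVs.
#' @param epochs_csv,covariates_csv Input paths for real data: an epoch
#'   table (`participant_id`, `date`, `epoch_index`, `met_value`) and a
#'   participant table (design-coded covariates, `icv_mm3`,
#'   `right_hipp_mm3`, `left_hipp_mm3`). Ignored when `cohort` is given.
#' @param nonwear_min,nonwear_strict,valid_day_min,min_valid_days,sb_max,mvpa_min
#'   Screening thresholds (defaults: zero-signal runs longer than 60 min
#'   are non-wear, a valid day has >= 600 wear minutes, inclusion needs
#'   >= 4 valid days, MET cut-points 1.5 / 3.0).
#' @param zero_strategy Zero-handling for compositions
#'   (see [replace_zeros()]).
#' @param composition_method `"pooled"` or `"daymean"`
#'   (see [participant_composition()]).
#' @param models Adjustment levels to fit (subset of 1:5).
#' @param include_ratio Also fit volume/ICV sensitivity outcomes.
#' @param realloc_focal,realloc_deltas_pp,realloc_rule,realloc_base
#'   Reallocation settings; `realloc_base` is `"arithmetic"` (closure of
#'   the mean daily minutes, the convention that matches published
#'   reallocation figures) or `"geometric"` (the compositional mean).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            epochs_csv = NULL, covariates_csv = NULL,
                            nonwear_min = 60L, nonwear_strict = TRUE,
                            valid_day_min = 600L, min_valid_days = 4L,
                            sb_max = 1.5, mvpa_min = 3.0,
                            zero_strategy = "multiplicative",
                            composition_method = "pooled",
                            models = 1:5, include_ratio = TRUE,
                            realloc_focal = "mvpa",
                            realloc_deltas_pp = seq(-3, 3, by = 0.5),
                            realloc_rule = "equal",
                            realloc_base = "arithmetic") {
  if (is.null(cohort)) {
    if (is.null(epochs_csv) || is.null(covariates_csv))
      stop("either a cohort config or both input CSV paths are required")
    if (!file.exists(epochs_csv)) stop("epochs_csv not found: ", epochs_csv)
    if (!file.exists(covariates_csv))
      stop("covariates_csv not found: ", covariates_csv)
  }
  stopifnot(nonwear_min > 0, valid_day_min > 0, min_valid_days > 0,
            all(models %in% 1:5))
  structure(list(
    cohort = cohort, epochs_csv = epochs_csv,
    covariates_csv = covariates_csv, nonwear_min = nonwear_min,
    nonwear_strict = nonwear_strict, valid_day_min = valid_day_min,
    min_valid_days = min_valid_days, sb_max = sb_max, mvpa_min = mvpa_min,
    zero_strategy = zero_strategy,
    composition_method = composition_method, models = models,
    include_ratio = include_ratio, realloc_focal = realloc_focal,
    realloc_deltas_pp = realloc_deltas_pp, realloc_rule = realloc_rule,
    realloc_base = realloc_base), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Ingestion (synthetic generation or CSVs) -> non-wear / valid-day /
#' valid-participant screening -> wear-time compositions with zero
#' handling -> descriptives and variation matrix -> nested compositional
#' model suite -> reallocation curve for the focal behaviour, each artifact
#' written to `out_dir`. If screening leaves no participants the pipeline
#' writes the screening artifacts and the log, reports n = 0, and skips
#' model fitting gracefully.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list: `days`, `participants`, `analysis` (the
#'   merged model table), `variation`, `suite`, `realloc`, `log`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = config_log(config))

  # --- ingestion -----------------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort)
    outcomes <- generate_outcomes(cohort)
    epochs <- generate_epochs(cohort)$epochs
    covariates <- merge(cohort$covariates,
                        outcomes[, c("participant_id", "right_hipp_mm3",
                                     "left_hipp_mm3")],
                        by = "participant_id")
  } else {
    epochs <- data.table::fread(config$epochs_csv)
    covariates <- data.table::fread(config$covariates_csv,
                                    data.table = FALSE)
  }
  log$n_input <- length(unique(epochs$participant_id))

  # --- accelerometer screening --------------------------------------------
  days <- process_epochs(epochs, config$nonwear_min, config$nonwear_strict,
                         config$valid_day_min, config$sb_max,
                         config$mvpa_min)
  participants <- screen_participants(days, config$min_valid_days)
  participants$exclusion_reason <- ifelse(participants$included, "",
                                          "insufficient_valid_days")
  log$n_included <- sum(participants$included)
  log$n_excluded_wear <- sum(!participants$included)

  utils::write.table(days, file.path(out_dir, "days.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(participants, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- compositions --------------------------------------------------------
  comp <- participant_composition(participants, config$composition_method,
                                  day_summaries = days)
  analysis <- merge(comp, covariates, by = "participant_id")
  log$n_analysis <- nrow(analysis)

  if (nrow(analysis) == 0L) {
    log$note <- "no participants survived screening; model fitting skipped"
    write_descriptives(analysis, file.path(out_dir, "descriptives.tsv"))
    write_run_log(log, file.path(out_dir, "run_log.json"))
    message("pipeline: n = 0 after screening; model fitting skipped")
    return(invisible(list(days = days, participants = participants,
                          analysis = analysis, variation = NULL,
                          suite = NULL, realloc = NULL, log = log)))
  }

  cm <- replace_zeros(analysis[, behaviour_parts()],
                      strategy = config$zero_strategy)
  log$n_zero_parts_replaced <- attr(cm, "n_replaced")
  analysis[, behaviour_parts()] <- cm

  act <- participants[participants$included, , drop = FALSE]
  act <- act[match(analysis$participant_id, act$participant_id), ]
  analysis$wear_mean <- act$wear_mean
  analysis$sb_mean <- act$sb_mean
  analysis$lpa_mean <- act$lpa_mean
  analysis$mvpa_mean <- act$mvpa_mean

  write_descriptives(analysis, file.path(out_dir, "descriptives.tsv"))

  vm <- variation_matrix(analysis[, behaviour_parts()])
  write_variation_matrix(vm, file.path(out_dir, "variation_matrix.tsv"))

  # --- model suite ---------------------------------------------------------
  suite <- run_model_suite(analysis, models = config$models,
                           include_ratio = config$include_ratio)
  write_coefficient_table(suite, file.path(out_dir, "coefficients.tsv"))

  # --- reallocation --------------------------------------------------------
  top <- max(config$models)
  pm <- fit_pivot_models(analysis, top, "right_hipp_mm3")
  base <- if (config$realloc_base == "geometric") {
    compositional_mean(analysis[, behaviour_parts()])
  } else {
    close_composition(colMeans(cbind(sb = analysis$sb_mean,
                                     lpa = analysis$lpa_mean,
                                     mvpa = analysis$mvpa_mean)))
  }
  wear <- mean(analysis$wear_mean)
  realloc <- reallocation_curve(pm$log_contrast, base,
                                focal = config$realloc_focal,
                                deltas_pp = config$realloc_deltas_pp,
                                rule = config$realloc_rule,
                                wear_min = wear)
  names(realloc)[names(realloc) == "predicted_diff"] <- "predicted_diff_mm3"
  utils::write.table(realloc, file.path(out_dir, "reallocation_curve.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  log$realloc_base_composition <- stats::setNames(as.numeric(base),
                                                  behaviour_parts())
  log$realloc_base_convention <- config$realloc_base
  log$mean_wear_min <- wear

  write_run_log(log, file.path(out_dir, "run_log.json"))
  invisible(list(days = days, participants = participants,
                 analysis = analysis, variation = vm, suite = suite,
                 realloc = realloc, log = log))
}

# Flatten the config for the run log (drop the non-scalar cohort internals
# to a short summary).
config_log <- function(config) {
  out <- unclass(config)
  if (!is.null(out$cohort)) {
    ch <- out$cohort
    out$cohort <- list(n_participants = ch$n_participants, seed = ch$seed,
                       days_per_participant = ch$days_per_participant,
                       wear_mean = ch$wear_mean)
  }
  out
}

write_run_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write a descriptives table (n (%) / mean (SD))
#'
#' @param analysis The merged analysis table from [run_pipeline()] (may be
#'   empty, giving a header-only file).
#' @param path Output TSV.
#' @return The descriptives data.frame, invisibly.
#' @export
write_descriptives <- function(analysis, path) {
  rows <- list()
  add_cat <- function(label, x) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = label, n = sum(x), pct = sprintf("%.1f", 100 * mean(x)),
      mean = "", sd = "")
  }
  add_num <- function(label, x, digits = 1) {
    s <- stats::sd(x)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = label, n = NA_integer_, pct = "",
      mean = sprintf("%.*f", digits, mean(x)),
      sd = if (is.na(s)) "" else sprintf("%.*f", digits, s))
  }
  if (nrow(analysis) > 0L) {
    add_cat("Sex, male", analysis$sex_male == 1)
    add_num("Age, years", analysis$age_years)
    add_cat("BMI <18.5", analysis$bmi_cat == "under")
    add_cat("BMI >=25.0", analysis$bmi_cat == "over")
    add_cat("Education >=13 years", analysis$education_13y == 1)
    add_cat("Smoker", analysis$smoker == 1)
    add_cat("Alcohol >=60 g/day", analysis$alcohol_heavy == 1)
    add_cat("Medication: hypertension", analysis$med_hypertension == 1)
    add_cat("Medication: dyslipidemia", analysis$med_dyslipidemia == 1)
    add_cat("Medication: diabetes", analysis$med_diabetes == 1)
    if ("wear_mean" %in% names(analysis)) {
      add_num("Accelerometer wear time, min/day", analysis$wear_mean)
      add_num("SB, min/day", analysis$sb_mean)
      add_num("LPA, min/day", analysis$lpa_mean)
      add_num("MVPA, min/day", analysis$mvpa_mean)
    }
    add_num("Intracranial volume, mm^3", analysis$icv_mm3)
    if ("right_hipp_mm3" %in% names(analysis)) {
      add_num("Right hippocampal volume, mm^3", analysis$right_hipp_mm3)
      add_num("Left hippocampal volume, mm^3", analysis$left_hipp_mm3)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), n = integer(0), pct = character(0),
               mean = character(0), sd = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Write epoch and participant tables as CSV
#'
#' Convenience writers for the pipeline's CSV dialects.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(x, path) {
  data.table::fwrite(x, path)
  invisible(path)
}
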