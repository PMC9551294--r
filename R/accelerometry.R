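# Epoch-level accelerometry processing: non-wear detection, MET intensity
# banding, day summaries and participant-level screening. All rules default
# to the conventional criteria for waist-worn devices in older cohorts:
# non-wear = a zero-signal run longer than 60 min, valid day = >= 600 wear
# minutes, valid participant = >= 4 valid days, MET cut-points 1.5 / 3.0.

EPOCHS_PER_DAY <- 1440L

#' Detect non-wear epochs in a day of MET values
#'
#' An epoch belongs to non-wear when it sits inside a run of consecutive
#' zero-MET (no-signal) epochs whose length exceeds the threshold.
#'
#' @param met Numeric vector of 1440 non-negative MET values (60-s epochs);
#'   0 encodes absence of an acceleration signal.
#' @param threshold_min Run-length threshold in minutes (default 60).
#' @param strict If `TRUE` (default) a run must be strictly longer than the
#'   threshold ("longer than 60 minutes"); `FALSE` uses `>=`.
#' @return Logical vector of length 1440, `TRUE` for non-wear epochs.
#' @examples
#' met <- rep(1, 1440); met[101:161] <- 0
#' which(detect_nonwear(met))  # the 61-epoch zero run
#' @export
detect_nonwear <- function(met, threshold_min = 60L, strict = TRUE) {
  if (length(met) != EPOCHS_PER_DAY)
    stop("expected ", EPOCHS_PER_DAY, " epochs, got ", length(met))
  if (anyNA(met) || any(met < 0)) stop("MET values must be non-negative")
  r <- rle(met == 0)
  long <- r$values & if (strict) r$lengths > threshold_min else r$lengths >= threshold_min
  rep(long, r$lengths)
}

#' Classify worn epochs into intensity bands
#'
#' @param met Strictly positive MET values (worn epochs only; a 0 value is a
#'   contract violation since non-worn epochs must not be classified).
#' @param sb_max Upper MET bound of sedentary behaviour (default 1.5).
#' @param mvpa_min Lower MET bound of MVPA (default 3.0).
#' @return Factor with levels `sb`, `lpa`, `mvpa`: `sb` if `met <= sb_max`,
#'   `mvpa` if `met >= mvpa_min`, `lpa` in between.
#' @export
classify_intensity <- function(met, sb_max = 1.5, mvpa_min = 3.0) {
  if (anyNA(met) || any(met <= 0))
    stop("classify_intensity is defined only for worn epochs (MET > 0)")
  band <- ifelse(met <= sb_max, "sb", ifelse(met >= mvpa_min, "mvpa", "lpa"))
  factor(band, levels = behaviour_parts())
}

#' Summarise one day of epochs into wear and intensity minutes
#'
#' Wear epochs are those with a signal (`met > 0`) not belonging to a
#' non-wear run; each wear epoch contributes one minute to its band.
#'
#' @inheritParams detect_nonwear
#' @inheritParams classify_intensity
#' @param valid_min Minimum wear minutes for a valid day (default 600, i.e.
#'   10 h).
#' @return A one-row data.frame: `wear_min`, `sb_min`, `lpa_min`,
#'   `mvpa_min`, `valid`. Always `sb + lpa + mvpa == wear`.
#' @export
summarize_day <- function(met, threshold_min = 60L, strict = TRUE,
                          valid_min = 600L, sb_max = 1.5, mvpa_min = 3.0) {
  nw <- detect_nonwear(met, threshold_min, strict)
  worn <- met > 0 & !nw
  if (any(worn)) {
    band <- classify_intensity(met[worn], sb_max, mvpa_min)
    counts <- tabulate(band, nbins = 3L)
  } else {
    counts <- integer(3L)
  }
  wear <- sum(worn)
  data.frame(wear_min = wear, sb_min = counts[1L], lpa_min = counts[2L],
             mvpa_min = counts[3L], valid = wear >= valid_min)
}

#' Process an epoch table into per-day summaries
#'
#' @param epochs A data.frame/data.table with columns `participant_id`,
#'   `date`, `epoch_index` (0-1439) and `met_value`. Days with fewer than
#'   1440 recorded epochs are padded with zero (no-signal) epochs at the
#'   missing indices, so partial days are handled as non-wear.
#' @inheritParams summarize_day
#' @return A data.table with one row per (participant, date):
#'   `participant_id`, `date`, `wear_min`, `sb_min`, `lpa_min`, `mvpa_min`,
#'   `valid`.
#' @export
process_epochs <- function(epochs, threshold_min = 60L, strict = TRUE,
                           valid_min = 600L, sb_max = 1.5, mvpa_min = 3.0) {
  need <- c("participant_id", "date", "epoch_index", "met_value")
  if (!all(need %in% names(epochs)))
    stop("epochs table must have columns ", paste(need, collapse = ", "))
  dt <- data.table::as.data.table(epochs)
  if (anyDuplicated(dt, by = c("participant_id", "date", "epoch_index")))
    stop("duplicate (participant, date, epoch_index) records")
  if (any(dt$epoch_index < 0L | dt$epoch_index >= EPOCHS_PER_DAY))
    stop("epoch_index must lie in 0..1439")
  epoch_index <- met_value <- NULL  # NSE bindings
  dt[, {
    met <- numeric(EPOCHS_PER_DAY)
    met[epoch_index + 1L] <- met_value
    summarize_day(met, threshold_min, strict, valid_min, sb_max, mvpa_min)
  }, by = c("participant_id", "date")]
}

#' Screen a participant's day summaries into inclusion-level totals
#'
#' Totals and per-day means are computed over valid days only; a
#' participant is included with at least `min_valid_days` valid days.
#'
#' @param days Day summaries for one participant ([summarize_day()] rows).
#' @param min_valid_days Inclusion threshold (default 4).
#' @return One-row data.frame: day counts, total and mean minutes per band,
#'   total wear, and the `included` flag.
#' @export
screen_participant <- function(days, min_valid_days = 4L) {
  if (nrow(days) < 1L) stop("at least one day summary required")
  v <- days[days$valid, , drop = FALSE]
  nv <- nrow(v)
  tot <- function(col) if (nv) as.numeric(sum(v[[col]])) else 0
  avg <- function(col) if (nv) mean(v[[col]]) else NA_real_
  data.frame(
    n_days = nrow(days), n_valid_days = nv,
    sb_total = tot("sb_min"), lpa_total = tot("lpa_min"),
    mvpa_total = tot("mvpa_min"), wear_total = tot("wear_min"),
    sb_mean = avg("sb_min"), lpa_mean = avg("lpa_min"),
    mvpa_mean = avg("mvpa_min"), wear_mean = avg("wear_min"),
    included = nv >= min_valid_days)
}

#' Screen all participants in a day-summary table
#'
#' @param day_summaries Output of [process_epochs()].
#' @inheritParams screen_participant
#' @return A data.table with one row per participant
#'   (see [screen_participant()]).
#' @export
screen_participants <- function(day_summaries, min_valid_days = 4L) {
  dt <- data.table::as.data.table(day_summaries)
  dt[, screen_participant(.SD, min_valid_days), by = "participant_id"]
}

#' Wear-time compositions of included participants
#'
#' The default (`"pooled"`) composition divides each behaviour's total
#' minutes over valid days by the total wear time over valid days, so days
#' with more wear weigh more. `"daymean"` instead averages the daily
#' proportions, weighting every valid day equally; it is provided as a
#' sensitivity variant.
#'
#' @param activity Participant table from [screen_participants()]; only
#'   rows with `included == TRUE` are used.
#' @param method `"pooled"` (default) or `"daymean"`.
#' @param day_summaries Required for `method = "daymean"`: the per-day table
#'   the activity table was screened from.
#' @return A data.frame: `participant_id`, `sb`, `lpa`, `mvpa` (closed
#'   proportions, possibly containing zeros — see [replace_zeros()]).
#' @export
participant_composition <- function(activity, method = c("pooled", "daymean"),
                                    day_summaries = NULL) {
  method <- match.arg(method)
  inc <- activity[activity$included, , drop = FALSE]
  if (nrow(inc) == 0L)
    return(data.frame(participant_id = character(0), sb = numeric(0),
                      lpa = numeric(0), mvpa = numeric(0)))
  if (method == "pooled") {
    if (any(inc$wear_total <= 0)) stop("included participant with zero wear")
    comp <- close_composition(cbind(sb = inc$sb_total, lpa = inc$lpa_total,
                                    mvpa = inc$mvpa_total))
  } else {
    if (is.null(day_summaries))
      stop("day_summaries required for method = 'daymean'")
    dt <- data.table::as.data.table(day_summaries)
    valid <- wear_min <- sb_min <- lpa_min <- mvpa_min <- NULL
    dm <- dt[valid == TRUE & participant_id %in% inc$participant_id,
             .(sb = mean(sb_min / wear_min), lpa = mean(lpa_min / wear_min),
               mvpa = mean(mvpa_min / wear_min)), by = "participant_id"]
    dm <- dm[match(inc$participant_id, dm$participant_id)]
    comp <- close_composition(cbind(sb = dm$sb, lpa = dm$lpa, mvpa = dm$mvpa))
  }
  data.frame(participant_id = inc$participant_id, comp,
             row.names = NULL, check.names = FALSE)
}

utils::globalVariables(c("participant_id", "valid", "wear_min", "sb_min",
                         "lpa_min", "mvpa_min", "met_value", "epoch_index",
                         ".SD"))
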