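test_that("non-wear detection applies the strict run-length rule", {
  expect_equal(sum(detect_nonwear(rep(1.0, 1440))), 0)
  # exactly 60 zero minutes is not "longer than 60"
  met60 <- rep(1.0, 1440); met60[201:260] <- 0
  expect_equal(sum(detect_nonwear(met60)), 0)
  # 61 zero minutes starting at epoch index 100 (0-based): 100..160 masked
  met61 <- rep(1.0, 1440); met61[101:161] <- 0
  expect_equal(which(detect_nonwear(met61)), 101:161)
  # the inclusive variant flags the 60-run
  expect_equal(sum(detect_nonwear(met60, strict = FALSE)), 60)
  expect_error(detect_nonwear(rep(1, 100)), "1440")
  expect_error(detect_nonwear(rep(-1, 1440)), "non-negative")
})

test_that("non-wear detection agrees with a brute-force zero-run scan", {
  set.seed(101)
  for (i in 1:50) {
    met <- rand_day()
    expect_identical(detect_nonwear(met), brute_nonwear(met))
    expect_identical(detect_nonwear(met, strict = FALSE),
                     brute_nonwear(met, strict = FALSE))
  }
})

test_that("MET banding uses the 1.5 / 3.0 cut-points", {
  expect_equal(as.character(classify_intensity(c(0.9, 1.5, 1.6, 2.0, 2.9,
                                                 3.0, 6.0))),
               c("sb", "sb", "lpa", "lpa", "lpa", "mvpa", "mvpa"))
  # the cut-points are operative on the continuous scale, not the 0.1-MET
  # display grid: values between 1.5 and 1.6 are light activity
  expect_equal(as.character(classify_intensity(1.55)), "lpa")
  expect_error(classify_intensity(0), "worn")
  expect_error(classify_intensity(c(2, 0)), "worn")
})

test_that("day summaries conserve minutes and apply the 10-hour rule", {
  # 400 SB + 350 LPA + 50 MVPA worn epochs, remainder one long zero run
  met <- c(rep(1.0, 400), rep(2.0, 350), rep(4.0, 50), rep(0, 640))
  d <- summarize_day(met)
  expect_equal(unlist(d[, c("wear_min", "sb_min", "lpa_min", "mvpa_min")]),
               c(wear_min = 800, sb_min = 400, lpa_min = 350,
                 mvpa_min = 50))
  expect_true(d$valid)
  # boundary of the validity rule: 599 worn epochs
  met599 <- c(rep(1.0, 599), rep(0, 841))
  d599 <- summarize_day(met599)
  expect_equal(d599$wear_min, 599)
  expect_false(d599$valid)
  expect_true(summarize_day(c(rep(1.0, 600), rep(0, 840)))$valid)
  # all-zero day
  d0 <- summarize_day(numeric(1440))
  expect_equal(d0$wear_min, 0)
  expect_false(d0$valid)
  # conservation + monotonicity on random days
  set.seed(55)
  for (i in 1:25) {
    met <- rand_day()
    d <- summarize_day(met)
    expect_identical(d$sb_min + d$lpa_min + d$mvpa_min, d$wear_min)
    # turning a zero run into worn epochs never decreases wear
    met2 <- met
    met2[met2 == 0] <- 1.0
    expect_gte(summarize_day(met2)$wear_min, d$wear_min)
    # a stricter (inclusive) non-wear rule never increases wear
    expect_lte(summarize_day(met, strict = FALSE)$wear_min, d$wear_min)
  }
})

test_that("participant screening needs four valid days and averages them", {
  day <- function(wear, sb, lpa, mvpa, valid)
    data.frame(wear_min = wear, sb_min = sb, lpa_min = lpa,
               mvpa_min = mvpa, valid = valid)
  d3 <- do.call(rbind, c(replicate(3, day(700, 400, 250, 50, TRUE),
                                   simplify = FALSE),
                         replicate(4, day(100, 60, 30, 10, FALSE),
                                   simplify = FALSE)))
  s3 <- screen_participant(d3)
  expect_false(s3$included)
  expect_equal(s3$n_valid_days, 3L)
  # invalid days contribute nothing to totals or means
  expect_equal(s3$wear_total, 2100)
  d7 <- do.call(rbind, replicate(7, day(800, 450, 300, 50, TRUE),
                                 simplify = FALSE))
  s7 <- screen_participant(d7)
  expect_true(s7$included)
  expect_equal(s7$mvpa_mean, 50)
  expect_equal(s7$wear_mean, 800)
  mv <- c(40, 50, 60, 50, 50)
  d5 <- do.call(rbind, lapply(mv, function(m) day(700, 400, 300 - m, m,
                                                  TRUE)))
  expect_equal(screen_participant(d5)$mvpa_mean, 50)
})

test_that("participant compositions divide band totals by total wear", {
  act <- data.frame(participant_id = "P1", n_days = 7L, n_valid_days = 5L,
                    sb_total = 2000, lpa_total = 1750, mvpa_total = 250,
                    wear_total = 4000, sb_mean = 400, lpa_mean = 350,
                    mvpa_mean = 50, wear_mean = 800, included = TRUE)
  comp <- participant_composition(act)
  expect_equal(unlist(comp[, c("sb", "lpa", "mvpa")]),
               c(sb = 0.5, lpa = 0.4375, mvpa = 0.0625))
  # a zero band survives as a zero part for downstream handling
  act$mvpa_total <- 0
  expect_equal(participant_composition(act)$mvpa, 0)
  # excluded participants yield no rows
  act$included <- FALSE
  expect_equal(nrow(participant_composition(act)), 0L)
})

test_that("epoch tables are padded, screened and composed end to end", {
  # two participants: one full week of valid days, one with short days
  set.seed(9)
  mk_day <- function(id, date, met) data.frame(
    participant_id = id, date = date, epoch_index = seq_along(met) - 1L,
    met_value = met)
  good <- do.call(rbind, lapply(1:5, function(d)
    mk_day("A", d, c(rep(1.0, 500), rep(2.0, 200), rep(3.5, 20),
                     rep(0, 720)))))
  # partial day records (only 300 epochs present) pad to non-wear
  bad <- do.call(rbind, lapply(1:5, function(d)
    mk_day("B", d, rep(1.2, 300))))
  days <- process_epochs(rbind(good, bad))
  expect_equal(nrow(days), 10L)
  expect_true(all(days[days$participant_id == "A", ]$valid))
  expect_true(all(!days[days$participant_id == "B", ]$valid))
  parts <- screen_participants(days)
  expect_identical(parts$included, c(TRUE, FALSE))
  comp <- participant_composition(parts)
  expect_equal(comp$participant_id, "A")
  expect_equal(comp$sb, 500 / 720)
  # day-mean variant agrees here because every day is identical
  comp_dm <- participant_composition(parts, "daymean", days)
  expect_equal(comp_dm$sb, comp$sb)
  expect_error(process_epochs(rbind(good, good)), "duplicate")
})
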