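# Independent oracles and small fixture builders shared across tests.

# Brute-force non-wear scan: walk every maximal zero run and mark it when
# longer than the threshold. Deliberately naive; the reference the fast
# rle-based implementation is checked against.
brute_nonwear <- function(met, threshold = 60, strict = TRUE) {
  n <- length(met)
  mask <- logical(n)
  i <- 1L
  while (i <= n) {
    if (met[i] == 0) {
      j <- i
      while (j < n && met[j + 1L] == 0) j <- j + 1L
      len <- j - i + 1L
      if (if (strict) len > threshold else len >= threshold)
        mask[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  mask
}

# Random strictly positive closed compositions.
rand_comp <- function(n) {
  m <- matrix(stats::rexp(3L * n) + 1e-6, ncol = 3L,
              dimnames = list(NULL, c("sb", "lpa", "mvpa")))
  close_composition(m)
}

# Random day built from alternating runs of zero-signal and worn epochs,
# exercising run lengths around the non-wear threshold.
rand_day <- function() {
  met <- numeric(0)
  zero <- stats::runif(1) < 0.5
  while (length(met) < 1440L) {
    len <- 1L + stats::rgeom(1L, 1 / 45)
    vals <- if (zero) numeric(len) else
      round(stats::runif(len, 0.9, 5.9), 1)
    met <- c(met, vals)
    zero <- !zero
  }
  met[seq_len(1440L)]
}

# Merged analysis table (true compositions + covariates + outcomes) for a
# synthetic cohort, bypassing the epoch layer.
make_analysis <- function(config) {
  cohort <- generate_cohort(config)
  outcomes <- generate_outcomes(cohort)
  merge(cohort$truth[, c("participant_id", "sb", "lpa", "mvpa")],
        merge(cohort$covariates, outcomes, by = "participant_id"),
        by = "participant_id")
}
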