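# Time-reallocation (isotemporal substitution) prediction on the simplex:
# shift a stated share of wear time into or out of one behaviour, spread
# the balance over the others, and predict the outcome difference from a
# fitted compositional model in its basis-free log-contrast form.

#' Log-contrast representation of a compositional effect
#'
#' A compositional linear effect can be written basis-free as coefficients
#' `a` on the log-parts with `sum(a) = 0`; the predicted outcome difference
#' between compositions `x_new` and `x_base` is
#' `sum(a * (log(x_new) - log(x_base)))`, identical in any ilr basis.
#'
#' `log_contrast()` builds the vector from the three pivot-first `z1`
#' coefficients (one per behaviour): `a_i = sqrt(2/3) * (b_i - mean(b))`,
#' the exact inverse of the pivot construction; centring absorbs rounding
#' when the betas come from a published table and do not sum exactly to
#' zero. `log_contrast_from_pivot()` builds it from one fit's `(z1, z2)`
#' pair via the pivot basis.
#'
#' @param z1_betas Named vector `c(sb=, lpa=, mvpa=)` of pivot-first `z1`
#'   coefficients (outcome units per ilr unit).
#' @return Named length-3 numeric of class `log_contrast`, summing to 0.
#' @export
log_contrast <- function(z1_betas) {
  b <- z1_betas[behaviour_parts()]
  if (anyNA(b)) stop("z1_betas must be named sb, lpa, mvpa")
  a <- sqrt(2 / 3) * (b - mean(b))
  structure(stats::setNames(as.numeric(a), behaviour_parts()),
            class = "log_contrast")
}

#' @rdname log_contrast
#' @param beta_z1,beta_z2 Coefficients of one fitted pivot pair.
#' @inheritParams pivot_basis
#' @export
log_contrast_from_pivot <- function(beta_z1, beta_z2,
                                    pivot_order = c("mvpa", "sb", "lpa")) {
  a <- drop(pivot_basis(pivot_order) %*% c(beta_z1, beta_z2))
  structure(stats::setNames(a, behaviour_parts()), class = "log_contrast")
}

#' Reallocate a share of wear time between behaviours
#'
#' The focal behaviour's proportion changes by `delta_pp` percentage points
#' of wear time; the other two behaviours absorb the opposite change either
#' equally (default) or in proportion to their base shares.
#'
#' @param base A strictly positive closed composition (named vector or
#'   1 x 3 matrix).
#' @param focal `"sb"`, `"lpa"` or `"mvpa"`.
#' @param delta_pp Signed change in percentage points of wear time.
#' @param rule `"equal"` or `"proportional"` redistribution.
#' @return The reallocated closed composition (1 x 3 matrix).
#' @examples
#' base <- close_composition(c(sb = 442.7, lpa = 391.2, mvpa = 53.6))
#' reallocate(base, "mvpa", -3)
#' @export
reallocate <- function(base, focal = "mvpa", delta_pp = 0,
                       rule = c("equal", "proportional")) {
  rule <- match.arg(rule)
  m <- as_part_matrix(base)
  if (nrow(m) != 1L) stop("reallocate expects a single base composition")
  if (any(m <= 0) || abs(sum(m) - 1) > 1e-8)
    stop("base must be a strictly positive closed composition")
  if (!focal %in% behaviour_parts())
    stop("focal must be one of ", paste(behaviour_parts(), collapse = ", "))
  delta <- delta_pp / 100
  others <- setdiff(behaviour_parts(), focal)
  new <- m
  new[, focal] <- m[, focal] + delta
  if (rule == "equal") {
    new[, others] <- m[, others] - delta / 2
  } else {
    new[, others] <- m[, others] * (1 - new[, focal]) / (1 - m[, focal])
  }
  if (any(new <= 0)) {
    lo <- -m[, focal]
    hi <- if (rule == "equal") 2 * min(m[, others]) else 1 - m[, focal]
    stop(sprintf(
      "infeasible reallocation: delta_pp = %.3g leaves a non-positive part; feasible range is (%.3g, %.3g) percentage points",
      delta_pp, 100 * lo, 100 * hi))
  }
  new / sum(new)
}

#' Predict the outcome difference for one reallocation
#'
#' Computes `sum(a * (log(new) - log(base)))` and cross-checks it against
#' the equivalent ilr-coordinate path
#' `beta_z %*% (ilr(new) - ilr(base))`; the two must agree to 1e-10
#' (relative), an internal consistency guarantee of the compositional
#' geometry.
#'
#' @param lc A [log_contrast()] effect vector.
#' @param base Strictly positive closed base composition.
#' @param focal,delta_pp,rule Passed to [reallocate()].
#' @param wear_min Optional mean wear time (min/day) used to express
#'   `delta_pp` in minutes.
#' @return A one-row data.frame: `focal`, `delta_pp`, `minutes_equiv`
#'   (`NA` without `wear_min`), the new composition (`new_sb`, `new_lpa`,
#'   `new_mvpa`) and `predicted_diff` in outcome units.
#' @export
predict_difference <- function(lc, base, focal = "mvpa", delta_pp = 0,
                               rule = c("equal", "proportional"),
                               wear_min = NULL) {
  rule <- match.arg(rule)
  if (!inherits(lc, "log_contrast")) lc <- log_contrast(lc)
  m <- as_part_matrix(base)
  if (any(m <= 0)) stop("base composition must be strictly positive")
  new <- reallocate(m, focal, delta_pp, rule)
  diff_lc <- sum(unclass(lc) * (log(new[1L, ]) - log(m[1L, ])))
  # Independent path: convert to any pivot basis and difference the ilr
  # images; agreement is an exact property, so disagreement is a bug.
  V <- pivot_basis()
  beta_z <- drop(crossprod(V, unclass(lc)))
  diff_ilr <- drop((ilr_pivot(new) - ilr_pivot(m)) %*% beta_z)
  if (abs(diff_lc - diff_ilr) > 1e-10 * max(1, abs(diff_lc)))
    stop("log-contrast and ilr prediction paths disagree")
  data.frame(focal = focal, delta_pp = delta_pp,
             minutes_equiv = if (is.null(wear_min)) NA_real_ else
               abs(delta_pp) / 100 * wear_min,
             new_sb = new[1L, "sb"], new_lpa = new[1L, "lpa"],
             new_mvpa = new[1L, "mvpa"], predicted_diff = diff_lc)
}

#' Reallocation curve over a grid of shifts
#'
#' @inheritParams predict_difference
#' @param deltas_pp Grid of percentage-point shifts; infeasible points are
#'   dropped with a warning.
#' @param wear_min Mean wear time (min/day) for the minutes-equivalent
#'   column.
#' @return A data.frame with one row per feasible grid point (columns as in
#'   [predict_difference()]).
#' @export
reallocation_curve <- function(lc, base, focal = "mvpa",
                               deltas_pp = seq(-3, 3, by = 0.5),
                               rule = c("equal", "proportional"),
                               wear_min = NULL) {
  rule <- match.arg(rule)
  rows <- list()
  dropped <- numeric(0)
  for (d in deltas_pp) {
    row <- tryCatch(
      predict_difference(lc, base, focal, d, rule, wear_min),
      error = function(e) {
        if (grepl("infeasible reallocation", conditionMessage(e))) NULL
        else stop(e)
      })
    if (is.null(row)) dropped <- c(dropped, d) else
      rows[[length(rows) + 1L]] <- row
  }
  if (length(dropped))
    warning("dropped infeasible grid points: ",
            paste(dropped, collapse = ", "))
  if (!length(rows)) stop("no feasible grid points")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
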