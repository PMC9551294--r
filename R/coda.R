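# Compositional geometry for 3-part time-use compositions (SB, LPA, MVPA):
# closure, zero replacement, pivot ilr coordinates and their inverse, the
# compositional (geometric-mean) centre, and the variation matrix.

#' Canonical behaviour labels
#'
#' All compositions in this package are 3-part wear-time compositions over
#' sedentary behaviour (`"sb"`), light physical activity (`"lpa"`) and
#' moderate-to-vigorous physical activity (`"mvpa"`), stored in this order.
#'
#' @return Character vector `c("sb", "lpa", "mvpa")`.
#' @export
behaviour_parts <- function() c("sb", "lpa", "mvpa")

# Coerce a composition input (named length-3 vector, matrix or data.frame
# with sb/lpa/mvpa columns) to an n x 3 matrix in canonical part order.
as_part_matrix <- function(x) {
  parts <- behaviour_parts()
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(names(x), parts), drop = FALSE])
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      stop("a composition must have exactly 3 parts, got ", length(x))
    if (is.null(names(x))) names(x) <- parts
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  }
  if (!all(parts %in% colnames(x)))
    stop("composition columns must be named ", paste(parts, collapse = ", "))
  x <- x[, parts, drop = FALSE]
  storage.mode(x) <- "double"
  x
}

#' Closure: normalise non-negative parts to proportions summing to 1
#'
#' @param x Amounts (e.g. minutes per behaviour): a named length-3 vector or
#'   an n x 3 matrix/data.frame with columns `sb`, `lpa`, `mvpa`.
#' @return A matrix of the same shape with each row rescaled to sum to 1
#'   (a single vector input returns a 1 x 3 matrix).
#' @details Rows with a zero part are closed as-is; pass the result through
#'   [replace_zeros()] before any log-ratio operation. An all-zero or
#'   negative row is an error, since it carries no relative information.
#' @examples
#' close_composition(c(sb = 442.7, lpa = 391.2, mvpa = 53.6))
#' @export
close_composition <- function(x) {
  m <- as_part_matrix(x)
  if (any(m < 0)) stop("composition parts must be non-negative")
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("each composition needs at least one positive part")
  m / tot
}

#' Multiplicative replacement of zero parts
#'
#' Structural zeros (behaviours never observed for a participant) break
#' log-ratio operations. The multiplicative strategy sets each zero part to a
#' small detection-limit value `delta` and shrinks the remaining parts
#' proportionally so the row still sums to 1.
#'
#' @param x Closed compositions (rows sum to 1), any zero parts allowed.
#' @param delta Replacement value per part: a scalar or a length-3 named
#'   vector. Default: per part, 0.65 times the smallest non-zero proportion
#'   observed for that part across rows; if a part is zero everywhere,
#'   0.65 times the smallest non-zero proportion anywhere in `x`.
#' @param strategy `"multiplicative"` (default), `"fail"` (error on any
#'   zero) or `"none"` (return unchanged).
#' @return The compositions with strictly positive parts; attribute
#'   `n_replaced` counts replaced entries.
#' @export
replace_zeros <- function(x, delta = NULL,
                          strategy = c("multiplicative", "fail", "none")) {
  strategy <- match.arg(strategy)
  m <- as_part_matrix(x)
  zero <- m == 0
  if (strategy == "none" || !any(zero)) {
    attr(m, "n_replaced") <- 0L
    return(m)
  }
  if (strategy == "fail")
    stop("zero parts present in ", sum(rowSums(zero) > 0), " composition(s)")
  if (is.null(delta)) {
    nz_min_all <- min(m[m > 0])
    delta <- apply(m, 2L, function(col) {
      if (any(col > 0)) 0.65 * min(col[col > 0]) else 0.65 * nz_min_all
    })
  }
  if (length(delta) == 1L) delta <- rep(delta, 3L)
  delta <- as_part_matrix(delta)[1L, ]
  if (any(delta <= 0) || any(delta >= 1)) stop("delta must lie in (0, 1)")
  out <- m
  for (i in which(rowSums(zero) > 0)) {
    z <- zero[i, ]
    out[i, z] <- delta[z]
    out[i, !z] <- m[i, !z] * (1 - sum(delta[z]))
  }
  attr(out, "n_replaced") <- sum(zero)
  out
}

#' Orthonormal pivot basis for a 3-part composition
#'
#' Builds the 3 x 2 matrix `V` whose columns express the two pivot ilr
#' coordinates as log-contrasts in canonical part order: for pivot order
#' `(p1, p2, p3)`,
#' `z1 = sqrt(2/3) * ln(p1 / sqrt(p2 * p3))` isolates the pivot behaviour
#' against the geometric mean of the rest, and
#' `z2 = sqrt(1/2) * ln(p3 / p2)` contrasts the remaining two. Columns are
#' orthonormal with zero sum, so `z = log(x) %*% V` and
#' `x = close(exp(z %*% t(V)))`.
#'
#' @param pivot_order Character permutation of `behaviour_parts()`; the first
#'   element is the pivot behaviour.
#' @return A 3 x 2 numeric matrix, rows in canonical part order.
#' @export
pivot_basis <- function(pivot_order = c("mvpa", "sb", "lpa")) {
  parts <- behaviour_parts()
  if (length(pivot_order) != 3L || !setequal(pivot_order, parts))
    stop("pivot_order must be a permutation of ", paste(parts, collapse = ", "))
  V <- matrix(0, 3L, 2L, dimnames = list(parts, c("z1", "z2")))
  V[pivot_order[1L], 1L] <- sqrt(2 / 3)
  V[pivot_order[2L:3L], 1L] <- -sqrt(1 / 6)
  V[pivot_order[2L], 2L] <- -sqrt(1 / 2)
  V[pivot_order[3L], 2L] <- sqrt(1 / 2)
  V
}

#' Pivot isometric log-ratio coordinates
#'
#' @inheritParams close_composition
#' @inheritParams pivot_basis
#' @param x Strictly positive closed compositions.
#' @return An n x 2 matrix with columns `z1`, `z2`. `z1` carries the pivot
#'   behaviour's share relative to the geometric mean of the other two; the
#'   default MVPA-first order gives `z2 = sqrt(1/2) * ln(lpa / sb)`.
#' @examples
#' ilr_pivot(close_composition(c(sb = 442.7, lpa = 391.2, mvpa = 53.6)))
#' @export
ilr_pivot <- function(x, pivot_order = c("mvpa", "sb", "lpa")) {
  m <- as_part_matrix(x)
  if (any(m <= 0))
    stop("ilr requires strictly positive parts; run replace_zeros() first")
  log(m) %*% pivot_basis(pivot_order)
}

#' Inverse pivot ilr: map real coordinates back to the simplex
#'
#' @param z A length-2 vector `(z1, z2)` or an n x 2 matrix.
#' @inheritParams pivot_basis
#' @return Closed strictly positive compositions (n x 3, canonical order).
#' @export
ilr_inverse <- function(z, pivot_order = c("mvpa", "sb", "lpa")) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != 2L) stop("z must have 2 columns (z1, z2)")
  e <- exp(z %*% t(pivot_basis(pivot_order)))
  e / rowSums(e)
}

#' Variation matrix of pairwise log-ratios
#'
#' Entry (i, j) is the sample variance (n - 1 divisor) of `ln(x_i / x_j)`
#' across compositions. Values near 0 mean the two behaviours are nearly
#' proportional across participants (high co-dependence).
#'
#' @param x At least two strictly positive closed compositions.
#' @return A symmetric 3 x 3 matrix with zero diagonal, dimnames
#'   `sb`/`lpa`/`mvpa`.
#' @export
variation_matrix <- function(x) {
  m <- as_part_matrix(x)
  if (nrow(m) < 2L) stop("variation matrix needs at least 2 compositions")
  if (any(m <= 0)) stop("variation matrix requires strictly positive parts")
  lm_ <- log(m)
  parts <- behaviour_parts()
  out <- matrix(0, 3L, 3L, dimnames = list(parts, parts))
  for (i in 1:2) for (j in (i + 1):3) {
    v <- stats::var(lm_[, i] - lm_[, j])
    out[i, j] <- v
    out[j, i] <- v
  }
  out
}

#' Compositional mean (closed geometric means)
#'
#' @param x Strictly positive closed compositions (n >= 1).
#' @return A 1 x 3 matrix: the closure of the part-wise geometric means.
#' @export
compositional_mean <- function(x) {
  m <- as_part_matrix(x)
  if (any(m <= 0)) stop("compositional mean requires strictly positive parts")
  g <- exp(colMeans(log(m)))
  matrix(g / sum(g), nrow = 1L, dimnames = list(NULL, behaviour_parts()))
}

#' Write a variation matrix as a labelled lower-triangle TSV
#'
#' @param vm A 3 x 3 variation matrix from [variation_matrix()].
#' @param path Output file.
#' @param digits Decimal places (default 2, the conventional display
#'   resolution for log-ratio variances).
#' @return `path`, invisibly.
#' @export
write_variation_matrix <- function(vm, path, digits = 2) {
  parts <- toupper(behaviour_parts())
  lines <- c(paste(c("", parts), collapse = "\t"))
  for (i in 1:3) {
    vals <- vapply(seq_len(i), function(j)
      if (i == j) "0" else formatC(vm[i, j], format = "f", digits = digits),
      character(1))
    lines <- c(lines, paste(c(parts[i], vals), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
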