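#' Round an angle to the nearest 5 degrees
#'
#' Exact half-way values round away from zero, so the map is odd and
#' idempotent and never moves a value by more than 2.5 degrees.
#'
#' @param angle_deg numeric vector (degrees).
#' @return numeric vector of multiples of 5.
#' @export
round_to_nearest_5 <- function(angle_deg) {
  sign(angle_deg) * 5 * floor(abs(angle_deg) / 5 + 0.5)
}

#' Paired Student t-test (from the formula)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y`, `df = n - 1`, and a
#' two-sided p-value from the t distribution. Implemented directly so the
#' pipeline's statistic is self-contained; agreement with a reference
#' implementation is part of the test suite. Zero-variance differences are
#' degenerate: `t` and `p` are `NA` and `degenerate` is set.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("paired t-test needs n >= 2")
  d <- x - y
  s <- sd(d)
  if (!is.finite(s) || s < 1e-12) {
    return(list(t = NA_real_, df = n - 1, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Pearson correlation (from the formula)
#'
#' Sample Pearson coefficient with the usual t-approximation p-value
#' (`t = r * sqrt((n - 2) / (1 - r^2))`, df = n - 2, two-sided).
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("pearson_r needs n >= 3")
  sx <- sd(x); sy <- sd(y)
  if (sx < 1e-12 || sy < 1e-12) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- min(1, max(-1, r))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2), n = n)
}

#' Cohort accounting summary
#'
#' Bookkeeping of a screening funnel: eligible cases minus exclusions gives
#' the analyzed count, with sex percentages recomputed from the counts.
#'
#' @param eligible cases fulfilling inclusion criteria.
#' @param excluded cases removed.
#' @param n_female females among the analyzed cases.
#' @return list with `analyzed`, `n_female`, `n_male`, `pct_female`,
#'   `pct_male` (percent, one decimal).
#' @export
cohort_accounting <- function(eligible, excluded, n_female) {
  analyzed <- eligible - excluded
  if (n_female > analyzed) stop("more females than analyzed cases")
  list(analyzed = analyzed, n_female = n_female,
       n_male = analyzed - n_female,
       pct_female = round(100 * n_female / analyzed, 1),
       pct_male = round(100 * (analyzed - n_female) / analyzed, 1))
}
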