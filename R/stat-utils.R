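# Thin wrappers around stats:: with explicit degenerate-input conventions.

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` (two-sided), `n`. `r` and `p` are NA when
#'   either vector has zero variance or n < 3.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value, n = n)
}

#' Two-sided paired t-test
#'
#' @param x,y Numeric vectors of equal length (paired).
#' @return List with `t`, `p`, `mean_diff`, `n`. With n < 2 the statistic is
#'   undefined (NA); with constant differences t = 0/p = 1 for zero mean
#'   difference and |t| = Inf/p = 0 otherwise.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  if (n < 2L) return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d), n = n))
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0, mean_diff = mean(d), n = n))
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, mean_diff = mean(d), n = n)
}

#' Quartiles by linear interpolation
#'
#' Q2 is the median; Q1/Q3 use the standard linear-interpolation convention
#' (type 7).
#'
#' @param x Numeric vector.
#' @return Numeric(3): Q1, Q2, Q3.
#' @export
quartiles <- function(x) {
  stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
}

#' Ordinary least-squares slope with two-sided t-test
#'
#' Fits `y ~ x` and tests slope != 0. Degenerate conventions: zero residual
#' variance gives p = 1 for a (numerically) zero slope and p = 0 otherwise;
#' zero variance in `x` gives NA.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `slope`, `t`, `p`, `n`.
#' @export
ols_slope_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L || stats::var(x) == 0)
    return(list(slope = NA_real_, t = NA_real_, p = NA_real_, n = n))
  fit <- stats::lm(y ~ x)
  sl <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-10 * max(1, sum(y^2)))
    return(list(slope = sl, t = if (abs(sl) < 1e-12) 0 else sign(sl) * Inf,
                p = if (abs(sl) < 1e-12) 1 else 0, n = n))
  co <- summary(fit)$coefficients
  list(slope = sl, t = unname(co[2, 3]), p = unname(co[2, 4]), n = n)
}
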