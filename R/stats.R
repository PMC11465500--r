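#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Thin wrapper used for the cross-treatment comparisons: exact two-sided p
#' by enumeration when both samples are small (min(n, m) <= 8) and tie-free,
#' otherwise the normal approximation with tie correction. Returns the
#' Mann-Whitney U statistic for the first sample.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (U) and `p_value` (two-sided).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("rank_sum_test: both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Ordinary least-squares fit with R-squared
#'
#' Used to relate percent endogenous to input amount: simple linear
#' regression `y ~ x`; R-squared is the squared Pearson correlation and the
#' p-value is the slope t-test.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with `r_squared`, `p_value`, `slope`, `intercept`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("linear_fit_r2: need n >= 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0)
    stop("linear_fit_r2: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["x", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
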