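#' Log response ratio between low- and high-concentration groups
#'
#' The within-study effect size for the respiratory dilution effect:
#' \eqn{\mathrm{LRR} = \ln(X_L / X_H)}, where \eqn{X_L} is the mean per
#' capita sperm metabolic rate at the lower concentration and \eqn{X_H} at
#' the higher. LRR > 0 means diluted sperm respire faster per capita.
#' Estimates are deliberately unweighted: scaling by sampling error would
#' distort the quantitative density-metabolism relationship the ratio is
#' meant to capture.
#'
#' @param mean_low mean per capita rate at the lower concentration (> 0).
#' @param mean_high mean per capita rate at the higher concentration (> 0).
#' @return ln response ratio. Vectorized.
#' @examples
#' log_response_ratio(1.2, 1.0)  # 0.1823, a 1.2-fold difference
#' @export
log_response_ratio <- function(mean_low, mean_high) {
  if (any(mean_low <= 0) || any(mean_high <= 0)) {
    stop("group means must be > 0", call. = FALSE)
  }
  log(mean_low / mean_high)
}

#' One-sample location test on study-level log response ratios
#'
#' Tests whether the mean study-level LRR differs from zero (no dilution
#' effect) with an unweighted one-sample t test, and reports the mean
#' ratio as a fold-difference.
#'
#' @param lrr numeric vector of study-level log response ratios (>= 2).
#' @return list with `mean_lrr`, `fold` (= exp(mean)), `t_statistic`, `df`,
#'   `p_value`, `n`.
#' @export
lrr_group_test <- function(lrr) {
  lrr <- lrr[!is.na(lrr)]
  if (length(lrr) < 2L) {
    stop("need at least two study-level LRRs", call. = FALSE)
  }
  tt <- stats::t.test(lrr, mu = 0)
  list(mean_lrr = unname(tt$estimate), fold = exp(unname(tt$estimate)),
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = length(lrr))
}

#' Percent change in per capita metabolic rate per 10-fold dilution
#'
#' For a per-capita concentration exponent \eqn{b}, a 10-fold decrease in
#' concentration multiplies the per capita rate by \eqn{10^{-b}};
#' the percent change is \eqn{100 (10^{-b} - 1)}. With \eqn{b = -0.13}
#' (ejaculate exponent 0.87) dilution by one decade raises per capita
#' metabolism by 34.9%, the "35%" headline under half-up integer rounding
#' (see [round_half_up()], the presentation step).
#'
#' @param per_capita_exponent the per-capita exponent \eqn{b}
#'   (ejaculate-level exponent minus 1).
#' @return percent change per 10-fold dilution. Vectorized.
#' @examples
#' percent_change_per_decade(-0.13)        # 34.9
#' round_half_up(percent_change_per_decade(-0.13))  # 35
#' @export
percent_change_per_decade <- function(per_capita_exponent) {
  100 * (10^(-per_capita_exponent) - 1)
}

#' Half-up rounding for headline percentages
#'
#' Rounds halves away from zero (so 34.5 -> 35, -34.5 -> -35), the
#' convention used for the package's headline integer percentages; base
#' [round()] rounds halves to even.
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
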