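# Independent oracles used across test files.

# Exhaustive window search with stats::lm as the slope/SE engine; the
# package's best_local_slope uses its own closed-form accumulation, so this
# is an independent route to the same objective.
brute_force_best_window <- function(trace, min_window_fraction = 1/3) {
  n <- nrow(trace)
  min_size <- max(5L, ceiling(min_window_fraction * n))
  time_h <- trace$time_min / 60
  sat <- trace$pct_air_saturation
  best <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      len <- j - i + 1L
      if (len < min_size) next
      fit <- summary(stats::lm(sat[i:j] ~ time_h[i:j]))$coefficients
      slope <- fit[2, 1]
      se <- fit[2, 2]
      rel <- if (slope == 0) Inf else se / abs(slope)
      if (is.null(best) || rel < best$rel - 1e-12 ||
          (abs(rel - best$rel) <= 1e-12 &&
           (len > best$len ||
            (len == best$len && i < best$window[1])))) {
        best <- list(rel = rel, len = len, window = c(i, j), slope = slope,
                     se = se)
      }
    }
  }
  best
}

# Pooled OLS slope of ln(rate) on ln(concentration), the closed-form
# least-squares oracle for degenerate mixed-model limits.
pooled_ols <- function(records, covariate = NULL) {
  df <- data.frame(y = log(records$rate_ul_o2_per_h),
                   x = log(records$concentration_sperm_per_ml))
  if (!is.null(covariate)) {
    df$g <- factor(records[[covariate]],
                   levels = c("ectotherm", "endotherm"))
    stats::lm(y ~ x + g, data = df)
  } else {
    stats::lm(y ~ x, data = df)
  }
}

default_dataset <- function(seed = 1, ...) {
  generate_metabolic_dataset(generator_config(seed = seed, ...))
}
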