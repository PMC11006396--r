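test_that("saturation filter keeps the contiguous in-window prefix", {
  # 100 -> 60%: keep from the start down to the last point >= 75
  tr <- generate_oxygen_trace(true_vo2 = 3.833, volume = 750,
                              capacitance = 5.11, duration = 30,
                              noise_sd = 0, seed = 1)  # -100 % AS h^-1
  filt <- saturation_filter(tr, 100, 75)
  expect_true(all(filt$pct_air_saturation >= 75 &
                    filt$pct_air_saturation <= 100))
  expect_equal(filt$time_min[1], 0)
  last <- max(which(tr$pct_air_saturation >= 75))
  expect_equal(nrow(filt), last)

  # trace entirely within bounds is untouched
  flat <- generate_oxygen_trace(0.1, noise_sd = 0, seed = 1)
  expect_equal(saturation_filter(flat, 100, 75), flat)

  # trace starting below the lower bound is empty (caller excludes chamber)
  low <- generate_oxygen_trace(0.38325, start_saturation = 60,
                               noise_sd = 0, seed = 1)
  expect_equal(nrow(saturation_filter(low, 100, 75)), 0L)
})

test_that("best_local_slope recovers exact slopes with full-window ties", {
  tr <- generate_oxygen_trace(0.38325 / 2, noise_sd = 0, seed = 1)  # -5 %/h
  est <- best_local_slope(tr)
  expect_equal(est$slope, -5, tolerance = 1e-12)
  expect_equal(est$window, c(1L, nrow(tr)))
  expect_equal(est$n_points, nrow(tr))
  expect_false(est$unstable)
})

test_that("best_local_slope matches the exhaustive lm-based window search", {
  cases <- list(
    generate_oxygen_trace(0.2, noise_sd = 0.5, duration = 40, seed = 11),
    generate_oxygen_trace(0.38325, noise_sd = 1.0, duration = 60, seed = 12),
    generate_oxygen_trace(0.05, noise_sd = 0.2, duration = 99, seed = 13)
  )
  for (tr in cases) {
    est <- best_local_slope(tr)
    oracle <- brute_force_best_window(tr)
    expect_equal(est$window, oracle$window)
    expect_equal(est$slope, oracle$slope, tolerance = 1e-9)
    expect_equal(est$standard_error, oracle$se, tolerance = 1e-9)
  }
})

test_that("a piecewise steep-then-flat trace selects a window in the steep segment", {
  steep <- generate_oxygen_trace(0.7665, duration = 15, noise_sd = 0.1,
                                 seed = 14)  # -20 %/h for 15 min
  flat_part <- generate_oxygen_trace(0.0383, duration = 15, noise_sd = 0.1,
                                     start_saturation =
                                       min(steep$pct_air_saturation),
                                     seed = 15)  # -1 %/h
  flat_part$time_min <- flat_part$time_min + 16
  tr <- rbind(as.data.frame(steep), as.data.frame(flat_part))
  est <- best_local_slope(tr, min_window_fraction = 1/3)
  oracle <- brute_force_best_window(tr, 1/3)
  expect_equal(est$window, oracle$window)
  expect_lte(est$window[2], nrow(steep) + 1L)  # lies in the steep segment
})

test_that("pure sensor noise is flagged unstable in most seeded runs", {
  flagged <- vapply(1:10, function(s) {
    tr <- generate_oxygen_trace(0, noise_sd = 1, duration = 60, seed = s)
    best_local_slope(tr)$unstable
  }, logical(1))
  expect_gte(sum(flagged), 8L)
  # and a genuine signal at similar noise is comfortably stable
  tr <- generate_oxygen_trace(0.38325, noise_sd = 0.3, duration = 60,
                              seed = 1)
  expect_lt(best_local_slope(saturation_filter(tr))$relative_se, 0.05)
})

test_that("control correction subtracts the mean control slope", {
  expect_equal(control_corrected_slope(-10, c(0, 0)), -10)
  expect_equal(control_corrected_slope(-10, -2), -8)
  expect_equal(control_corrected_slope(-5, c(-4, -6)), 0)
  expect_error(control_corrected_slope(-10, numeric(0)), "control")
})

test_that("slope_to_vo2 performs the capacitance-volume unit conversion", {
  expect_equal(slope_to_vo2(-10, 5.11, 750), 0.38325)
  expect_equal(slope_to_vo2(0, 5.11, 750), 0)
  # joint linearity in slope magnitude, capacitance and volume
  expect_equal(slope_to_vo2(-20, 5.11, 750), 2 * slope_to_vo2(-10, 5.11, 750))
  expect_equal(slope_to_vo2(-10, 5.11, 1500), 2 * slope_to_vo2(-10, 5.11, 750))
  expect_equal(slope_to_vo2(-10, 10.22, 750), 2 * slope_to_vo2(-10, 5.11, 750))
  # oxygen gain clamps to zero with a warning
  expect_warning(v <- slope_to_vo2(2, 5.11, 750), "clamped")
  expect_equal(v, 0)
  expect_error(slope_to_vo2(-10, 0, 750), "> 0")
})

test_that("the noise-free pipeline returns the generating VO2", {
  for (vo2 in c(0.05, 0.38325, 1.2)) {
    tr <- generate_oxygen_trace(vo2, volume = 750, capacitance = 5.11,
                                duration = 30, noise_sd = 0, seed = 1)
    ctrl <- generate_oxygen_trace(0, volume = 750, capacitance = 5.11,
                                  duration = 30, noise_sd = 0, seed = 2,
                                  is_control = TRUE)
    out <- trace_to_vo2(tr, list(ctrl))
    expect_true(out$usable)
    expect_equal(out$vo2, vo2, tolerance = 1e-9)
  }
  # drifting controls are corrected out exactly
  tr <- generate_oxygen_trace(0.38325, noise_sd = 0, control_drift = -3,
                              seed = 1)
  ctrl <- generate_oxygen_trace(0, noise_sd = 0, control_drift = -3,
                                seed = 2, is_control = TRUE)
  out <- trace_to_vo2(tr, list(ctrl))
  expect_equal(out$vo2, 0.38325, tolerance = 1e-9)
  # an unusable (too-depleted) chamber reports NA, not an error
  low <- generate_oxygen_trace(0.38325, start_saturation = 60,
                               noise_sd = 0, seed = 1)
  expect_false(trace_to_vo2(low, list(ctrl))$usable)
})

test_that("trace files round-trip through read_traces", {
  tr <- generate_oxygen_trace(0.2, noise_sd = 0.1, seed = 3,
                              chamber_id = "A1")
  ctrl <- generate_oxygen_trace(0, noise_sd = 0.1, seed = 4,
                                chamber_id = "C1", is_control = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rbind(as.data.frame(tr), as.data.frame(ctrl)), path,
                   row.names = FALSE)
  traces <- read_traces(path)
  expect_named(traces, c("A1", "C1"))
  expect_equal(traces$A1$pct_air_saturation, tr$pct_air_saturation)
  expect_true(traces$C1$is_control[1])
})
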