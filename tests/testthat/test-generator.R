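test_that("generated dataset honours the configured dimensions", {
  d <- default_dataset(seed = 1)
  r <- d$records
  expect_equal(nrow(r), 198L)
  expect_equal(length(unique(r$species)), 49L)
  sp <- r[!duplicated(r$species), ]
  expect_equal(sum(sp$thermoregulation == "endotherm"), 21L)
  expect_true(all(r$rate_ul_o2_per_h > 0))
  expect_true(all(r$concentration_sperm_per_ml >= 1e5 &
                    r$concentration_sperm_per_ml <= 1e9))
  # every species maps to exactly one thermoregulation category
  expect_true(all(tapply(r$thermoregulation, r$species,
                         function(x) length(unique(x))) == 1L))
  # allocation rule: floor(198/49) = 4 per species plus 2 remainders
  counts <- table(r$species)
  expect_setequal(as.integer(counts), c(4L, 5L))
  expect_equal(sum(counts == 5L), 2L)
})

test_that("generation is bit-reproducible for a fixed seed and leaves the RNG alone", {
  d1 <- default_dataset(seed = 7)
  d2 <- default_dataset(seed = 7)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$truth$species_effects, d2$truth$species_effects)
  set.seed(123)
  before <- .Random.seed
  invisible(default_dataset(seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("noise-free degenerate config collapses onto the exact power law", {
  d <- generate_metabolic_dataset(generator_config(
    species_sd = 0, residual_sd = 0, endotherm_multiplier = 1, seed = 3))
  r <- d$records
  cfg <- d$truth$config
  resid <- log(r$rate_ul_o2_per_h) -
    cfg$beta * log(r$concentration_sperm_per_ml)
  expect_equal(resid, rep(cfg$base_coefficient, nrow(r)), tolerance = 1e-10)
  # per-capita rate then has exact log-log slope beta - 1
  pcr <- per_capita_rate(r)
  fit <- stats::lm(log(pcr) ~ log(r$concentration_sperm_per_ml))
  expect_equal(unname(coef(fit)[2]), cfg$beta - 1, tolerance = 1e-10)
})

test_that("pooled OLS recovers the generative exponent on a default dataset", {
  d <- default_dataset(seed = 1)
  slope <- unname(coef(pooled_ols(d$records))[2])
  expect_lt(abs(slope - 0.87), 0.05)
})

test_that("invalid configurations name the offending field", {
  expect_error(generator_config(seed = 1, obs_total = 10, n_species = 49),
               "obs_total")
  expect_error(generator_config(seed = 1, species_sd = -1), "species_sd")
  expect_error(generator_config(seed = 1, log10_conc_range = c(9, 5)),
               "log10_conc_range")
  expect_error(generator_config(seed = 1, n_endotherm = 60), "n_endotherm")
  expect_error(generator_config(), "seed")
})

test_that("standardized reports apply the linear transformation and invert exactly", {
  d <- default_dataset(seed = 2)
  rep_all <- generate_standardized_reports(d, std_concentration = 1e8,
                                           fraction_standardized = 1,
                                           seed = 2)
  expect_true(all(rep_all$reporting == "standardized"))
  expect_equal(rep_all$rate_ul_o2_per_h,
               d$records$rate_ul_o2_per_h * 1e8 /
                 d$records$concentration_sperm_per_ml)
  # round trip through back-calculation restores the originals
  restored <- back_calculate_actual_rate(
    rep_all$rate_ul_o2_per_h,
    rep_all$std_concentration_sperm_per_ml,
    rep_all$concentration_sperm_per_ml)
  expect_equal(restored, d$records$rate_ul_o2_per_h, tolerance = 1e-12)

  # the worked example: 4.02 measured at 3e8 reported standardized at 1e8
  one <- d$records[1, ]
  one$rate_ul_o2_per_h <- 4.02
  one$concentration_sperm_per_ml <- 3e8
  std <- generate_standardized_reports(one, std_concentration = 1e8,
                                       fraction_standardized = 1, seed = 1)
  expect_equal(std$rate_ul_o2_per_h, 1.34)

  # a record measured exactly at the standard concentration is unchanged
  one$concentration_sperm_per_ml <- 1e8
  std2 <- generate_standardized_reports(one, std_concentration = 1e8,
                                        fraction_standardized = 1, seed = 1)
  expect_equal(std2$rate_ul_o2_per_h, 4.02)

  # fraction 0 is the identity
  expect_identical(
    generate_standardized_reports(d, fraction_standardized = 0, seed = 1),
    d$records)
  # empty input passes through
  expect_equal(nrow(generate_standardized_reports(d$records[0, ],
                                                  fraction_standardized = 1,
                                                  seed = 1)), 0L)
})

test_that("oxygen traces decline at the unit-converted rate", {
  # hand conversion: 0.38325 / (5.11 * 0.75) * 100 = 10 % AS per hour
  tr <- generate_oxygen_trace(0.38325, volume = 750, capacitance = 5.11,
                              noise_sd = 0, control_drift = 0, seed = 1)
  slopes <- diff(tr$pct_air_saturation) / diff(tr$time_min / 60)
  expect_equal(slopes, rep(-10, length(slopes)), tolerance = 1e-9)
  expect_equal(attr(tr, "true_slope"), -10)

  # zero consumption, zero drift: flat at the start saturation
  flat <- generate_oxygen_trace(0, noise_sd = 0, seed = 1)
  expect_equal(flat$pct_air_saturation, rep(100, nrow(flat)))

  # parameters implying full depletion within one interval are rejected
  expect_error(generate_oxygen_trace(1e5, volume = 750, interval = 1),
               "depleted")
})

test_that("a trace that starts below the window is rejected downstream", {
  tr <- generate_oxygen_trace(0.38325, start_saturation = 60, noise_sd = 0,
                              seed = 1)
  expect_equal(nrow(saturation_filter(tr, 100, 75)), 0L)
})
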