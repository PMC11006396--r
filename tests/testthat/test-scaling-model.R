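test_that("near-degenerate data recovers the generative exponent almost exactly", {
  d <- generate_metabolic_dataset(generator_config(
    species_sd = 0, residual_sd = 1e-8, endotherm_multiplier = 1, seed = 1))
  fit <- fit_scaling_model(d, model_spec(covariate = "none"))
  expect_equal(fit$beta, 0.87, tolerance = 1e-6)
})

test_that("a single-species dataset falls back to ordinary least squares", {
  d <- generate_metabolic_dataset(generator_config(
    n_species = 1, n_endotherm = 0, obs_total = 30, seed = 2))
  fit <- fit_scaling_model(d, model_spec(covariate = "none"))
  ols <- pooled_ols(d$records)
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$beta_se, summary(ols)$coefficients[2, 2],
               tolerance = 1e-10)
  expect_true(fit$boundary)
  expect_equal(fit$species_variance, 0)
})

test_that("a species variance estimated at its boundary reduces to pooled OLS", {
  # with no species heterogeneity in truth the variance estimate often (not
  # always) lands exactly at 0; whenever it does, the fixed effects must
  # match the pooled least-squares fit
  hits <- 0L
  for (s in 1:8) {
    d <- generate_metabolic_dataset(generator_config(
      species_sd = 0, residual_sd = 0.5, seed = s))
    fit <- fit_scaling_model(d, model_spec(covariate = "thermoregulation"))
    if (fit$boundary) {
      hits <- hits + 1L
      expect_equal(fit$species_variance, 0)
      ols <- pooled_ols(d$records, covariate = "thermoregulation")
      expect_lt(abs(fit$beta - unname(coef(ols)[2])), 1e-6)
      expect_lt(abs(fit$covariate_effect - unname(coef(ols)[3])), 1e-6)
    }
  }
  expect_gte(hits, 1L)
})

test_that("the exponent is invariant to the concentration unit", {
  d <- default_dataset(seed = 4)
  fit1 <- fit_scaling_model(d, model_spec(covariate = "thermoregulation"))
  scaled <- d$records
  scaled$concentration_sperm_per_ml <-
    scaled$concentration_sperm_per_ml * 1e3  # sperm per litre
  fit2 <- fit_scaling_model(scaled,
                            model_spec(covariate = "thermoregulation"))
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
  expect_equal(fit1$beta_se, fit2$beta_se, tolerance = 1e-6)
})

test_that("per-capita and ejaculate-level fits are linked by exactly -1", {
  d <- default_dataset(seed = 5)
  ej <- fit_scaling_model(d, model_spec(response = "ejaculate_rate",
                                        covariate = "thermoregulation"))
  pc <- fit_scaling_model(d, model_spec(response = "per_capita_rate",
                                        covariate = "thermoregulation"))
  expect_lt(abs(pc$beta - (ej$beta - 1)), 1e-10)
  expect_lt(abs(pc$beta_se - ej$beta_se), 1e-10)
  expect_equal(per_capita_exponent(ej)$exponent, ej$beta - 1)
  expect_equal(per_capita_exponent(0.87)$exponent, -0.13)
  expect_equal(per_capita_exponent(1.0)$exponent, 0)
  expect_error(per_capita_exponent(pc), "ejaculate-level")
})

test_that("standardized-only records are excluded from the fit, with count", {
  d <- default_dataset(seed = 6)
  r <- d$records
  r$reporting[1:5] <- "standardized"
  r$std_concentration_sperm_per_ml[1:5] <- 1e8
  fit <- fit_scaling_model(r, model_spec(covariate = "thermoregulation"))
  expect_equal(fit$n_obs, nrow(r) - 5L)
  expect_equal(fit$n_excluded, 5L)
})

test_that("a single-level covariate raises a singular-design error", {
  d <- generate_metabolic_dataset(generator_config(
    n_endotherm = 0, seed = 7))
  expect_error(
    fit_scaling_model(d, model_spec(covariate = "thermoregulation")),
    "singular design")
})

test_that("model reduction drops a null interaction at close to the nominal rate", {
  dropped <- vapply(1:150, function(s) {
    d <- default_dataset(seed = s)
    fit <- model_reduction(d, model_spec(covariate = "thermoregulation",
                                         include_interaction = TRUE))
    !fit$reduction$interaction_retained
  }, logical(1))
  expect_gte(mean(dropped), 0.9)
})

test_that("model reduction retains a real interaction and honours alpha = 1", {
  retained <- vapply(1:10, function(s) {
    d <- generate_metabolic_dataset(generator_config(
      interaction_effect = 0.3, seed = s))
    fit <- model_reduction(d, model_spec(covariate = "thermoregulation",
                                         include_interaction = TRUE))
    fit$reduction$interaction_retained
  }, logical(1))
  expect_gt(mean(retained), 0.5)
  # alpha = 1 always keeps the full model
  d <- default_dataset(seed = 1)
  fit <- model_reduction(d, model_spec(covariate = "thermoregulation",
                                       include_interaction = TRUE),
                         alpha = 1)
  expect_true(fit$reduction$interaction_retained)
  expect_false(is.na(fit$interaction_effect))
})

test_that("the reduced model never out-likelihoods the full model under ML", {
  worse <- vapply(1:25, function(s) {
    d <- default_dataset(seed = 100 + s)
    fit <- model_reduction(d, model_spec(covariate = "thermoregulation",
                                         include_interaction = TRUE))
    fit$reduction$full_loglik + 1e-6 >= fit$reduction$reduced_loglik
  }, logical(1))
  expect_true(all(worse))
})

test_that("Wald test matches the t distribution and its trivial limits", {
  # worked example at the printed precision
  w <- wald_test(0.87, beta_se = 0.04, df = 198)
  expect_equal(abs(w$t_statistic), 3.25)
  expect_equal(w$p_value, 2 * stats::pt(-3.25, 198))
  expect_equal(round(w$p_value, 3), 0.001)
  # beta equal to the null
  w0 <- wald_test(1.0, beta_se = 0.05, df = 100)
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_value, 1)
  # t-distribution CDF oracle
  w2 <- wald_test(0.90, beta_se = 0.05, df = 100)
  expect_equal(w2$t_statistic, -2)
  expect_equal(w2$p_value, 0.0482, tolerance = 1e-3)
  expect_error(wald_test(0.9, beta_se = 0, df = 10), "beta_se")
  # fit method uses residual-df convention
  d <- default_dataset(seed = 8)
  fit <- fit_scaling_model(d, model_spec(covariate = "thermoregulation"))
  wf <- wald_test(fit)
  expect_equal(wf$df, fit$n_obs - fit$n_fixed)
  expect_equal(wf$t_statistic, (fit$beta - 1) / fit$beta_se)
})

test_that("exponent recovery is unbiased with honest Wald interval coverage", {
  fits <- lapply(1:100, function(s) {
    fit_scaling_model(default_dataset(seed = 200 + s),
                      model_spec(covariate = "thermoregulation"))
  })
  betas <- vapply(fits, `[[`, numeric(1), "beta")
  ses <- vapply(fits, `[[`, numeric(1), "beta_se")
  expect_lt(abs(mean(betas) - 0.87), 0.02)
  dfs <- vapply(fits, function(f) f$n_obs - f$n_fixed, numeric(1))
  crit <- stats::qt(0.975, dfs)
  covered <- abs(betas - 0.87) <= crit * ses
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
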