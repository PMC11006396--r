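#' Specify a density-metabolism scaling model
#'
#' The core model regresses log metabolic rate on log sperm concentration
#' with a species random intercept:
#' \deqn{\ln R_{is} = \ln a + \beta \ln C_{is} + \gamma x_s (+ \theta x_s
#'   \ln C_{is}) + u_s + \varepsilon_{is},}
#' where \eqn{x_s} is an optional species-level or record-level covariate
#' (thermoregulation, diluent or fertilization mode), \eqn{u_s} a species
#' random intercept and all quantities are on the natural-log scale. With
#' the ejaculate-level response, \eqn{\beta} is the density-metabolism
#' exponent; the per-capita exponent is \eqn{\beta - 1}.
#'
#' @param response `"ejaculate_rate"` (ln rate) or `"per_capita_rate"`
#'   (ln rate per spermatozoon; shifts the concentration slope by exactly
#'   -1 under constant assay volume).
#' @param covariate `"thermoregulation"`, `"diluent"`,
#'   `"fertilization_mode"` or `"none"`. Reference levels are ectotherm,
#'   carbohydrate-free and external respectively, so the fitted offset is
#'   the ln fold-difference of the non-reference group.
#' @param include_interaction include the covariate-by-ln-concentration
#'   interaction (requires a covariate).
#' @param estimation `"REML"` (reported fits) or `"ML"` (likelihood-ratio
#'   and AIC comparisons).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response = c("ejaculate_rate", "per_capita_rate"),
                       covariate = c("thermoregulation", "diluent",
                                     "fertilization_mode", "none"),
                       include_interaction = FALSE,
                       estimation = c("REML", "ML")) {
  response <- match.arg(response)
  covariate <- match.arg(covariate)
  estimation <- match.arg(estimation)
  if (include_interaction && covariate == "none") {
    stop("an interaction requires a covariate", call. = FALSE)
  }
  structure(list(response = response, covariate = covariate,
                 include_interaction = include_interaction,
                 estimation = estimation),
            class = "model_spec")
}

covariate_reference <- c(thermoregulation = "ectotherm",
                         diluent = "carbohydrate_free",
                         fertilization_mode = "external")

# Assemble the ln-scale model frame from a record table.
build_model_frame <- function(records, spec, default_volume_ml = 1) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  keep <- records$reporting == "actual" & fit_eligible(records)
  n_excluded <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop("no fit-eligible records (reporting = actual with known ",
         "concentration); harmonize_records() first?", call. = FALSE)
  }
  resp <- if (spec$response == "per_capita_rate") {
    log(per_capita_rate(records, default_volume_ml))
  } else {
    log(records$rate_ul_o2_per_h)
  }
  mf <- data.frame(ln_rate = resp,
                   ln_conc = log(records$concentration_sperm_per_ml),
                   species = factor(records$species),
                   stringsAsFactors = FALSE)
  if (spec$covariate != "none") {
    lev <- record_vocab[[spec$covariate]]
    ref <- covariate_reference[[spec$covariate]]
    mf$covariate <- factor(records[[spec$covariate]],
                           levels = c(ref, setdiff(lev, ref)))
    if (nlevels(droplevels(mf$covariate)) < 2L) {
      stop("covariate '", spec$covariate, "' has a single level in the ",
           "fitting data: singular design", call. = FALSE)
    }
  }
  attr(mf, "n_excluded") <- n_excluded
  mf
}

#' Fit the log-log density-metabolism mixed model
#'
#' Fits \eqn{\ln(\mathrm{rate}) \sim \ln(\mathrm{concentration})} plus an
#' optional covariate (and interaction) with a species random intercept,
#' via [lme4::lmer()]. Only records with `reporting = "actual"` and a known
#' measured concentration enter the fit (standardized-only reports are
#' excluded, with the count recorded). A dataset with fewer than two
#' species cannot identify a between-species variance; it falls back to
#' ordinary least squares with the species variance fixed at zero and is
#' flagged.
#'
#' @param records a record table (or `synthetic_dataset`).
#' @param spec a [model_spec()].
#' @param default_volume_ml assay volume assumed for the per-capita
#'   response when unreported.
#' @return object of class `scaling_fit`: a list with elements `beta`,
#'   `beta_se` (concentration exponent and SE), `intercept`,
#'   `covariate_effect`, `covariate_se`, `interaction_effect`,
#'   `interaction_se`, `species_variance`, `residual_variance`, `loglik`,
#'   `aic`, `n_obs`, `n_species`, `n_fixed`, `n_excluded`, `converged`,
#'   `boundary` (species variance estimated at 0), `spec` and the
#'   underlying `model`. `aic = 2k - 2 loglik` with `k = n_fixed` plus the
#'   number of variance parameters (2).
#' @examples
#' d <- generate_metabolic_dataset(generator_config(seed = 1))
#' fit <- fit_scaling_model(d, model_spec(covariate = "thermoregulation"))
#' fit$beta            # close to the generative 0.87
#' exp(fit$covariate_effect)  # close to the generative 2-fold offset
#' @export
fit_scaling_model <- function(records, spec = model_spec(),
                              default_volume_ml = 1) {
  stopifnot(inherits(spec, "model_spec"))
  mf <- build_model_frame(records, spec, default_volume_ml)
  n_species <- nlevels(droplevels(mf$species))
  fixed_rhs <- "ln_conc"
  if (spec$covariate != "none") {
    fixed_rhs <- paste(fixed_rhs,
                       if (spec$include_interaction) "* covariate"
                       else "+ covariate")
  }
  reml <- spec$estimation == "REML"

  if (n_species < 2L) {
    fit0 <- stats::lm(stats::as.formula(paste("ln_rate ~", fixed_rhs)),
                      data = mf)
    cf <- summary(fit0)$coefficients
    res <- extract_fit(cf, spec,
                       species_variance = 0,
                       residual_variance = summary(fit0)$sigma^2,
                       loglik = as.numeric(stats::logLik(fit0)),
                       n_obs = nrow(mf), n_species = n_species,
                       converged = TRUE, boundary = TRUE, model = fit0)
    res$n_excluded <- attr(mf, "n_excluded")
    return(res)
  }

  form <- stats::as.formula(
    paste("ln_rate ~", fixed_rhs, "+ (1 | species)"))
  fit0 <- lme4::lmer(form, data = mf, REML = reml,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular =
                                                   "ignore"))
  vc <- lme4::VarCorr(fit0)
  cf <- stats::coef(summary(fit0))
  conv_msgs <- fit0@optinfo$conv$lme4$messages
  res <- extract_fit(
    cf, spec,
    species_variance = as.numeric(vc$species[1, 1]),
    residual_variance = stats::sigma(fit0)^2,
    loglik = as.numeric(stats::logLik(fit0)),
    n_obs = nrow(mf), n_species = n_species,
    converged = is.null(conv_msgs) || length(conv_msgs) == 0L,
    boundary = lme4::isSingular(fit0), model = fit0
  )
  res$n_excluded <- attr(mf, "n_excluded")
  res
}

# Shared coefficient extraction for lmer and the single-species lm path.
extract_fit <- function(cf, spec, species_variance, residual_variance,
                        loglik, n_obs, n_species, converged, boundary,
                        model) {
  rn <- rownames(cf)
  pick <- function(pattern) {
    i <- grep(pattern, rn)
    if (length(i) == 1L) c(cf[i, 1], cf[i, 2]) else c(NA_real_, NA_real_)
  }
  beta <- pick("^ln_conc$")
  cov_eff <- pick("^covariate")
  # the interaction row is "ln_conc:covariate<level>"
  inter <- pick("^ln_conc:covariate")
  n_fixed <- nrow(cf)
  k <- n_fixed + 2L  # fixed effects + species variance + residual variance
  structure(
    list(beta = unname(beta[1]), beta_se = unname(beta[2]),
         intercept = unname(cf[1, 1]), intercept_se = unname(cf[1, 2]),
         covariate_effect = unname(cov_eff[1]),
         covariate_se = unname(cov_eff[2]),
         interaction_effect = unname(inter[1]),
         interaction_se = unname(inter[2]),
         species_variance = species_variance,
         residual_variance = residual_variance,
         loglik = loglik, aic = 2 * k - 2 * loglik,
         n_obs = n_obs, n_species = n_species, n_fixed = n_fixed,
         converged = converged, boundary = boundary,
         spec = spec, model = model),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Density-metabolism scaling fit (", x$spec$response, ", ",
      x$spec$estimation, ")\n", sep = "")
  cat(sprintf("  exponent beta = %.4f (SE %.4f)\n", x$beta, x$beta_se))
  if (!is.na(x$covariate_effect)) {
    cat(sprintf("  %s effect = %.4f (SE %.4f), fold = %.3f\n",
                x$spec$covariate, x$covariate_effect, x$covariate_se,
                exp(x$covariate_effect)))
  }
  if (!is.na(x$interaction_effect)) {
    cat(sprintf("  interaction = %.4f (SE %.4f)\n",
                x$interaction_effect, x$interaction_se))
  }
  cat(sprintf("  species var = %.4f, residual var = %.4f\n",
              x$species_variance, x$residual_variance))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, n = %d obs / %d species%s%s\n",
              x$loglik, x$aic, x$n_obs, x$n_species,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$boundary) " [variance at boundary]" else ""))
  invisible(x)
}

#' Likelihood-ratio model reduction for the interaction term
#'
#' Implements the multistep reduction: fit the full model (with the
#' covariate-by-concentration interaction) and the reduced model (without)
#' under maximum likelihood, compare them by a likelihood-ratio chi-square
#' on 1 degree of freedom and by AIC, retain the interaction only when
#' `p <= alpha`, and refit the selected structure under the spec's final
#' estimation mode. The comparison trail (chi-square, p, delta-AIC,
#' decision) is attached to the returned fit as `reduction`.
#'
#' @param records a record table (or `synthetic_dataset`).
#' @param spec a [model_spec()] with `include_interaction = TRUE`.
#' @param alpha retention threshold for the interaction p-value.
#' @param default_volume_ml see [fit_scaling_model()].
#' @return the selected `scaling_fit` with a `reduction` element:
#'   list(`chisq`, `df`, `p_value`, `delta_aic`, `interaction_retained`).
#' @export
model_reduction <- function(records, spec, alpha = 0.05,
                            default_volume_ml = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$include_interaction) {
    stop("model_reduction requires a spec with include_interaction = TRUE",
         call. = FALSE)
  }
  ml_spec_full <- spec; ml_spec_full$estimation <- "ML"
  ml_spec_red <- ml_spec_full; ml_spec_red$include_interaction <- FALSE
  full <- fit_scaling_model(records, ml_spec_full, default_volume_ml)
  red <- fit_scaling_model(records, ml_spec_red, default_volume_ml)
  chisq <- 2 * (full$loglik - red$loglik)
  p <- stats::pchisq(max(chisq, 0), df = 1, lower.tail = FALSE)
  delta_aic <- red$aic - full$aic
  retain <- p <= alpha
  final_spec <- spec
  final_spec$include_interaction <- retain
  out <- fit_scaling_model(records, final_spec, default_volume_ml)
  out$reduction <- list(chisq = chisq, df = 1L, p_value = p,
                        delta_aic = delta_aic,
                        interaction_retained = retain,
                        full_loglik = full$loglik,
                        reduced_loglik = red$loglik)
  out
}

#' Wald test of the scaling exponent against a null value
#'
#' Tests whether the fitted concentration exponent differs from a null
#' value, canonically 1: the exponent a linear (density-independent
#' per-capita) world would produce. `t = (beta - null) / SE(beta)` is
#' referred to a t distribution.
#'
#' For a `scaling_fit` the degrees of freedom default to
#' `n_obs - n_fixed` (a residual-df convention, documented rather than
#' derived). The numeric method takes the estimate, its standard error and
#' the degrees of freedom explicitly, e.g.
#' `wald_test(0.87, 0.04, df = 198)` gives |t| = 3.25, p = 0.001.
#'
#' @param fit a `scaling_fit`, or (numeric method) the exponent estimate.
#' @param null_value null exponent (default 1).
#' @param ... method arguments: for the numeric method, `beta_se` and `df`.
#' @return object of class `wald_result`: list(`t_statistic`, `df`,
#'   `p_value`, `null_value`, `estimate`, `se`).
#' @examples
#' w <- wald_test(0.87, beta_se = 0.04, df = 198)
#' abs(w$t_statistic)  # 3.25
#' round(w$p_value, 3) # 0.001
#' @export
wald_test <- function(fit, null_value = 1, ...) UseMethod("wald_test")

#' @rdname wald_test
#' @export
wald_test.scaling_fit <- function(fit, null_value = 1, ...) {
  if (!isTRUE(fit$converged)) {
    stop("wald_test: fit did not converge", call. = FALSE)
  }
  wald_test.numeric(fit$beta, null_value = null_value,
                    beta_se = fit$beta_se, df = fit$n_obs - fit$n_fixed)
}

#' @rdname wald_test
#' @param beta_se standard error of the estimate (numeric method).
#' @param df degrees of freedom (numeric method).
#' @export
wald_test.numeric <- function(fit, null_value = 1, beta_se, df, ...) {
  if (!is.numeric(beta_se) || beta_se <= 0) {
    stop("wald_test: beta_se must be > 0", call. = FALSE)
  }
  t_stat <- (fit - null_value) / beta_se
  structure(
    list(t_statistic = t_stat, df = df,
         p_value = 2 * stats::pt(-abs(t_stat), df = df),
         null_value = null_value, estimate = fit, se = beta_se),
    class = "wald_result"
  )
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald test vs %g: t_%g = %.3f, p = %.4g (estimate %.4f, SE %.4f)\n",
              x$null_value, x$df, x$t_statistic, x$p_value,
              x$estimate, x$se))
  invisible(x)
}

#' Per-capita scaling exponent from an ejaculate-level fit
#'
#' The per-capita rate is the ejaculate rate divided by sperm count, so on
#' log-log axes its concentration exponent is the ejaculate-level exponent
#' minus one — an exact algebraic identity (constant volume), with the
#' standard error unchanged. An ejaculate exponent of 0.87 is a per-capita
#' exponent of -0.13: dilution raises per-capita metabolism.
#'
#' @param fit a `scaling_fit` on the ejaculate-level response, or a numeric
#'   ejaculate-level exponent.
#' @return list with `exponent` (beta - 1) and `se` (carried over; `NA` for
#'   bare numeric input without a fit).
#' @export
per_capita_exponent <- function(fit) {
  if (inherits(fit, "scaling_fit")) {
    if (fit$spec$response != "ejaculate_rate") {
      stop("per_capita_exponent expects an ejaculate-level fit",
           call. = FALSE)
    }
    list(exponent = fit$beta - 1, se = fit$beta_se)
  } else {
    list(exponent = as.numeric(fit) - 1, se = NA_real_)
  }
}
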