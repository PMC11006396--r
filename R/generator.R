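#' Configuration for the synthetic metabolic-record generator
#'
#' Parameterizes the generative model used throughout the package's tests and
#' simulations:
#' \deqn{\ln R = \ln a + \beta \ln C + \gamma\,[\mathrm{endotherm}] +
#'   \delta\,[\mathrm{carb.\ diluent}] + \theta\,[\mathrm{endotherm}]\ln C +
#'   u_s + \varepsilon,}
#' where \eqn{R} is ejaculate-level oxygen consumption (µl O2 h^-1), \eqn{C}
#' sperm concentration (sperm ml^-1), \eqn{u_s \sim N(0,
#' \code{species_sd}^2)} a species random intercept and \eqn{\varepsilon \sim
#' N(0, \code{residual_sd}^2)} multiplicative (lognormal) noise. The defaults
#' mirror the structure of the published compilation this model emulates: 198
#' observations over 49 species (21 endotherms), concentrations spanning
#' about six orders of magnitude, an ejaculate-level density-metabolism
#' exponent of 0.87 and a 2-fold endotherm rate offset.
#'
#' @param n_species number of species.
#' @param n_endotherm number of endothermic species (the rest are
#'   ectotherms; endotherms are modelled as internal fertilizers, ectotherms
#'   as external).
#' @param obs_total total number of observations, allocated as
#'   `floor(obs_total / n_species)` per species with the remainder given to
#'   the first species in seeded random order.
#' @param beta ejaculate-level density-metabolism exponent (slope of
#'   \eqn{\ln R} on \eqn{\ln C}); the per-capita exponent is `beta - 1`.
#' @param endotherm_multiplier fold-difference in rate between endotherm and
#'   ectotherm sperm at equal concentration; enters the linear predictor as
#'   \eqn{\gamma = \ln(\mathrm{endotherm\_multiplier})}.
#' @param base_coefficient grand intercept \eqn{\ln a} on the natural-log
#'   scale. The default (`NULL`) sets \eqn{\ln a = -\beta \ln 10^8} so that
#'   an ectotherm sample at 10^8 sperm ml^-1 respires 1 µl O2 h^-1 in
#'   expectation, keeping rates in a plausible range.
#' @param species_sd standard deviation of species random intercepts
#'   (natural-log scale).
#' @param residual_sd residual standard deviation (natural-log scale).
#' @param log10_conc_range length-2 increasing vector; concentrations are
#'   drawn log-uniformly over this log10 range (sperm ml^-1).
#' @param diluent_effect ln-scale rate offset for carbohydrate-containing
#'   diluent (default 0, the no-resource-effect null).
#' @param interaction_effect ln-scale modifier of the concentration slope
#'   for endotherms (thermoregulation-by-concentration interaction; default
#'   0, the common-slope null).
#' @param prop_carb_diluent probability that a record used a
#'   carbohydrate-containing diluent (default 50/198, the compilation's
#'   diluent mix).
#' @param seed integer seed; required. Generation uses R's Mersenne-Twister
#'   RNG via [set.seed()] and is bit-reproducible for a fixed seed.
#' @return A list of class `generator_config`.
#' @seealso [generate_metabolic_dataset()]
#' @export
generator_config <- function(n_species = 49L,
                             n_endotherm = 21L,
                             obs_total = 198L,
                             beta = 0.87,
                             endotherm_multiplier = 2.0,
                             base_coefficient = NULL,
                             species_sd = 1.0,
                             residual_sd = 0.5,
                             log10_conc_range = c(5, 9),
                             diluent_effect = 0,
                             interaction_effect = 0,
                             prop_carb_diluent = 50 / 198,
                             seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("generator_config: 'seed' must be a single integer", call. = FALSE)
  }
  bad <- function(field, msg) {
    stop(sprintf("generator_config: invalid '%s': %s", field, msg),
         call. = FALSE)
  }
  if (n_species < 1L) bad("n_species", "must be >= 1")
  if (n_endotherm < 0L || n_endotherm > n_species) {
    bad("n_endotherm", "must be between 0 and n_species")
  }
  if (obs_total < n_species) bad("obs_total", "must be >= n_species")
  if (species_sd < 0) bad("species_sd", "must be >= 0")
  if (residual_sd < 0) bad("residual_sd", "must be >= 0")
  if (length(log10_conc_range) != 2L ||
      !(log10_conc_range[2] > log10_conc_range[1])) {
    bad("log10_conc_range", "must be an increasing pair")
  }
  if (endotherm_multiplier <= 0) bad("endotherm_multiplier", "must be > 0")
  if (prop_carb_diluent < 0 || prop_carb_diluent > 1) {
    bad("prop_carb_diluent", "must be in [0, 1]")
  }
  if (is.null(base_coefficient)) {
    base_coefficient <- -beta * log(1e8)
  }
  structure(
    list(n_species = as.integer(n_species),
         n_endotherm = as.integer(n_endotherm),
         obs_total = as.integer(obs_total),
         beta = beta,
         endotherm_multiplier = endotherm_multiplier,
         base_coefficient = base_coefficient,
         species_sd = species_sd,
         residual_sd = residual_sd,
         log10_conc_range = as.numeric(log10_conc_range),
         diluent_effect = diluent_effect,
         interaction_effect = interaction_effect,
         prop_carb_diluent = prop_carb_diluent,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Run code with a private RNG state so generators do not disturb the
# caller's random stream.
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a synthetic sperm metabolic-rate dataset
#'
#' Draws a dataset with the statistical structure the scaling analysis
#' assumes: a log-log power-law mean, a species-level random intercept, a
#' thermoregulation offset and lognormal noise (see [generator_config()] for
#' the model). Observations are allocated `floor(obs_total / n_species)` per
#' species, with the remainder going to the first species in seeded random
#' order; concentrations are drawn log-uniformly over `log10_conc_range`.
#'
#' @param config a [generator_config()].
#' @return An object of class `synthetic_dataset`: a list with
#'   * `records`: a data.frame in the package's record schema (see
#'     [read_records()]), all rows `reporting = "actual"`;
#'   * `truth`: the config plus the realized species intercepts
#'     (`species_effects`, named ln-scale offsets).
#' @examples
#' d <- generate_metabolic_dataset(generator_config(seed = 1))
#' nrow(d$records)        # 198
#' table(d$records$thermoregulation[!duplicated(d$records$species)])
#' @export
generate_metabolic_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("'config' must be a generator_config object", call. = FALSE)
  }
  with_private_seed(config$seed, {
    ns <- config$n_species
    species <- sprintf("species_%02d", seq_len(ns))
    thermo <- rep(c("endotherm", "ectotherm"),
                  c(config$n_endotherm, ns - config$n_endotherm))
    # allocation: fixed base per species, remainder to first species in
    # seeded order (draw order: allocation, concentrations, species effects,
    # residuals, diluent)
    base_n <- config$obs_total %/% ns
    extra <- config$obs_total - base_n * ns
    n_obs <- rep(base_n, ns)
    seeded_order <- sample.int(ns)
    if (extra > 0L) {
      n_obs[seeded_order[seq_len(extra)]] <- base_n + 1L
    }
    idx <- rep(seq_len(ns), n_obs)

    n <- config$obs_total
    log10_conc <- stats::runif(n, config$log10_conc_range[1],
                               config$log10_conc_range[2])
    conc <- 10^log10_conc
    u <- stats::rnorm(ns, 0, config$species_sd)
    names(u) <- species
    eps <- stats::rnorm(n, 0, config$residual_sd)
    carb <- stats::rbinom(n, 1L, config$prop_carb_diluent)

    endo <- as.integer(thermo[idx] == "endotherm")
    ln_rate <- config$base_coefficient +
      config$beta * log(conc) +
      log(config$endotherm_multiplier) * endo +
      config$diluent_effect * carb +
      config$interaction_effect * endo * log(conc) +
      u[idx] + eps

    records <- data.frame(
      species = species[idx],
      thermoregulation = thermo[idx],
      fertilization_mode = ifelse(endo == 1L, "internal", "external"),
      diluent = ifelse(carb == 1L, "carbohydrate_containing",
                       "carbohydrate_free"),
      diluent_job = "unknown",
      handling = "fresh",
      concentration_sperm_per_ml = conc,
      rate_ul_o2_per_h = exp(ln_rate),
      reporting = "actual",
      std_concentration_sperm_per_ml = NA_real_,
      assay_volume_ml = NA_real_,
      n_replicates = NA_integer_,
      source = "synthetic",
      stringsAsFactors = FALSE
    )
    structure(
      list(records = records,
           truth = list(config = config, species_effects = u)),
      class = "synthetic_dataset"
    )
  })
}

#' Apply linear standardization to a fraction of synthetic records
#'
#' Emulates the dominant reporting convention in the sperm-metabolism
#' literature: rates measured at concentration \eqn{C} are linearly rescaled
#' to a standard concentration \eqn{C_{std}} as
#' \eqn{Z = R \cdot C_{std} / C}, which silently assumes no density
#' dependence. Selected records get `rate_ul_o2_per_h` replaced by the
#' standardized value, `reporting = "standardized"` and
#' `std_concentration_sperm_per_ml` set; the measured concentration is
#' retained, so [back_calculate_actual_rate()] inverts the transformation
#' exactly.
#'
#' @param dataset a `synthetic_dataset` or a record data.frame.
#' @param std_concentration the standard concentration (sperm ml^-1), > 0.
#' @param fraction_standardized proportion of records to standardize, in
#'   \[0, 1\]. The subset is drawn uniformly at random under `seed`.
#' @param seed integer seed for the record selection.
#' @return the records data.frame with the selected rows standardized.
#' @export
generate_standardized_reports <- function(dataset, std_concentration = 1e8,
                                          fraction_standardized = 1,
                                          seed = 1L) {
  records <- if (inherits(dataset, "synthetic_dataset")) {
    dataset$records
  } else {
    dataset
  }
  stopifnot(is.data.frame(records))
  if (!is.numeric(std_concentration) || std_concentration <= 0) {
    stop("'std_concentration' must be > 0", call. = FALSE)
  }
  if (fraction_standardized < 0 || fraction_standardized > 1) {
    stop("'fraction_standardized' must be in [0, 1]", call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0L) return(records)
  with_private_seed(seed, {
    k <- round(fraction_standardized * n)
    sel <- if (k > 0L) sort(sample.int(n, k)) else integer(0)
    if (length(sel)) {
      records$rate_ul_o2_per_h[sel] <- records$rate_ul_o2_per_h[sel] *
        std_concentration / records$concentration_sperm_per_ml[sel]
      records$reporting[sel] <- "standardized"
      records$std_concentration_sperm_per_ml[sel] <- std_concentration
    }
    records
  })
}

#' Simulate a closed-chamber oxygen-saturation trace
#'
#' Generates the percent-air-saturation time series a sensor-dish
#' respirometry chamber would record for a sample with a known oxygen
#' consumption rate. Saturation declines linearly at
#' \eqn{100 \cdot \dot{V}_{O_2} / (\kappa V)} percent air saturation per
#' hour, where \eqn{\kappa} is the oxygen capacitance of the medium
#' (ml O2 l^-1, numerically µl O2 per ml water) and \eqn{V} the chamber
#' water volume in ml, plus any background drift, Gaussian sensor noise,
#' and a floor at 0% AS.
#'
#' @param true_vo2 oxygen consumption rate, µl O2 h^-1 (>= 0).
#' @param volume chamber water volume, µl.
#' @param capacitance oxygen capacitance of air-saturated medium,
#'   ml O2 l^-1 (5.11 for seawater at 21°C).
#' @param start_saturation initial saturation, % AS, in (0, 100].
#' @param duration trace length, minutes.
#' @param interval sampling interval, minutes.
#' @param noise_sd Gaussian sensor noise SD, % AS.
#' @param control_drift background drift, % AS h^-1 (applies to controls and
#'   samples alike; negative = background consumption).
#' @param seed integer seed for the noise draws.
#' @param chamber_id chamber label.
#' @param is_control logical; flag the trace as a sperm-free control.
#' @return A data.frame of class `oxygen_trace` with columns `chamber_id`,
#'   `time_min`, `pct_air_saturation`, `is_control`. The noise-free decline
#'   rate (% AS h^-1, drift included) is attached as attribute
#'   `true_slope`.
#' @export
generate_oxygen_trace <- function(true_vo2, volume = 750, capacitance = 5.11,
                                  start_saturation = 100, duration = 30,
                                  interval = 1, noise_sd = 0,
                                  control_drift = 0, seed = 1L,
                                  chamber_id = "chamber_1",
                                  is_control = FALSE) {
  if (volume <= 0 || capacitance <= 0 || duration <= 0 || interval <= 0) {
    stop("volume, capacitance, duration and interval must all be > 0",
         call. = FALSE)
  }
  if (start_saturation <= 0 || start_saturation > 100) {
    stop("'start_saturation' must be in (0, 100]", call. = FALSE)
  }
  if (true_vo2 < 0) stop("'true_vo2' must be >= 0", call. = FALSE)
  decline <- 100 * true_vo2 / (capacitance * volume / 1000)  # % AS h^-1
  slope <- -decline + control_drift
  if (-slope * interval / 60 >= start_saturation) {
    stop("oxygen would be fully depleted within a single sampling interval; ",
         "reduce true_vo2 or the interval", call. = FALSE)
  }
  times <- seq(0, duration, by = interval)
  with_private_seed(seed, {
    sat <- start_saturation + slope * times / 60 +
      stats::rnorm(length(times), 0, noise_sd)
    sat <- pmax(sat, 0)
    structure(
      data.frame(chamber_id = chamber_id,
                 time_min = times,
                 pct_air_saturation = sat,
                 is_control = is_control,
                 stringsAsFactors = FALSE),
      class = c("oxygen_trace", "data.frame"),
      true_slope = slope
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "Synthetic sperm metabolism dataset: %d records, %d species (%d endotherm)\n",
    nrow(x$records), cfg$n_species, cfg$n_endotherm))
  cat(sprintf("  generative exponent beta = %.3f, endotherm fold = %.2f, seed = %d\n",
              cfg$beta, cfg$endotherm_multiplier, cfg$seed))
  invisible(x)
}
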