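#' Restrict an oxygen trace to a saturation window
#'
#' Slope extraction is confined to a band of oxygen saturation (by default
#' 100-75% air saturation) so that rates are compared across similar oxygen
#' environments and possible oxy-conforming behaviour at low saturation does
#' not contaminate the estimate. The filter first discards leading points
#' above `upper`, then keeps the maximal contiguous run from the first
#' remaining point whose saturation stays within `[lower, upper]`. A trace
#' that is already below `lower` when measurement starts (dense samples
#' deplete oxygen before the first reading) yields an empty result, which
#' callers treat as "exclude this chamber" — not an error.
#'
#' @param trace a data.frame with columns `time_min` (strictly increasing)
#'   and `pct_air_saturation`.
#' @param upper,lower window bounds, % air saturation, `upper > lower`.
#' @return the filtered trace (possibly zero rows).
#' @export
saturation_filter <- function(trace, upper = 100, lower = 75) {
  stopifnot(is.data.frame(trace), upper > lower)
  sat <- trace$pct_air_saturation
  n <- length(sat)
  if (n == 0L) return(trace[0, , drop = FALSE])
  start <- which(sat <= upper)[1]
  if (is.na(start) || sat[start] < lower) return(trace[0, , drop = FALSE])
  end <- start
  while (end < n && sat[end + 1] >= lower && sat[end + 1] <= upper) {
    end <- end + 1
  }
  trace[start:end, , drop = FALSE]
}

# closed-form OLS slope + SE of saturation (%AS) on time (hours)
ols_slope_se <- function(time_h, sat) {
  k <- length(sat)
  xm <- mean(time_h); ym <- mean(sat)
  dx <- time_h - xm
  sxx <- sum(dx^2)
  slope <- sum(dx * (sat - ym)) / sxx
  resid <- sat - ym - slope * dx
  rss <- sum(resid^2)
  se <- if (k > 2) sqrt(rss / (k - 2) / sxx) else 0
  # guard tiny negative/rounding noise in exact-fit cases
  if (se < 1e-12 * max(abs(slope), 1)) se <- max(se, 0)
  c(slope = slope, se = se)
}

#' Best local regression slope of an oxygen trace
#'
#' Estimates the rate of oxygen decline (% air saturation per hour) by
#' ordinary least squares over every contiguous window of at least
#' `min_window_fraction` of the (filtered) trace, and returns the window
#' minimizing the relative imprecision SE(slope)/|slope| — the most stable
#' locally linear segment. Ties are broken toward the longer window, then
#' the earlier start, so a noise-free linear trace yields the full-length
#' window. Times are taken in minutes and the slope is reported per hour.
#'
#' @param trace a (typically [saturation_filter()]ed) oxygen trace.
#' @param min_window_fraction minimum window length as a fraction of the
#'   trace (default 1/3); windows are additionally at least 5 points.
#' @param instability_threshold relative-SE level above which the estimate
#'   is flagged unstable (default 0.25).
#' @return an object of class `slope_estimate`: list with `slope` (% AS
#'   h^-1), `standard_error`, `window` (start and end index), `n_points`,
#'   `relative_se`, and `unstable` flag.
#' @export
best_local_slope <- function(trace, min_window_fraction = 1/3,
                             instability_threshold = 0.25) {
  stopifnot(is.data.frame(trace))
  n <- nrow(trace)
  min_size <- max(5L, ceiling(min_window_fraction * n))
  if (n < min_size) {
    stop(sprintf("too few points (%d) for slope estimation in chamber '%s'",
                 n, if (n > 0) trace$chamber_id[1] else "?"), call. = FALSE)
  }
  if (is.unsorted(trace$time_min, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  time_h <- trace$time_min / 60
  sat <- trace$pct_air_saturation
  best <- NULL
  best_key <- NULL
  for (i in seq_len(n - min_size + 1L)) {
    for (j in seq(i + min_size - 1L, n)) {
      fit <- ols_slope_se(time_h[i:j], sat[i:j])
      # an exactly flat exact fit is a perfectly determined zero slope;
      # a near-zero slope with residual noise is maximally unstable
      rel <- if (fit["slope"] == 0) {
        if (fit["se"] == 0) 0 else Inf
      } else {
        fit["se"] / abs(fit["slope"])
      }
      key <- c(rel, -(j - i + 1L), i)
      if (is.null(best_key) || key[1] < best_key[1] ||
          (key[1] == best_key[1] && (key[2] < best_key[2] ||
            (key[2] == best_key[2] && key[3] < best_key[3])))) {
        best_key <- key
        best <- list(slope = unname(fit["slope"]),
                     standard_error = unname(fit["se"]),
                     window = c(i, j), n_points = j - i + 1L)
      }
    }
  }
  best$relative_se <- unname(best_key[1])
  best$unstable <- !is.finite(best_key[1]) ||
    best$relative_se > instability_threshold
  class(best) <- "slope_estimate"
  best
}

#' Control-correct a sample slope
#'
#' Subtracts the mean slope of the sperm-free control chambers (background
#' microbial respiration and sensor drift) from the sample slope.
#'
#' @param sample a `slope_estimate` (or a numeric slope, % AS h^-1).
#' @param controls a list of `slope_estimate`s or a numeric vector of
#'   control slopes; at least one is required.
#' @return net slope, % AS h^-1.
#' @export
control_corrected_slope <- function(sample, controls) {
  as_slope <- function(x) {
    if (inherits(x, "slope_estimate")) x$slope else as.numeric(x)
  }
  ctrl <- if (is.list(controls) && !is.data.frame(controls)) {
    vapply(controls, as_slope, numeric(1))
  } else {
    as.numeric(controls)
  }
  if (length(ctrl) == 0L || any(is.na(ctrl))) {
    stop("at least one control slope is required", call. = FALSE)
  }
  as_slope(sample) - mean(ctrl)
}

#' Convert a net oxygen-decline slope to an oxygen consumption rate
#'
#' \deqn{\dot{V}_{O_2} = \frac{|\mathrm{slope}|}{100} \times \kappa \times V,}
#' with the net decline slope in % air saturation per hour, capacitance
#' \eqn{\kappa} in ml O2 l^-1 (numerically µl O2 per ml of water) and
#' chamber volume in µl (converted to ml internally). A chamber losing 10%
#' AS per hour in 750 µl of seawater at 21°C (capacitance 5.11 ml l^-1)
#' consumes 0.38325 µl O2 h^-1. A positive net slope (the sample gaining
#' oxygen after control correction) is physically a non-respiring chamber:
#' it maps to 0 with a warning rather than a negative rate.
#'
#' @param net_slope control-corrected slope, % AS h^-1 (consumption is
#'   negative).
#' @param capacitance oxygen capacitance, ml O2 l^-1.
#' @param volume chamber water volume, µl.
#' @return oxygen consumption rate, µl O2 h^-1.
#' @export
slope_to_vo2 <- function(net_slope, capacitance = 5.11, volume = 750) {
  if (capacitance <= 0 || volume <= 0) {
    stop("capacitance and volume must be > 0", call. = FALSE)
  }
  if (any(net_slope > 0)) {
    warning("positive net slope (oxygen gain) clamped to zero V_O2")
  }
  abs(pmin(net_slope, 0)) / 100 * capacitance * (volume / 1000)
}

#' Full respirometry pipeline for one chamber
#'
#' Chains [saturation_filter()], [best_local_slope()],
#' [control_corrected_slope()] and [slope_to_vo2()] for a sample trace and
#' its control traces, the complete path from raw saturation series to
#' metabolic rate.
#'
#' @param trace sample oxygen trace.
#' @param controls list of control traces (same filtering is applied).
#' @param upper,lower saturation window, % AS.
#' @param min_window_fraction passed to [best_local_slope()] for the sample
#'   trace.
#' @param control_window_fraction minimum window fraction for control
#'   traces. Defaults to 1 (full-trace regression): control drift is weak
#'   and assumed linear, and window *selection* on a near-flat noisy trace
#'   preferentially finds spuriously steep segments, which would bias every
#'   corrected sample rate.
#' @param capacitance,volume passed to [slope_to_vo2()].
#' @return list with `vo2` (µl O2 h^-1), `net_slope`, `sample` and
#'   `control_slopes`, and `usable` (FALSE when the saturation filter left
#'   too few points, in which case `vo2` is `NA`).
#' @export
trace_to_vo2 <- function(trace, controls, upper = 100, lower = 75,
                         min_window_fraction = 1/3,
                         control_window_fraction = 1,
                         capacitance = 5.11, volume = 750) {
  filt <- saturation_filter(trace, upper, lower)
  if (nrow(filt) < 5L) {
    return(list(vo2 = NA_real_, net_slope = NA_real_, sample = NULL,
                control_slopes = NULL, usable = FALSE))
  }
  sample_est <- best_local_slope(filt, min_window_fraction)
  ctrl_est <- lapply(controls, function(ct) {
    best_local_slope(saturation_filter(ct, upper, lower),
                     control_window_fraction)
  })
  net <- control_corrected_slope(sample_est, ctrl_est)
  list(vo2 = slope_to_vo2(net, capacitance, volume),
       net_slope = net, sample = sample_est,
       control_slopes = vapply(ctrl_est, `[[`, numeric(1), "slope"),
       usable = TRUE)
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("slope %.4f %% AS h^-1 (SE %.4f, rel. SE %.3g) over points %d-%d (n=%d)%s\n",
              x$slope, x$standard_error, x$relative_se,
              x$window[1], x$window[2], x$n_points,
              if (x$unstable) " [UNSTABLE]" else ""))
  invisible(x)
}

#' Read a long-format oxygen trace file
#'
#' Expects a CSV with columns `chamber_id`, `time_min`,
#' `pct_air_saturation`, `is_control`; returns a named list of per-chamber
#' traces.
#'
#' @param path file path.
#' @return named list of `oxygen_trace` data.frames.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("chamber_id", "time_min", "pct_air_saturation", "is_control")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("trace file missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$is_control <- as.logical(raw$is_control)
  out <- split(raw, raw$chamber_id)
  lapply(out, function(tr) {
    tr <- tr[order(tr$time_min), , drop = FALSE]
    rownames(tr) <- NULL
    class(tr) <- c("oxygen_trace", "data.frame")
    tr
  })
}
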