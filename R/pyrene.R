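#' Time for an assembly trace to reach a fraction of its amplitude
#'
#' Bulk pyrene traces report polymer mass versus time. The nucleation-phase
#' readout used throughout this package is the time at which a trace first
#' reaches one-eighth of its amplitude (baseline to plateau), interpolated
#' linearly between frames after light smoothing.
#'
#' @param trace A single assembly trace: data frame with `time_s` and
#'   `signal_au` columns (strictly increasing time).
#' @param fraction Fraction of the amplitude to cross, default `1/8`.
#' @param baseline Baseline fluorescence (a.u.). Default: first smoothed point.
#' @param plateau Plateau fluorescence (a.u.). Default: mean of the final 5% of
#'   samples, after checking the trace has actually plateaued (final slope
#'   below 1% of the maximum rate).
#' @param smooth_k Odd moving-average window (samples) applied before the
#'   crossing search; `1` disables smoothing.
#' @return Crossing time in seconds.
#' @export
time_to_fraction <- function(trace, fraction = 1 / 8, baseline = NULL,
                             plateau = NULL, smooth_k = 5L) {
  trace <- check_assembly_trace(trace)
  assert_scalar_num(fraction, "fraction", lo = 0, hi = 1)
  t <- trace$time_s
  y <- moving_average(trace$signal_au, smooth_k)
  n <- length(y)
  if (n < 4L) abort_input("trace too short (need >= 4 samples)")

  baseline <- baseline %||% y[1L]
  if (is.null(plateau)) {
    tail_idx <- which(t >= t[n] - 0.05 * (t[n] - t[1L]))
    if (length(tail_idx) < 3L) tail_idx <- (n - 2L):n
    plateau <- mean(y[tail_idx])
    # reject plateaus read off a still-rising trace
    local_slope <- diff(y) / diff(t)
    max_rate <- max(abs(local_slope))
    end_fit <- ols_line(t[tail_idx], y[tail_idx])
    if (max_rate > 0 && is.finite(end_fit$slope) &&
        end_fit$slope > 0.01 * max_rate) {
      abort_input("plateau indeterminable: trace still rising at end; ",
                  "extend the trace or supply plateau explicitly")
    }
  }
  if (plateau <= baseline) abort_input("plateau must exceed baseline")

  level <- baseline + fraction * (plateau - baseline)
  above <- which(y >= level)
  if (length(above) == 0L) {
    abort_input("incomplete reaction: trace never reaches ",
                signif(fraction, 3), " of its amplitude")
  }
  i <- above[1L]
  if (i == 1L) return(t[1L])
  # linear interpolation between the bracketing frames
  t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}

#' Local slope of an assembly trace at a given time
#'
#' Least-squares slope of signal versus time over a centered window. Used to
#' read the assembly rate at the one-eighth time of a pyrene trace.
#'
#' @inheritParams time_to_fraction
#' @param t Center of the regression window (s).
#' @param window_s Window width (s), default 20.
#' @return Slope in a.u./s.
#' @export
slope_at_time <- function(trace, t, window_s = 20) {
  trace <- check_assembly_trace(trace)
  assert_scalar_num(t, "t")
  assert_scalar_num(window_s, "window_s", lo = 0)
  sel <- trace$time_s >= t - window_s / 2 & trace$time_s <= t + window_s / 2
  if (sum(sel) < 4L) {
    abort_input("fewer than 4 samples in the ", window_s, " s window around t = ", t)
  }
  ols_line(trace$time_s[sel], trace$signal_au[sel])$slope
}

#' Nucleation strength from a formin dilution series
#'
#' For each trace, computes the time to one-eighth completion and the assembly
#' slope there; the nucleation strength is the ordinary-least-squares slope of
#' those per-dose slopes against formin concentration (a.u./s per nM). Early in
#' the reaction nucleation dominates, so this slope is a dose-normalized
#' specific nucleation activity.
#'
#' @param traces Long-form trace set: data frame with `trace_id`, `formin_nM`,
#'   `time_s`, `signal_au`. At least 3 distinct formin concentrations.
#' @param fraction,window_s,smooth_k Passed to [time_to_fraction()] and
#'   [slope_at_time()].
#' @return A list of class `nucleation_result` with `per_dose` (tibble of
#'   `trace_id`, `formin_nM`, `t_one_eighth_s`, `slope_au_per_s`), `strength`,
#'   `strength_se`, and `intercept`.
#' @export
nucleation_strength <- function(traces, fraction = 1 / 8, window_s = 20,
                                smooth_k = 5L) {
  if (!all(c("trace_id", "formin_nM", "time_s", "signal_au") %in% names(traces))) {
    abort_input("traces must have columns trace_id, formin_nM, time_s, signal_au")
  }
  ids <- unique(traces$trace_id)
  per <- lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, , drop = FALSE]
    res <- tryCatch({
      t18 <- time_to_fraction(tr, fraction = fraction, smooth_k = smooth_k)
      sl <- slope_at_time(tr, t18, window_s = window_s)
      list(t18 = t18, slope = sl)
    }, error = function(e) {
      abort_input("trace '", id, "': ", conditionMessage(e))
    })
    tibble::tibble(trace_id = id, formin_nM = tr$formin_nM[1L],
                   t_one_eighth_s = res$t18, slope_au_per_s = res$slope)
  })
  per <- do.call(rbind, per)
  if (length(unique(per$formin_nM)) < 3L) {
    abort_input("need >= 3 distinct formin concentrations, got ",
                length(unique(per$formin_nM)))
  }
  fit <- ols_line(per$formin_nM, per$slope_au_per_s)
  structure(
    list(per_dose = per, strength = fit$slope, strength_se = fit$se,
         intercept = fit$intercept),
    class = "nucleation_result"
  )
}

#' @export
print.nucleation_result <- function(x, ...) {
  cat("Nucleation strength:", signif(x$strength, 3), "a.u./s per nM",
      "(se", signif(x$strength_se, 3), ")\n")
  cat("Intercept (actin alone):", signif(x$intercept, 3), "a.u./s over",
      nrow(x$per_dose), "traces\n")
  invisible(x)
}

#' Initial elongation rate of a seeded-assembly trace
#'
#' Least-squares slope over the first 90 s (the pre-depletion linear regime of
#' a seeded elongation assay). If the trace is shorter than the window, the
#' available span is used with a warning.
#'
#' @inheritParams time_to_fraction
#' @param window_s Regression window from time zero, default 90 s.
#' @return Rate in a.u./s.
#' @export
initial_rate <- function(trace, window_s = 90) {
  trace <- check_assembly_trace(trace)
  span <- max(trace$time_s) - min(trace$time_s)
  if (span < window_s) {
    warning("trace spans only ", signif(span, 3), " s; using available span ",
            "instead of the ", window_s, " s window", call. = FALSE)
    window_s <- span
  }
  sel <- trace$time_s <= min(trace$time_s) + window_s
  if (sum(sel) < 4L) abort_input("fewer than 4 samples in the initial window")
  ols_line(trace$time_s[sel], trace$signal_au[sel])$slope
}

#' Normalize elongation rates against the actin-alone control
#'
#' Each experiment carries its own no-formin control; rates are expressed
#' relative to it. Rates above the control (elongation acceleration) are
#' preserved, not clipped.
#'
#' @param rates Data frame with `formin_nM` and `rate` columns.
#' @param actin_alone_rate Positive control rate (a.u./s).
#' @return Tibble with `formin_nM` and normalized rate `r`.
#' @export
normalize_rates <- function(rates, actin_alone_rate) {
  if (!all(c("formin_nM", "rate") %in% names(rates))) {
    abort_input("rates must have columns formin_nM and rate")
  }
  assert_scalar_num(actin_alone_rate, "actin_alone_rate")
  if (actin_alone_rate <= 0) abort_input("actin_alone_rate must be positive")
  tibble::tibble(formin_nM = rates$formin_nM, r = rates$rate / actin_alone_rate)
}
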