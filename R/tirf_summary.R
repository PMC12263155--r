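#' Summary statistics of TIRF formin events
#'
#' Aggregates detected events and whole-trace growth into the summary metrics
#' reported for single-filament formin assays: whole-trace average elongation
#' rates, burst (formin-mediated) elongation rates, run lengths with a
#' characteristic (exponential maximum-likelihood) run length, and pause
#' (capping) durations.
#'
#' Censored bursts (those reaching the end of the movie) are excluded from
#' run-length statistics by default; `include_censored = TRUE` uses the
#' censored-exponential MLE (total length over the number of uncensored
#' events) for the characteristic run length instead. Pauses pass a minimum
#' duration gate of `min_pause_s` during detection; because an exponential
#' distribution is memoryless, the mean of gated durations overestimates the
#' underlying mean by exactly the gate, so the summary reports both the raw
#' detected mean (`pause_mean_s`) and the gate-corrected capping-duration
#' estimate (`capping_duration_s = pause_mean_s - min_pause_s`).
#'
#' @param events Event tibble from [extract_events()]/[detect_events()].
#' @param traces Optional trace tibble (for whole-trace average rates and the
#'   filament count).
#' @param min_pause_s Detection gate used when the events were segmented (s).
#' @param include_censored Include censored bursts in the characteristic
#'   run-length estimate via the censored-exponential MLE.
#' @param subunits_per_um Actin geometry constant (370).
#' @return A list of class `tirf_summary`.
#' @export
event_statistics <- function(events, traces = NULL, min_pause_s = 5,
                             include_censored = FALSE, subunits_per_um = 370) {
  n_events <- nrow(events)
  n_filaments <- if (!is.null(traces)) {
    length(unique(traces$filament_id))
  } else if (n_events > 0L && "filament_id" %in% names(events)) {
    length(unique(events$filament_id))
  } else NA_integer_

  avg_rate_mean <- avg_rate_sd <- NA_real_
  if (!is.null(traces)) {
    rates <- vapply(split(traces, traces$filament_id), function(tr) {
      ols_line(tr$time_s, tr$length_um * subunits_per_um)$slope
    }, numeric(1))
    avg_rate_mean <- mean(rates)
    avg_rate_sd <- stats::sd(rates)
  }

  if (n_events == 0L) {
    return(structure(
      list(n_events = 0L, n_filaments = n_filaments,
           avg_rate_mean = avg_rate_mean, avg_rate_sd = avg_rate_sd,
           burst_rate_mean = NA_real_, burst_rate_sd = NA_real_,
           n_rates = 0L,
           run_length_mean = NA_real_, run_length_sd = NA_real_,
           run_length_char = NA_real_, pause_mean_s = NA_real_,
           pause_sd_s = NA_real_, capping_duration_s = NA_real_,
           n_pauses = 0L, n_uncensored = 0L,
           burst_frequency_per_filament = 0),
      class = "tirf_summary"
    ))
  }

  # Burst-rate statistics carry inverse-detection-probability weights. A rate
  # is only measurable when the burst covers >= 2 frames; for exponential run
  # lengths (scale lambda, estimated from the uncensored runs) a burst at
  # rate v lasts u = l*spu/v, and the probability that an event at rate v
  # yields a measurable rate is P(v) = (lambda/a) (exp(-a/lambda) -
  # exp(-2a/lambda)) with a = v dt / spu. Fast bursts are under-sampled
  # (P decreasing in v); weighting by 1/P removes that selection bias.
  # Weights are capped to keep single events from dominating.
  dt <- attr(events, "frame_interval_s") %||% 2.5
  has_rate <- is.finite(events$burst_rate_sub_per_s)
  w <- rep(0, n_events)
  if (any(has_rate)) {
    lam <- mean(events$run_length_um[!events$censored])
    v <- events$burst_rate_sub_per_s[has_rate]
    if (is.finite(lam) && lam > 0) {
      a <- v * dt / subunits_per_um
      P <- (lam / a) * (exp(-a / lam) - exp(-2 * a / lam))
      w[has_rate] <- pmin(1 / pmax(P, 1e-3), 10)
    } else {
      w[has_rate] <- 1
    }
  }
  wsum <- sum(w)
  burst_rate_mean <- if (wsum > 0) {
    sum(w * events$burst_rate_sub_per_s, na.rm = TRUE) / wsum
  } else NA_real_
  burst_rate_sd <- if (sum(has_rate) > 1L) {
    sqrt(sum(w * (events$burst_rate_sub_per_s - burst_rate_mean)^2,
             na.rm = TRUE) / wsum * sum(has_rate) / (sum(has_rate) - 1L))
  } else NA_real_

  unc <- events[!events$censored, , drop = FALSE]
  run_mean <- if (nrow(unc)) mean(unc$run_length_um) else NA_real_
  run_sd <- if (nrow(unc) > 1L) stats::sd(unc$run_length_um) else NA_real_
  run_char <- if (include_censored) {
    if (nrow(unc) == 0L) {
      warning("all bursts censored: characteristic run length unavailable",
              call. = FALSE)
      NA_real_
    } else {
      sum(events$run_length_um) / nrow(unc)
    }
  } else {
    if (nrow(unc) == 0L) {
      warning("all bursts censored: characteristic run length unavailable",
              call. = FALSE)
    }
    run_mean
  }

  pauses <- events$pause_duration_s[is.finite(events$pause_duration_s)]
  pause_mean <- if (length(pauses)) mean(pauses) else NA_real_
  pause_sd <- if (length(pauses) > 1L) stats::sd(pauses) else NA_real_
  capping <- if (length(pauses)) max(0, pause_mean - min_pause_s) else NA_real_

  structure(
    list(n_events = n_events, n_filaments = n_filaments,
         avg_rate_mean = avg_rate_mean, avg_rate_sd = avg_rate_sd,
         burst_rate_mean = burst_rate_mean,
         burst_rate_sd = burst_rate_sd,
         n_rates = sum(has_rate),
         run_length_mean = run_mean, run_length_sd = run_sd,
         run_length_char = run_char,
         pause_mean_s = pause_mean, pause_sd_s = pause_sd,
         capping_duration_s = capping,
         n_pauses = length(pauses), n_uncensored = nrow(unc),
         burst_frequency_per_filament =
           if (is.na(n_filaments)) NA_real_ else n_events / n_filaments),
    class = "tirf_summary"
  )
}

#' @export
print.tirf_summary <- function(x, ...) {
  cat("TIRF event summary:", x$n_events, "events over", x$n_filaments,
      "filaments\n")
  if (is.finite(x$avg_rate_mean)) {
    cat("  average elongation:", signif(x$avg_rate_mean, 3), "+/-",
        signif(x$avg_rate_sd, 3), "subunits/s\n")
  }
  if (x$n_events > 0L) {
    cat("  burst rate:", signif(x$burst_rate_mean, 3), "+/-",
        signif(x$burst_rate_sd, 3), "subunits/s\n")
    cat("  run length:", signif(x$run_length_mean, 3), "+/-",
        signif(x$run_length_sd, 3), "um (characteristic",
        signif(x$run_length_char, 3), "um,", x$n_uncensored, "uncensored)\n")
    cat("  pause: detected mean", signif(x$pause_mean_s, 3), "s; capping",
        "duration estimate", signif(x$capping_duration_s, 3), "s over",
        x$n_pauses, "pauses\n")
  }
  invisible(x)
}

#' Match detected events to planted ground truth
#'
#' Greedy one-to-one matching of detected burst intervals to planted burst
#' intervals by temporal overlap, for sensitivity / false-discovery checks of
#' the segmentation pipeline against the generator's truth.
#'
#' @param detected Event tibble from [detect_events()].
#' @param truth Planted-event tibble from [simulate_filament_ensemble()].
#' @param min_overlap_s Minimum overlap between a detected and a planted
#'   burst interval to count as a match; default half a frame (1.25 s). For
#'   planted bursts briefer than this, half the planted duration is required
#'   instead, so near-instantaneous events remain matchable.
#' @return List with `sensitivity`, `fdr`, `n_truth`, `n_detected`, and the
#'   matched index pairs.
#' @export
match_events <- function(detected, truth, min_overlap_s = 1.25) {
  if (nrow(truth) == 0L) {
    return(list(sensitivity = NA_real_,
                fdr = if (nrow(detected)) 1 else NA_real_,
                n_truth = 0L, n_detected = nrow(detected),
                matches = data.frame(detected = integer(), truth = integer())))
  }
  used_truth <- rep(FALSE, nrow(truth))
  matches <- list()
  for (i in seq_len(nrow(detected))) {
    cand <- which(!used_truth &
                    truth$filament_id == detected$filament_id[i])
    if (length(cand) == 0L) next
    ov <- pmin(detected$t_end[i], truth$t_burst_end_s[cand]) -
      pmax(detected$t_start[i], truth$t_pause_end_s[cand])
    need <- pmin(min_overlap_s,
                 0.5 * (truth$t_burst_end_s[cand] - truth$t_pause_end_s[cand]))
    j <- which.max(ov - need)
    if (ov[j] >= need[j]) {
      used_truth[cand[j]] <- TRUE
      matches[[length(matches) + 1L]] <- c(detected = i, truth = cand[j])
    }
  }
  m <- if (length(matches)) {
    as.data.frame(do.call(rbind, matches))
  } else data.frame(detected = integer(), truth = integer())
  list(
    sensitivity = nrow(m) / nrow(truth),
    fdr = if (nrow(detected)) 1 - nrow(m) / nrow(detected) else NA_real_,
    n_truth = nrow(truth), n_detected = nrow(detected), matches = m
  )
}
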