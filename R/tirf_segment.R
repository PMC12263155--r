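#' Segment a filament trace into free-growth, pause, and burst episodes
#'
#' Implements an algorithmic version of the visual pause/burst identification
#' used for formin TIRF data. Length is converted to subunits (370/um), a
#' global line is fit, and 3-point central local slopes classify samples:
#' runs of near-zero local slope are candidate pauses, accepted when they last
#' at least `min_pause_s` seconds with a fitted slope inside
#' (`pause_slope_lo`, `pause_slope_hi`) subunits/s; runs of dim intensity
#' (ratio below `dim_threshold` of the bright level) -- or, without an
#' intensity channel, fast runs following an accepted pause -- are candidate
#' bursts, accepted when the linear fit has R-squared above `burst_min_r2`
#' and a slope above the trace's free-growth rate. Segment boundaries are
#' refined to sub-frame resolution by intersecting the fitted lines of
#' adjacent segments, and the returned segments tile the trace exactly.
#'
#' @param trace Tibble with `time_s`, `length_um`, optional `intensity_au`
#'   (ratio to bright level) and `filament_id`; uniform cadence, >= 8 samples.
#' @param min_pause_s Minimum accepted pause duration (s), default 5.
#' @param pause_slope_lo,pause_slope_hi Pause slope window (subunits/s),
#'   default (-10, 5).
#' @param burst_min_r2 Minimum R-squared of the burst line fit, default 0.5.
#' @param dim_threshold Intensity ratio below which a sample counts as dim.
#' @param subunits_per_um Actin geometry constant (370).
#' @param use_intensity Use the intensity channel for burst detection when
#'   present (default TRUE).
#' @return Tibble of segments: `kind` (free/pause/burst), `t_start`, `t_end`,
#'   `slope_sub_per_s`, `slope_se`, `r2`, `mean_intensity_ratio`,
#'   `n_samples`; attributes `free_rate_sub_per_s` (robust free-growth
#'   estimate) and `frame_interval_s`.
#' @export
segment_trace <- function(trace, min_pause_s = 5, pause_slope_lo = -10,
                          pause_slope_hi = 5, burst_min_r2 = 0.5,
                          dim_threshold = 0.75, subunits_per_um = 370,
                          use_intensity = TRUE) {
  stopifnot(all(c("time_s", "length_um") %in% names(trace)))
  t <- trace$time_s
  n <- length(t)
  if (n < 8L) abort_input("need >= 8 samples to segment a trace")
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 0.01 * dt)) {
    abort_input("non-uniform sampling (cadence varies by > 1%); resample first")
  }
  y <- trace$length_um * subunits_per_um

  # 3-point central local slopes; one-sided at the ends
  ls <- c((y[2L] - y[1L]) / dt,
          (y[3:n] - y[1:(n - 2L)]) / (2 * dt),
          (y[n] - y[n - 1L]) / dt)
  free_rate <- stats::median(ls)

  lab <- rep("free", n)
  lab[ls > pause_slope_lo & ls < pause_slope_hi] <- "pause"
  has_intensity <- use_intensity && "intensity_au" %in% names(trace) &&
    any(is.finite(trace$intensity_au))
  if (has_intensity) {
    bright <- stats::median(trace$intensity_au, na.rm = TRUE)
    ratio <- trace$intensity_au / bright
    lab[is.finite(ratio) & ratio < dim_threshold] <- "burst"
    # a bright sample whose central-slope window straddles the pause-to-burst
    # transition is neither flat nor dim; reattach it to the pause so the
    # pause/burst adjacency (and the boundary intersection) is preserved
    for (i in seq_len(n)) {
      if (lab[i] == "free" && i > 1L && i < n &&
          lab[i - 1L] == "pause" && lab[i + 1L] == "burst") {
        lab[i] <- "pause"
      }
    }
  } else {
    ratio <- rep(NA_real_, n)
    # slope-only fallback: fast samples directly after a pause run
    r <- rle(lab)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] != "pause" || k == length(r$values)) next
      j <- idx_end[k] + 1L
      while (j <= n && ls[j] > free_rate && lab[j] == "free") {
        lab[j] <- "burst"
        j <- j + 1L
      }
    }
  }

  segs <- build_segments(t, y, lab, ls, ratio, dt)
  segs <- refine_boundaries(segs, dt, t[1L], t[n])

  # gates: failed pauses/bursts revert to free growth
  for (pass in 1:2) {
    changed <- FALSE
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      if (s$kind == "pause") {
        dur <- s$t_end - s$t_start
        if (dur < min_pause_s || s$slope <= pause_slope_lo ||
            s$slope >= pause_slope_hi) {
          segs[[k]]$kind <- "free"; changed <- TRUE
        }
      } else if (s$kind == "burst") {
        r2ok <- is.na(s$r2) || s$r2 > burst_min_r2
        if (!r2ok || !is.finite(s$slope) || s$slope <= free_rate) {
          segs[[k]]$kind <- "free"; changed <- TRUE
        }
      }
    }
    if (!changed) break
    segs <- merge_free_runs(segs, t, y, ls, ratio)
    segs <- refine_boundaries(segs, dt, t[1L], t[n])
  }

  out <- do.call(rbind, lapply(segs, function(s) {
    tibble::tibble(kind = s$kind, t_start = s$t_start, t_end = s$t_end,
                   slope_sub_per_s = s$slope, intercept_sub = s$intercept,
                   slope_se = s$se, r2 = s$r2,
                   mean_intensity_ratio = s$intensity, n_samples = s$n)
  }))
  if ("filament_id" %in% names(trace)) {
    out <- tibble::add_column(out, filament_id = trace$filament_id[1L],
                              .before = 1L)
  }
  attr(out, "free_rate_sub_per_s") <- free_rate
  attr(out, "frame_interval_s") <- dt
  out
}

# Fit a line to a run of samples; edge samples are trimmed from fits of
# longer runs because 3-point labeling blurs state transitions by one frame.
fit_run <- function(t, y, ls, i1, i2) {
  idx <- i1:i2
  fit_idx <- if (length(idx) >= 4L) idx[-c(1L, length(idx))] else idx
  if (length(fit_idx) >= 2L) {
    f <- ols_line(t[fit_idx], y[fit_idx])
    r2 <- if (length(fit_idx) >= 3L) f$r2 else 1
    list(slope = f$slope, intercept = f$intercept, se = f$se, r2 = r2)
  } else {
    list(slope = ls[i1], intercept = y[i1] - ls[i1] * t[i1],
         se = NA_real_, r2 = NA_real_)
  }
}

build_segments <- function(t, y, lab, ls, ratio, dt) {
  r <- rle(lab)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  lapply(seq_along(r$values), function(k) {
    i1 <- idx_start[k]; i2 <- idx_end[k]
    f <- fit_run(t, y, ls, i1, i2)
    list(kind = r$values[k], i1 = i1, i2 = i2,
         t_start = t[i1], t_end = t[i2],
         slope = f$slope, intercept = f$intercept, se = f$se, r2 = f$r2,
         intensity = mean(ratio[i1:i2]), n = i2 - i1 + 1L)
  })
}

merge_free_runs <- function(segs, t, y, ls, ratio) {
  out <- list()
  for (s in segs) {
    m <- length(out)
    if (m > 0L && out[[m]]$kind == "free" && s$kind == "free") {
      i1 <- out[[m]]$i1; i2 <- s$i2
      f <- fit_run(t, y, ls, i1, i2)
      out[[m]] <- list(kind = "free", i1 = i1, i2 = i2,
                       t_start = t[i1], t_end = t[i2],
                       slope = f$slope, intercept = f$intercept, se = f$se,
                       r2 = f$r2, intensity = mean(ratio[i1:i2]),
                       n = i2 - i1 + 1L)
    } else {
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

# Sub-frame boundary placement: intersect the fitted lines of adjacent
# segments; fall back to the midpoint between their edge samples when the
# lines are parallel or the intersection falls outside the inter-sample
# transition window. The window is strict -- an intersection outside
# [last sample of A, first sample of B] signals a length discontinuity (an
# unresolved burst between the segments), and intersecting there would
# swallow the step.
refine_boundaries <- function(segs, dt, t_first, t_last) {
  m <- length(segs)
  if (m == 0L) return(segs)
  bounds <- numeric(m + 1L)
  bounds[1L] <- t_first
  bounds[m + 1L] <- t_last
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      A <- segs[[k]]; B <- segs[[k + 1L]]
      lo <- A$t_end
      hi <- B$t_start
      mid <- (A$t_end + B$t_start) / 2
      tb <- mid
      if (is.finite(A$slope) && is.finite(B$slope) &&
          abs(A$slope - B$slope) > 1e-9) {
        ti <- (B$intercept - A$intercept) / (A$slope - B$slope)
        if (is.finite(ti) && ti >= lo && ti <= hi) tb <- ti
      }
      bounds[k + 1L] <- tb
    }
    bounds <- cummax(bounds)  # enforce ordering after clamping
  }
  for (k in seq_len(m)) {
    segs[[k]]$t_start <- bounds[k]
    segs[[k]]$t_end <- bounds[k + 1L]
  }
  segs
}

#' Extract formin events (pause/burst episodes) from segments
#'
#' Each accepted burst becomes one event, paired with an immediately
#' preceding pause when present. The run length is the burst-fit slope times
#' the refined burst duration (converted to um); bursts running into the end
#' of the movie are flagged censored. `baseline_return` records whether the
#' following free segment's rate is within 2 SD of the population free rate.
#'
#' @param segments Output of [segment_trace()].
#' @param free_rate_mean,free_rate_sd Population free-growth rate statistics
#'   (subunits/s) for the baseline-return check; defaults to the free
#'   segments in `segments`.
#' @param subunits_per_um Actin geometry constant (370).
#' @param step_min_um Bursts too brief to cover a single frame leave no dim
#'   sample, only a length step between the pause and the following
#'   free-growth line; steps larger than this (um) are recovered as events
#'   with indeterminate rate. Default 0.08 um (~4 SD of the line-jump noise
#'   at the default tracking noise).
#' @return Tibble of events: `filament_id` (if present), `t_start`, `t_end`,
#'   `pause_duration_s` (NA when no pause preceded), `burst_rate_sub_per_s`,
#'   `run_length_um`, `burst_r2`, `baseline_return`, `censored`.
#' @export
extract_events <- function(segments, free_rate_mean = NULL,
                           free_rate_sd = NULL, subunits_per_um = 370,
                           step_min_um = 0.08) {
  dt <- attr(segments, "frame_interval_s") %||% 2.5
  free <- segments[segments$kind == "free" & segments$n_samples >= 3L, ]
  free_rate_mean <- free_rate_mean %||%
    (if (nrow(free)) mean(free$slope_sub_per_s) else NA_real_)
  free_rate_sd <- free_rate_sd %||%
    (if (nrow(free) > 1L) stats::sd(free$slope_sub_per_s) else NA_real_)
  t_end_trace <- max(segments$t_end)

  idx <- which(segments$kind == "burst")
  empty <- tibble::tibble(filament_id = character(), t_start = numeric(),
                          t_end = numeric(), pause_duration_s = numeric(),
                          burst_rate_sub_per_s = numeric(),
                          run_length_um = numeric(), burst_r2 = numeric(),
                          baseline_return = logical(), censored = logical())
  line_at <- function(k, t) {
    segments$intercept_sub[k] + segments$slope_sub_per_s[k] * t
  }
  rows <- lapply(idx, function(k) {
    b <- segments[k, ]
    pause_dur <- NA_real_
    if (k > 1L && segments$kind[k - 1L] == "pause") {
      pause_dur <- segments$t_end[k - 1L] - segments$t_start[k - 1L]
    }
    censored <- b$t_end >= t_end_trace - dt / 2
    base_ret <- NA
    if (k < nrow(segments) && segments$kind[k + 1L] == "free" &&
        is.finite(free_rate_sd) && free_rate_sd > 0) {
      base_ret <- abs(segments$slope_sub_per_s[k + 1L] - free_rate_mean) <=
        2 * free_rate_sd
    }
    # run length as the length jump across the burst, read from the
    # neighboring segment lines at the refined boundaries: robust for bursts
    # spanning few (or single) frames, where the burst's own fit is weak
    len_before <- if (k > 1L && is.finite(segments$intercept_sub[k - 1L])) {
      line_at(k - 1L, b$t_start)
    } else if (is.finite(b$intercept_sub)) {
      line_at(k, b$t_start)
    } else NA_real_
    len_after <- if (k < nrow(segments) &&
                     is.finite(segments$intercept_sub[k + 1L])) {
      line_at(k + 1L, b$t_end)
    } else if (is.finite(b$intercept_sub)) {
      line_at(k, b$t_end)
    } else NA_real_
    run_um <- if (is.finite(len_before) && is.finite(len_after)) {
      max(0, (len_after - len_before) / subunits_per_um)
    } else {
      b$slope_sub_per_s * (b$t_end - b$t_start) / subunits_per_um
    }
    tibble::tibble(
      filament_id = if ("filament_id" %in% names(segments)) b$filament_id else NA_character_,
      t_start = b$t_start, t_end = b$t_end,
      pause_duration_s = pause_dur,
      # rate is indeterminate below two in-burst samples (resolution floor)
      burst_rate_sub_per_s = if (b$n_samples >= 2L) b$slope_sub_per_s else NA_real_,
      run_length_um = run_um,
      burst_r2 = b$r2, baseline_return = base_ret, censored = censored
    )
  })

  # sub-frame bursts: a pause handing straight back to free growth with a
  # length step between the two fitted lines records an event whose rate is
  # unresolved but whose run length is the step
  pidx <- which(segments$kind == "pause")
  step_rows <- lapply(pidx, function(k) {
    if (k >= nrow(segments) || segments$kind[k + 1L] != "free") return(NULL)
    if (!is.finite(segments$intercept_sub[k]) ||
        !is.finite(segments$intercept_sub[k + 1L])) return(NULL)
    tb <- segments$t_end[k]
    jump <- line_at(k + 1L, tb) - line_at(k, tb)
    if (!is.finite(jump) || jump < step_min_um * subunits_per_um) return(NULL)
    base_ret <- if (is.finite(free_rate_sd) && free_rate_sd > 0) {
      abs(segments$slope_sub_per_s[k + 1L] - free_rate_mean) <= 2 * free_rate_sd
    } else NA
    tibble::tibble(
      filament_id = if ("filament_id" %in% names(segments)) segments$filament_id[k] else NA_character_,
      t_start = tb - dt / 2, t_end = tb + dt / 2,
      pause_duration_s = segments$t_end[k] - segments$t_start[k],
      burst_rate_sub_per_s = NA_real_,
      run_length_um = jump / subunits_per_um,
      burst_r2 = NA_real_, baseline_return = base_ret, censored = FALSE
    )
  })

  rows <- c(rows, Filter(Negate(is.null), step_rows))
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$t_start), , drop = FALSE]
  attr(out, "frame_interval_s") <- dt
  out
}

#' Run segmentation and event extraction over a trace ensemble
#'
#' @param traces Long tibble of filament traces (`filament_id`, `time_s`,
#'   `length_um`, optional `intensity_au`).
#' @param ... Passed to [segment_trace()].
#' @return List with `segments` and `events` tibbles (all filaments).
#' @export
detect_events <- function(traces, ...) {
  ids <- unique(traces$filament_id)
  seg_list <- lapply(ids, function(id) {
    segment_trace(traces[traces$filament_id == id, , drop = FALSE], ...)
  })
  # population free rate pooled across filaments for the baseline check
  all_segs <- do.call(rbind, seg_list)
  free <- all_segs[all_segs$kind == "free" & all_segs$n_samples >= 3L, ]
  frm <- if (nrow(free)) mean(free$slope_sub_per_s) else NA_real_
  frs <- if (nrow(free) > 1L) stats::sd(free$slope_sub_per_s) else NA_real_
  ev_list <- lapply(seg_list, function(s) {
    extract_events(s, free_rate_mean = frm, free_rate_sd = frs)
  })
  events <- tibble::as_tibble(do.call(rbind, ev_list))
  attr(events, "frame_interval_s") <- attr(ev_list[[1L]], "frame_interval_s")
  list(segments = tibble::as_tibble(all_segs), events = events)
}
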