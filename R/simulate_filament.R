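#' Parameters for the single-filament growth simulator
#'
#' A renewal model of formin action on one growing filament: free barbed-end
#' growth at `v_free` is interrupted at exponential waiting times (`k_attach`)
#' by a formin capture, which first caps the end (a pause of exponential
#' duration), then drives a processive burst of fast elongation (exponential
#' run length, per-event rate drawn from a truncated normal floored at
#' `v_free`), after which the formin detaches and free growth resumes.
#' Material grown during a burst is dimmer than the bright baseline by
#' `dim_factor`, matching the appearance of formin-grown segments in TIRF
#' movies; the physical origin of the dimming is not modeled.
#'
#' Defaults reproduce the wild-type study conditions: bursts at 39 +/- 13
#' subunits/s, exponential run length with mean 1.10 um, exponential pauses
#' with mean 12 s, sampling at 2.5 s for 10 min movies, and 370 subunits per
#' um of filament.
#'
#' @param v_free Free elongation rate (subunits/s).
#' @param v_burst_mean,v_burst_sd Burst-rate distribution (subunits/s).
#' @param pause_mean Mean pause (capping) duration (s).
#' @param runlength_char Characteristic (exponential-mean) run length (um).
#' @param k_attach Formin capture rate per filament (s^-1).
#' @param dim_factor Intensity of burst-grown material relative to bright (0-1].
#' @param frame_interval Sampling cadence (s).
#' @param length_noise_sd Gaussian measurement noise on length (um).
#' @param intensity_noise_sd Gaussian noise on the intensity ratio.
#' @param duration Movie duration (s).
#' @param subunits_per_um Actin geometry constant, 370 subunits/um.
#' @return A list of class `filament_kinetics_params`.
#' @export
filament_params <- function(v_free = 10, v_burst_mean = 39, v_burst_sd = 13,
                            pause_mean = 12, runlength_char = 1.10,
                            k_attach = 0.01, dim_factor = 0.5,
                            frame_interval = 2.5, length_noise_sd = 0.02,
                            intensity_noise_sd = 0.05, duration = 600,
                            subunits_per_um = 370) {
  p <- list(v_free = v_free, v_burst_mean = v_burst_mean,
            v_burst_sd = v_burst_sd, pause_mean = pause_mean,
            runlength_char = runlength_char, k_attach = k_attach,
            dim_factor = dim_factor, frame_interval = frame_interval,
            length_noise_sd = length_noise_sd,
            intensity_noise_sd = intensity_noise_sd, duration = duration,
            subunits_per_um = subunits_per_um)
  if (p$frame_interval <= 0) abort_input("frame_interval must be > 0")
  if (p$pause_mean < 0) abort_input("pause_mean must be >= 0")
  if (p$runlength_char <= 0) abort_input("runlength_char must be > 0")
  if (p$dim_factor <= 0 || p$dim_factor > 1) {
    abort_input("dim_factor must be in (0, 1]")
  }
  if (p$k_attach < 0 || p$v_free < 0) abort_input("rates must be >= 0")
  structure(p, class = "filament_kinetics_params")
}

# Burst rate: normal truncated from below at the free rate (rejection
# sampling; the truncated mass is tiny at the default parameters).
draw_burst_rate <- function(mean, sd, floor) {
  repeat {
    v <- stats::rnorm(1L, mean, sd)
    if (v >= floor) return(v)
  }
}

#' Simulate one filament length-vs-time trace with planted events
#'
#' Generates the continuous-time piecewise-linear growth path of
#' [filament_params()], samples it at the frame interval with additive
#' Gaussian length noise, and returns the planted pause/burst events exactly.
#'
#' @param params A [filament_params()] object.
#' @param seed RNG seed.
#' @param filament_id Identifier stored in the output.
#' @return Tibble with `filament_id`, `time_s`, `length_um`, `intensity_au`
#'   (ratio to the bright level: 1 outside bursts, `dim_factor` during), and
#'   the ground truth in attribute `"truth_events"` (tibble with
#'   `t_pause_start_s`, `t_pause_end_s`, `t_burst_end_s`,
#'   `burst_rate_sub_per_s`, `run_length_um`).
#' @export
simulate_filament_trace <- function(params, seed = 0, filament_id = "fil_001") {
  stopifnot(inherits(params, "filament_kinetics_params"))
  with_seed(seed, simulate_filament_trace_impl(params, filament_id))
}

simulate_filament_trace_impl <- function(params, filament_id) {
  spu <- params$subunits_per_um
  # breakpoints of the piecewise-linear path: time, length (subunits), state
  bt <- 0; bl <- 0
  times <- 0; lengths <- 0
  seg_start <- numeric(); seg_end <- numeric(); seg_state <- character()
  events <- list()

  push_seg <- function(t0, t1, state) {
    seg_start <<- c(seg_start, t0); seg_end <<- c(seg_end, t1)
    seg_state <<- c(seg_state, state)
  }

  while (bt < params$duration) {
    wait <- if (params$k_attach > 0) stats::rexp(1L, params$k_attach) else Inf
    t_attach <- bt + wait
    if (t_attach >= params$duration) {
      push_seg(bt, params$duration, "free")
      bl <- bl + params$v_free * (params$duration - bt)
      times <- c(times, params$duration); lengths <- c(lengths, bl)
      break
    }
    # free growth until capture
    push_seg(bt, t_attach, "free")
    bl <- bl + params$v_free * (t_attach - bt)
    times <- c(times, t_attach); lengths <- c(lengths, bl)

    pause_dur <- stats::rexp(1L, 1 / params$pause_mean)
    run_um <- stats::rexp(1L, 1 / params$runlength_char)
    v_burst <- draw_burst_rate(params$v_burst_mean, params$v_burst_sd,
                               params$v_free)
    burst_dur <- run_um * spu / v_burst

    t_pause_end <- t_attach + pause_dur
    t_burst_end <- t_pause_end + burst_dur
    events[[length(events) + 1L]] <- tibble::tibble(
      filament_id = filament_id,
      t_pause_start_s = t_attach, t_pause_end_s = t_pause_end,
      t_burst_end_s = t_burst_end, burst_rate_sub_per_s = v_burst,
      run_length_um = run_um
    )

    # pause: no growth (full cap)
    t1 <- min(t_pause_end, params$duration)
    push_seg(t_attach, t1, "pause")
    times <- c(times, t1); lengths <- c(lengths, bl)
    if (t_pause_end >= params$duration) { bt <- params$duration; break }

    # burst: fast dim growth
    t2 <- min(t_burst_end, params$duration)
    push_seg(t_pause_end, t2, "burst")
    bl <- bl + v_burst * (t2 - t_pause_end)
    times <- c(times, t2); lengths <- c(lengths, bl)
    bt <- t2
    if (t_burst_end >= params$duration) break
  }

  t_frames <- seq(0, params$duration, by = params$frame_interval)
  len_sub <- stats::approx(times, lengths, xout = t_frames, rule = 2)$y
  state_at <- function(tt) {
    i <- findInterval(tt, seg_start)
    ifelse(i >= 1 & tt <= seg_end[pmax(i, 1L)], seg_state[pmax(i, 1L)], "free")
  }
  st <- vapply(t_frames, state_at, character(1))
  intensity <- ifelse(st == "burst", params$dim_factor, 1)

  length_um <- len_sub / spu
  if (params$length_noise_sd > 0) {
    length_um <- length_um +
      stats::rnorm(length(length_um), 0, params$length_noise_sd)
  }
  if (params$intensity_noise_sd > 0) {
    intensity <- intensity +
      stats::rnorm(length(intensity), 0, params$intensity_noise_sd)
  }

  out <- tibble::tibble(filament_id = filament_id, time_s = t_frames,
                        length_um = length_um, intensity_au = intensity)
  truth <- if (length(events)) {
    do.call(rbind, events)
  } else {
    tibble::tibble(filament_id = character(), t_pause_start_s = numeric(),
                   t_pause_end_s = numeric(), t_burst_end_s = numeric(),
                   burst_rate_sub_per_s = numeric(), run_length_um = numeric())
  }
  attr(out, "truth_events") <- truth
  attr(out, "params") <- params
  out
}

#' Simulate an ensemble of filament traces
#'
#' Convenience wrapper generating `n_filaments` independent traces from one
#' RNG stream, binding traces and planted events into long tibbles.
#'
#' @inheritParams simulate_filament_trace
#' @param n_filaments Number of filaments.
#' @return List with `traces` (long tibble) and `truth_events` (tibble).
#' @export
simulate_filament_ensemble <- function(n_filaments, params, seed = 0) {
  stopifnot(inherits(params, "filament_kinetics_params"))
  res <- with_seed(seed, {
    lapply(seq_len(n_filaments), function(i) {
      simulate_filament_trace_impl(params, sprintf("fil_%03d", i))
    })
  })
  traces <- do.call(rbind, res)
  attr(traces, "truth_events") <- NULL
  events <- do.call(rbind, lapply(res, attr, "truth_events"))
  list(traces = tibble::as_tibble(traces),
       truth_events = tibble::as_tibble(events))
}
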