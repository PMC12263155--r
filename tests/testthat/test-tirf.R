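test_that("a pure linear trace is one free segment at the generating rate", {
  p <- filament_params(k_attach = 0, length_noise_sd = 0,
                       intensity_noise_sd = 0)
  tr <- simulate_filament_trace(p, seed = 1)
  seg <- segment_trace(tr)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$kind, "free")
  expect_equal(seg$slope_sub_per_s, p$v_free, tolerance = 1e-9)
  expect_tiling(seg, 0, max(tr$time_s))
})

test_that("a planted pause + burst is recovered with sub-frame precision", {
  tr <- single_event_trace(pause_s = 8, run_um = 1.0, burst_rate = 39)
  seg <- segment_trace(tr)
  expect_equal(sum(seg$kind == "pause"), 1L)
  expect_equal(sum(seg$kind == "burst"), 1L)
  ev <- extract_events(seg)
  expect_equal(nrow(ev), 1L)
  # noise-free line intersections recover the exact planted values
  expect_equal(ev$pause_duration_s, 8, tolerance = 0.5)
  expect_equal(ev$burst_rate_sub_per_s, 39, tolerance = 0.5)
  expect_equal(ev$run_length_um, 1.0, tolerance = 0.05)
  expect_false(ev$censored)
  expect_tiling(seg, 0, max(tr$time_s))
})

test_that("pauses shorter than the 5 s minimum are rejected", {
  tr <- single_event_trace(pause_s = 3, run_um = 1.0)
  seg <- segment_trace(tr)
  expect_equal(sum(seg$kind == "pause"), 0L)
  # the burst itself is still found through the intensity channel
  expect_equal(sum(seg$kind == "burst"), 1L)
  ev <- extract_events(seg)
  expect_true(is.na(ev$pause_duration_s))
})

test_that("slopes and lengths respect the 370 subunits/um geometry", {
  tr <- single_event_trace(pause_s = 10, run_um = 1.2, burst_rate = 40)
  seg <- segment_trace(tr, subunits_per_um = 370)
  b <- seg[seg$kind == "burst", ]
  # slope in subunits/s equals 370 x slope of the um-trace fit
  f <- lm(length_um ~ time_s,
          data = tr[tr$time_s > 110 & tr$time_s < 110 + 1.2 * 370 / 40, ])
  expect_equal(b$slope_sub_per_s, 370 * unname(coef(f)[2L]), tolerance = 0.5)
})

test_that("segmentation validates sampling", {
  tr <- single_event_trace(8, 1)
  expect_error(segment_trace(tr[1:5, ]), ">= 8 samples")
  bad <- tr; bad$time_s[10] <- bad$time_s[10] + 0.5
  expect_error(segment_trace(bad), "non-uniform")
})

test_that("bursts reaching the movie end are censored", {
  tt <- seq(0, 100, 2.5)
  t1 <- 60; L <- ifelse(tt <= 50, 10 * tt,
                        ifelse(tt <= t1, 500, 500 + 39 * (tt - t1)))
  tr <- tibble::tibble(filament_id = "f", time_s = tt, length_um = L / 370,
                       intensity_au = ifelse(tt > t1, 0.5, 1))
  seg <- segment_trace(tr)
  ev <- extract_events(seg)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$censored)
  s <- suppressWarnings(event_statistics(ev))
  expect_true(is.na(s$run_length_char))
})

test_that("event statistics handle trivial and empty inputs", {
  ev <- tibble::tibble(filament_id = "f", t_start = c(10, 40, 70),
                       t_end = c(20, 50, 80), pause_duration_s = NA_real_,
                       burst_rate_sub_per_s = 39, run_length_um = 1,
                       burst_r2 = 1, baseline_return = TRUE, censored = FALSE)
  s <- event_statistics(ev)
  # the exponential MLE of the characteristic run length is the sample mean
  expect_equal(s$run_length_char, 1.0)
  expect_equal(s$run_length_mean, 1.0)
  s0 <- event_statistics(ev[0, ])
  expect_equal(s0$n_events, 0L)
  expect_true(is.na(s0$burst_rate_mean))
})

test_that("event recovery on a noisy ensemble meets sensitivity and FDR", {
  p <- filament_params()
  ens <- simulate_filament_ensemble(50, p, seed = 4)
  det <- detect_events(ens$traces)
  # all returned segment sets tile their traces
  ids <- unique(det$segments$filament_id)
  for (id in ids[1:5]) {
    expect_tiling(det$segments[det$segments$filament_id == id, ], 0, 600)
  }
  tru <- ens$truth_events
  floor_idx <- (tru$t_pause_end_s - tru$t_pause_start_s) >= 7.5 &
    tru$run_length_um >= 0.5 & tru$t_burst_end_s <= 600
  m <- match_events(det$events, tru[floor_idx, ])
  expect_gte(m$sensitivity, 0.9)
  mall <- match_events(det$events, tru)
  expect_lte(mall$fdr, 0.1)
})

test_that("no-formin traces with realistic noise yield almost no events", {
  p <- filament_params(k_attach = 0)
  ens <- simulate_filament_ensemble(40, p, seed = 5)
  det <- detect_events(ens$traces)
  expect_lt(nrow(det$events) / 40, 0.05)
})

test_that("gate-corrected capping duration recovers the exponential mean", {
  # memorylessness: mean of detected (> 5 s) exponential pauses sits one
  # gate-width above the generating mean; the corrected estimate removes it
  p <- filament_params()
  ens <- simulate_filament_ensemble(60, p, seed = 6)
  det <- detect_events(ens$traces)
  s <- event_statistics(det$events, ens$traces)
  sem <- 12 / sqrt(s$n_pauses)
  expect_lt(abs(s$pause_mean_s - (12 + 5)), 2 * sem + 2.5)
  expect_lt(abs(s$capping_duration_s - 12), 2 * sem + 2.5)
})
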