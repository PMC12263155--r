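test_that("time_to_fraction inverts a logistic in closed form", {
  # F(t) = 64 / (1 + exp(-(t - 50))) crosses 64/8 = 8 at t = 50 - ln 7
  tr <- logistic_trace(plateau = 64, k = 1, t0 = 50, t_grid = seq(0, 100, 0.5))
  expect_equal(time_to_fraction(tr, smooth_k = 1L), 50 - log(7),
               tolerance = 0.05)
  # the half-completion time of a symmetric logistic is its midpoint
  expect_equal(time_to_fraction(tr, fraction = 0.5, smooth_k = 1L), 50,
               tolerance = 0.02)
})

test_that("time_to_fraction rejects degenerate traces", {
  flat <- tibble::tibble(time_s = seq(0, 100, 1), signal_au = rep(3, 101))
  expect_error(time_to_fraction(flat), "plateau|incomplete")
  # still rising at the end: plateau cannot be read off the trace
  rising <- logistic_trace(64, k = 0.05, t0 = 100, t_grid = seq(0, 80, 0.5))
  expect_error(time_to_fraction(rising), "plateau")
  # explicit plateau rescues the rising trace
  expect_silent(time_to_fraction(rising, plateau = 64))
})

test_that("slope_at_time recovers exact and analytic slopes", {
  lin <- tibble::tibble(time_s = seq(0, 100, 2), signal_au = 0.5 * seq(0, 100, 2) + 3)
  expect_equal(slope_at_time(lin, 50), 0.5, tolerance = 1e-12)
  expect_equal(slope_at_time(lin, 10), 0.5, tolerance = 1e-12)
  flat <- tibble::tibble(time_s = seq(0, 100, 2), signal_au = rep(2, 51))
  expect_equal(slope_at_time(flat, 50), 0, tolerance = 1e-12)
  expect_error(slope_at_time(lin, 50, window_s = 2), "fewer than 4")

  # logistic identity: dF/dt at F = P/8 equals 7kP/64; holds through the
  # empirical pipeline when the regression window is local on the curve
  k <- 0.01; P <- 6400
  tr <- logistic_trace(P, k, t0 = 1200, t_grid = seq(0, 2500, 0.5))
  t18 <- time_to_fraction(tr, smooth_k = 1L)
  expect_equal(slope_at_time(tr, t18), 7 * k * P / 64, tolerance = 0.02)
})

test_that("nucleation strength is the slope of per-dose slopes vs dose", {
  # three doses whose slopes lie exactly on 0.1 + 0.32 * dose
  fx <- simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = c(0, 5, 10),
                   slope_au_per_s = c(0.10, 1.70, 3.30)),
    plateau = 457 * c(0.10, 1.70, 3.30), t_grid = seq(0, 1200, 0.5)
  )
  res <- nucleation_strength(fx)
  expect_equal(res$strength, 0.32, tolerance = 0.01)
  expect_equal(res$intercept, 0.10, tolerance = 0.02)
  expect_equal(nrow(res$per_dose), 3L)
  expect_true(all(res$per_dose$t_one_eighth_s > 0))
})

test_that("identical per-dose slopes give zero strength", {
  fx <- simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = c(0, 5, 10), slope_au_per_s = rep(2, 3)),
    plateau = 457 * 2, t_grid = seq(0, 1200, 0.5)
  )
  expect_equal(nucleation_strength(fx)$strength, 0, tolerance = 1e-6)
})

test_that("nucleation_strength validates input and names failing traces", {
  fx <- simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = c(0, 5), slope_au_per_s = c(1, 2)),
    plateau = 457 * c(1, 2), t_grid = seq(0, 1200, 0.5)
  )
  expect_error(nucleation_strength(fx), ">= 3 distinct")
  bad <- tibble::tibble(trace_id = c("a", "a", "a", "b", "b", "b", "c", "c", "c"),
                        formin_nM = rep(c(0, 5, 10), each = 3),
                        time_s = rep(c(0, 1, 2), 3),
                        signal_au = c(1, 1, 1, 1, 1, 1, 1, 1, 1))
  expect_error(nucleation_strength(bad), "trace 'a'")
})

test_that("initial_rate regresses over the first 90 s only", {
  t <- seq(0, 200, 1)
  lin <- tibble::tibble(time_s = t, signal_au = 2 * t)
  expect_equal(initial_rate(lin), 2, tolerance = 1e-12)
  # linear for 90 s then flat: the window excludes the flat part
  kink <- tibble::tibble(time_s = t, signal_au = pmin(2 * t, 180))
  expect_equal(initial_rate(kink), 2, tolerance = 1e-12)
  short <- tibble::tibble(time_s = seq(0, 50, 1), signal_au = 2 * seq(0, 50, 1))
  expect_warning(r <- initial_rate(short), "spans only")
  expect_equal(r, 2, tolerance = 1e-12)
})

test_that("rate normalization is per-control, preserves acceleration", {
  rates <- tibble::tibble(formin_nM = c(0, 1, 2), rate = c(4, 1, 6))
  out <- normalize_rates(rates, 4)
  expect_equal(out$r, c(1, 0.25, 1.5))
  # idempotence: normalizing already-normalized rates with control 1
  out2 <- normalize_rates(tibble::tibble(formin_nM = out$formin_nM, rate = out$r), 1)
  expect_equal(out2$r, out$r)
  expect_error(normalize_rates(rates, 0), "positive")
})
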