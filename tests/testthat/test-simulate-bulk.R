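test_that("bulk simulator conserves actin and orders doses correctly", {
  p <- bulk_params()
  doses <- c(0, 7.5, 30, 60)
  tb <- simulate_bulk_assembly(p, doses, seq(0, 4000, 10))
  st <- attr(tb, "state")
  for (s in st) {
    total <- s$monomer_uM + s$polymer_uM + 3 * s$nuclei_uM
    expect_lt(max(abs(total - p$actin_total)) / p$actin_total, 1e-6)
  }
  half <- vapply(doses, function(f) {
    time_to_fraction(tb[tb$formin_nM == f, ], fraction = 0.5)
  }, numeric(1))
  # more formin nucleation -> earlier half-times
  expect_true(all(diff(half[-1L]) < 0))
  expect_gt(half[1L], half[2L])
  # capping artifact: plateau decreases with dose
  finals <- vapply(doses, function(f) {
    max(tb$signal_au[tb$formin_nM == f])
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
  # noise-free traces are monotone non-decreasing
  for (f in doses) {
    expect_true(all(diff(tb$signal_au[tb$formin_nM == f]) >= -1e-9))
  }
})

test_that("no nucleation pathway means no polymer", {
  p <- bulk_params(k_nuc_spont = 0)
  tb <- simulate_bulk_assembly(p, 0, seq(0, 500, 5))
  expect_equal(max(tb$signal_au), p$signal_offset, tolerance = 1e-12)
})

test_that("bulk simulator is deterministic under a fixed seed", {
  p <- bulk_params()
  a <- simulate_bulk_assembly(p, c(0, 30), seq(0, 500, 5), noise_sd = 2, seed = 7)
  b <- simulate_bulk_assembly(p, c(0, 30), seq(0, 500, 5), noise_sd = 2, seed = 7)
  expect_identical(a$signal_au, b$signal_au)
  c2 <- simulate_bulk_assembly(p, c(0, 30), seq(0, 500, 5), noise_sd = 2, seed = 8)
  expect_false(identical(a$signal_au, c2$signal_au))
})

test_that("bulk simulator validates inputs", {
  p <- bulk_params()
  expect_error(simulate_bulk_assembly(p, -1, seq(0, 10, 1)), ">= 0")
  expect_error(simulate_bulk_assembly(p, 0, c(0, 2, 1)), "increasing")
  expect_error(simulate_bulk_assembly(p, 0, c(1, 2, 3)), "start at 0")
  expect_error(bulk_params(critical_conc = 5), "below actin_total")
  expect_error(bulk_params(k_elong_plus = -1), "k_elong_plus")
})

test_that("logistic fixtures hit the requested slope at one-eighth exactly", {
  # plateau 64, slope 7 -> k = 1; analytic dF/dt at F = 8 is 7
  fx <- simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = 0, slope_au_per_s = 7),
    plateau = 64, t_grid = seq(0, 40, 0.01)
  )
  gen <- attr(fx, "logistic")
  expect_equal(gen$k, 1)
  # analytic derivative of the generated curve, dF/dt = k F (1 - F/P),
  # evaluated at the grid point nearest the plateau/8 crossing
  t_cross <- gen$t0 - log(7) / gen$k
  i <- which.min(abs(fx$time_s - t_cross))
  F_i <- fx$signal_au[i]
  expect_equal(F_i, 8, tolerance = 0.01)
  expect_equal(gen$k * F_i * (1 - F_i / 64), 7, tolerance = 0.01)
})

test_that("fixture round-trips through the slope pipeline", {
  s <- 0.8
  fx <- simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = 0, slope_au_per_s = s),
    plateau = 457 * s, t_grid = seq(0, 1200, 0.5)
  )
  t18 <- time_to_fraction(fx)
  expect_equal(slope_at_time(fx, t18), s, tolerance = 0.01)
})

test_that("fixture builder handles edge cases", {
  empty <- simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = numeric(), slope_au_per_s = numeric()),
    plateau = 64, t_grid = seq(0, 10, 1)
  )
  expect_equal(nrow(empty), 0L)
  expect_error(simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = 0, slope_au_per_s = 1), plateau = 0,
    t_grid = seq(0, 10, 1)), "plateau")
  expect_error(simulate_bulk_from_slopes(
    tibble::tibble(formin_nM = 0, slope_au_per_s = -1), plateau = 64,
    t_grid = seq(0, 10, 1)), "slopes")
})

test_that("seeded traces start at v0 * r(F) and flatten concavely", {
  B <- 0.1; kd <- 0.5; a <- 1; b <- -4.5
  F <- c(0, 1000 * kd)
  tr <- simulate_seeded_elongation(kd, a, b, B, F, v0 = 2)
  # F = 0: initial slope v0 * a
  expect_equal(initial_rate(tr[tr$formin_nM == 0, ]), 2 * a, tolerance = 0.02)
  # F >> kd: initial slope -> v0 (a + 2 b B)
  expect_equal(initial_rate(tr[tr$formin_nM == 1000 * kd, ]),
               2 * (a + 2 * b * B), tolerance = 0.02)
  # non-decreasing and concave after the initial regime
  s0 <- tr$signal_au[tr$formin_nM == 0]
  expect_true(all(diff(s0) > 0))
  expect_true(all(diff(diff(s0)) < 1e-9))
})

test_that("seeded pipeline round-trips kd within 1% on noise-free data", {
  kd <- 0.028
  F <- c(0, 0.1 * kd * 2^(0:10))
  tr <- simulate_seeded_elongation(kd, 1, -4.5, 0.1, F)
  rates <- do.call(rbind, lapply(unique(tr$trace_id), function(id) {
    d <- tr[tr$trace_id == id, ]
    tibble::tibble(formin_nM = d$formin_nM[1L], rate = initial_rate(d))
  }))
  norm <- normalize_rates(rates, rates$rate[rates$formin_nM == 0])
  fit <- fit_barbed_end_affinity(norm, 0.1)
  expect_equal(fit$kd_nM, kd, tolerance = 0.01)
})

test_that("short seeded assays warn about the truncated window", {
  expect_warning(
    simulate_seeded_elongation(1, 1, -4.5, 0.1, 0, duration = 60),
    "90 s"
  )
})
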