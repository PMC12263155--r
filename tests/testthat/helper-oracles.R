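# Independent oracles and fixture builders shared across tests.

# Exhaustive 3-D grid search for the quadratic-binding fit. The residual sum
# of squares is expanded in sufficient statistics so the full (kd, a, b) grid
# is evaluated exactly but cheaply: for fixed kd the model is linear in
# (a, b), and SS(a, b) = Srr - 2a Sr - 2b Srg + a^2 n + 2ab Sg + b^2 Sgg.
grid_search_binding <- function(formin_nM, r, barbed_ends_nM,
                                kd_grid, a_grid, b_grid) {
  n <- length(r)
  Srr <- sum(r^2)
  Sr <- sum(r)
  best <- list(ss = Inf)
  A <- matrix(a_grid, length(a_grid), length(b_grid))
  B <- matrix(b_grid, length(a_grid), length(b_grid), byrow = TRUE)
  for (kd in kd_grid) {
    s <- barbed_ends_nM + formin_nM + kd
    g <- s - sqrt(pmax(s^2 - 4 * barbed_ends_nM * formin_nM, 0))
    Sg <- sum(g); Sgg <- sum(g^2); Srg <- sum(r * g)
    ss <- Srr - 2 * A * Sr - 2 * B * Srg + A^2 * n + 2 * A * B * Sg + B^2 * Sgg
    i <- arrayInd(which.min(ss), dim(ss))
    if (ss[i] < best$ss) {
      best <- list(ss = ss[i], kd = kd, a = a_grid[i[1L]], b = b_grid[i[2L]])
    }
  }
  best
}

# Single logistic assembly trace with known plateau, steepness, midpoint.
logistic_trace <- function(plateau, k, t0, t_grid, formin_nM = 0,
                           trace_id = "logi") {
  tibble::tibble(trace_id = trace_id, formin_nM = formin_nM, time_s = t_grid,
                 signal_au = plateau / (1 + exp(-k * (t_grid - t0))))
}

# Noise-free filament trace with one planted pause + burst, on the default
# 2.5 s cadence; free rate 10 subunits/s, burst as specified.
single_event_trace <- function(pause_s, run_um, burst_rate = 39,
                               v_free = 10, t_event = 100, t_max = 250,
                               dt = 2.5, dim_factor = 0.5) {
  tt <- seq(0, t_max, dt)
  t1 <- t_event + pause_s
  dur <- run_um * 370 / burst_rate
  t2 <- t1 + dur
  L <- vapply(tt, function(t) {
    if (t <= t_event) v_free * t
    else if (t <= t1) v_free * t_event
    else if (t <= t2) v_free * t_event + burst_rate * (t - t1)
    else v_free * t_event + burst_rate * dur + v_free * (t - t2)
  }, numeric(1))
  tibble::tibble(filament_id = "fix", time_s = tt, length_um = L / 370,
                 intensity_au = ifelse(tt > t1 & tt < t2, dim_factor, 1))
}

# Mean of a normal truncated from below (the generating burst-rate mean).
truncnorm_mean <- function(mu, sigma, lower) {
  alpha <- (lower - mu) / sigma
  mu + sigma * dnorm(alpha) / (1 - pnorm(alpha))
}

expect_tiling <- function(segments, t0, t1) {
  expect_equal(segments$t_start[1L], t0)
  expect_equal(segments$t_end[nrow(segments)], t1)
  if (nrow(segments) > 1L) {
    expect_equal(segments$t_start[-1L], segments$t_end[-nrow(segments)],
                 tolerance = 1e-9)
  }
  expect_true(all(segments$t_end > segments$t_start))
}
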