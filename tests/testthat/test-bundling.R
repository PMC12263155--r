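test_that("fraction pelleted is the pellet share in percent", {
  expect_equal(fraction_pelleted(80, 20), 80)
  expect_equal(fraction_pelleted(0, 5), 0)
  expect_equal(fraction_pelleted(5, 0), 100)
  expect_error(fraction_pelleted(0, 0), "both")
  expect_error(fraction_pelleted(-1, 2), "non-negative")
  # scale invariance and bounds
  set.seed(1)
  p <- runif(50, 0, 100); s <- runif(50, 0, 100)
  expect_equal(fraction_pelleted(p, s), fraction_pelleted(7.3 * p, 7.3 * s))
  f <- fraction_pelleted(p, s)
  expect_true(all(f >= 0 & f <= 100))
  # pellet-vs-total-load variant
  expect_equal(fraction_pelleted(30, 999, total_load_au = 60), 50)
})

test_that("noise-free gels round-trip planted fractions exactly", {
  curve <- tibble::tibble(formin_nM = c(0, 15, 60),
                          true_fraction = c(0.05, 0.35, 0.817))
  g <- simulate_cosedimentation(curve, noise_cv = 0)
  p <- g$intensity_au[g$band == "pellet"]
  s <- g$intensity_au[g$band == "supernatant"]
  expect_equal(fraction_pelleted(p, s), 100 * curve$true_fraction)
  # a 50/50 lane has equal bands
  g2 <- simulate_cosedimentation(
    tibble::tibble(formin_nM = 1, true_fraction = 0.5), noise_cv = 0)
  expect_equal(g2$intensity_au[1L], g2$intensity_au[2L])
  expect_error(simulate_cosedimentation(
    tibble::tibble(formin_nM = 0, true_fraction = 1.2)), "0, 1")
})

test_that("bundling curve summarizes replicates and flags anomalies", {
  curve <- tibble::tibble(formin_nM = c(0, 15, 60),
                          true_fraction = c(0.05, 0.35, 0.817))
  # identical replicates -> zero SD
  g0 <- simulate_cosedimentation(curve, noise_cv = 0, n_replicates = 3)
  r0 <- bundling_curve(g0)
  expect_equal(r0$per_dose$sd_pct, rep(0, 3))
  expect_equal(r0$reference_pct_mean, 81.7, tolerance = 1e-9)
  # single replicate: SD absent and flagged
  g1 <- simulate_cosedimentation(curve, noise_cv = 0, n_replicates = 1)
  r1 <- bundling_curve(g1)
  expect_true(all(is.na(r1$per_dose$sd_pct)))
  expect_true("single_replicate" %in% r1$flags)
  # noisy replicates recover the planted curve within 2 SD
  g3 <- simulate_cosedimentation(curve, noise_cv = 0.05, n_replicates = 3,
                                 seed = 2)
  r3 <- bundling_curve(g3)
  for (i in 1:3) {
    tol <- max(2 * r3$per_dose$sd_pct[i], 1)
    expect_lt(abs(r3$per_dose$mean_pct[i] - 100 * curve$true_fraction[i]), tol)
  }
})

test_that("mismatched replicate dose grids are rejected", {
  g <- rbind(
    simulate_cosedimentation(tibble::tibble(formin_nM = c(0, 10),
                                            true_fraction = c(0.1, 0.5)),
                             noise_cv = 0),
    within(simulate_cosedimentation(tibble::tibble(formin_nM = c(0, 20),
                                                   true_fraction = c(0.1, 0.5)),
                                    noise_cv = 0), gel_id <- "gel_02")
  )
  expect_error(bundling_curve(g), "mismatched")
})

test_that("a clearly non-monotone dose response is flagged", {
  curve <- tibble::tibble(formin_nM = c(0, 15, 30, 60),
                          true_fraction = c(0.1, 0.7, 0.2, 0.8))
  g <- simulate_cosedimentation(curve, noise_cv = 0.02, n_replicates = 3,
                                seed = 3)
  expect_true("non_monotone" %in% bundling_curve(g)$flags)
})
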