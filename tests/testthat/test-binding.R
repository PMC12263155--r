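test_that("quadratic binding rate matches hand arithmetic and limits", {
  # B = F = kd = 0.1: r = 1 - 5 (0.3 - sqrt 0.05) = 0.618034
  expect_equal(quadratic_binding_rate(0.1, 0.1, 0.1, 1, -5),
               1 - 5 * (0.3 - sqrt(0.05)), tolerance = 1e-12)
  expect_equal(quadratic_binding_rate(0.1, 0.1, 0.1, 1, -5), 0.618034,
               tolerance = 1e-6)
  # r(0) = a exactly, for any B and kd
  for (B in c(0.01, 0.1, 1)) {
    for (kd in c(0.01, 1, 100)) {
      expect_identical(quadratic_binding_rate(0, B, kd, 1.3, -2), 1.3)
    }
  }
  # saturation: r -> a + 2bB
  expect_equal(quadratic_binding_rate(1e6 * 0.1, 0.1, 0.1, 1, -5),
               1 + 2 * (-5) * 0.1, tolerance = 1e-3)
  expect_error(quadratic_binding_rate(-1, 0.1, 0.1, 1, -5), "non-negative")
})

test_that("r(F) is monotone decreasing for b < 0", {
  F <- c(0, 10^seq(-3, 2, length.out = 40))
  r <- quadratic_binding_rate(F, 0.1, 0.5, 1, -4.5)
  expect_true(all(diff(r) < 0))
})

test_that("affinity fit recovers noise-free parameters and matches the grid oracle", {
  kd <- 1.0; B <- 0.1; a <- 1; b <- -4.5
  F <- c(0, 0.03 * 2^(0:11))   # twofold series 0.03-61 nM
  r <- quadratic_binding_rate(F, B, kd, a, b)
  fit <- fit_barbed_end_affinity(tibble::tibble(formin_nM = F, r = r), B)
  expect_equal(fit$kd_nM, kd, tolerance = 0.02)
  expect_equal(fit$a, a, tolerance = 1e-3)
  expect_equal(fit$b, b, tolerance = 1e-2)
  expect_length(fit$flags, 0L)

  gr <- grid_search_binding(F, r, B, kd_grid = seq(0.5, 1.5, length.out = 201),
                            a_grid = seq(0.9, 1.1, length.out = 101),
                            b_grid = seq(-5, -4, length.out = 101))
  expect_equal(fit$kd_nM, gr$kd, tolerance = 0.005 + 1e-8)
})

test_that("fitter matches exhaustive grid search on random noise-free draws", {
  set.seed(11)
  for (i in 1:20) {
    kd <- 10^runif(1, -2, 1)
    a <- runif(1, 0.8, 1.2)
    b <- runif(1, -6, -2)
    B <- 0.1
    F <- c(0, 0.1 * kd * 2^(0:10))
    r <- quadratic_binding_rate(F, B, kd, a, b)
    fit <- fit_barbed_end_affinity(tibble::tibble(formin_nM = F, r = r), B)
    kd_grid <- kd * seq(0.8, 1.2, length.out = 201)  # resolution 0.2% of kd
    gr <- grid_search_binding(F, r, B, kd_grid,
                              a_grid = a * seq(0.95, 1.05, length.out = 81),
                              b_grid = b * seq(1.1, 0.9, length.out = 81))
    expect_equal(fit$kd_nM, gr$kd, tolerance = 0.004)
  }
})

test_that("flat dose response flags an unidentifiable kd", {
  F <- c(0, 0.1 * 2^(0:8))
  fit <- suppressWarnings(
    fit_barbed_end_affinity(tibble::tibble(formin_nM = F, r = rep(1, length(F))), 0.1)
  )
  expect_true(any(c("kd_at_bound", "kd_unidentifiable") %in% fit$flags))
})

test_that("kd recovery under 5% noise stays within 15% median error", {
  # three replicates per construct across the observed affinity range
  set.seed(21)
  kds <- c(0.028, 0.218, 0.470, 0.750, 4.9)
  rel_err <- unlist(lapply(kds, function(kd) {
    F <- c(0, 0.1 * kd * 2^(0:10))
    r0 <- quadratic_binding_rate(F, 0.1, kd, 1, -4.5)
    vapply(1:3, function(rep) {
      r <- r0 * (1 + rnorm(length(r0), 0, 0.05))
      fit <- suppressWarnings(
        fit_barbed_end_affinity(tibble::tibble(formin_nM = F, r = r), 0.1)
      )
      abs(fit$kd_nM - kd) / kd
    }, numeric(1))
  }))
  expect_lt(median(rel_err), 0.15)
})

test_that("fit requires enough informative points", {
  expect_error(fit_barbed_end_affinity(
    tibble::tibble(formin_nM = c(0, 1, 2), r = c(1, 0.5, 0.3)), 0.1),
    ">= 4 points")
  expect_warning(fit_barbed_end_affinity(
    tibble::tibble(formin_nM = c(0, 1, 1.5, 2, 3), r = quadratic_binding_rate(
      c(0, 1, 1.5, 2, 3), 0.1, 1, 1, -4.5)), 0.1),
    "decade")
})
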