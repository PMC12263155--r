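test_that("tail trimming follows the floor(0.025 n) rule exactly", {
  x40 <- rnorm(40)
  t40 <- trim_outliers(x40)
  expect_equal(t40$k, 1L)                       # floor(0.025 * 40) = 1
  expect_equal(length(t40$trimmed), 38L)
  expect_equal(sort(t40$trimmed), sort(x40)[2:39])
  expect_equal(trim_outliers(rnorm(20))$k, 0L)  # threshold is "exceeds 20"
  expect_equal(trim_outliers(rnorm(21))$k, 0L)  # floor(0.525) = 0
  expect_equal(length(trim_outliers(rnorm(21))$trimmed), 21L)
  # never removes more than 5% of the sample, any n
  for (n in c(25, 40, 80, 200, 1000)) {
    expect_lte(2L * trim_outliers(rnorm(n))$k, 0.05 * n)
  }
  # original sample kept alongside for plotting
  expect_identical(t40$original, x40)
})

test_that("normality gate selects the right test", {
  set.seed(31)
  r <- compare_two(rlnorm(50, sdlog = 1.5), rlnorm(50, sdlog = 1.5))
  expect_equal(r$test_used, "mann_whitney_u")
  r2 <- compare_two(rnorm(30), rnorm(30))
  expect_equal(r2$test_used, "t_two_sample_unpaired")
  # extreme separation is significant whatever the path
  r3 <- compare_two(rnorm(20), rnorm(20) + 10)
  expect_true(r3$significant)
  # constant group cannot be normal; falls through to Mann-Whitney
  r4 <- suppressWarnings(compare_two(rep(1, 10), rnorm(10)))
  expect_equal(r4$test_used, "mann_whitney_u")
})

test_that("bonferroni correction and overrides are applied", {
  set.seed(32)
  a <- rnorm(25); b <- rnorm(25) + 0.8
  r1 <- compare_two(a, b, stat_plan(family_size = 1))
  r4 <- compare_two(a, b, stat_plan(family_size = 4))
  expect_equal(r4$alpha_corrected, 0.0125)
  expect_equal(r1$p_value, r4$p_value)
  expect_identical(r4$significant, r4$p_value < 0.0125)
  rf <- compare_two(a, b, stat_plan(force_test = "mann_whitney_u"))
  expect_equal(rf$test_used, "mann_whitney_u")
  expect_error(compare_two(c(1, 2), rnorm(10)), ">= 3")
})

test_that("the gated procedure controls type-I error near nominal", {
  set.seed(42)
  rej <- vapply(seq_len(2000), function(i) {
    compare_two(rnorm(30), rnorm(30))$significant
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("the decision path is a pure function of the data", {
  set.seed(33)
  a <- rnorm(24); b <- rlnorm(24)
  r1 <- compare_two(a, b)
  r2 <- compare_two(a, b)
  expect_identical(r1, r2)
})

test_that("ANOVA + Tukey reports all pairs with adjusted p-values", {
  set.seed(34)
  g <- list(ctrl = rnorm(20), low = rnorm(20), high = rnorm(20) + 5)
  res <- compare_many(g)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$test_used == "anova_tukey"))
  sig <- res$significant[order(res$comparison)]
  names(sig) <- sort(res$comparison)
  expect_true(sig[["high-ctrl"]])
  expect_true(sig[["low-high"]] || sig[["high-low"]])
  expect_false(sig[["low-ctrl"]])
  expect_lt(attr(res, "anova_p"), 0.001)
  # identical groups: omnibus p near 1, nothing significant
  g0 <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  r0 <- compare_many(g0)
  expect_false(any(r0$significant))
  expect_gt(attr(r0, "anova_p"), 0.99)
  expect_error(compare_many(list(a = rnorm(5), b = rnorm(5))), "compare_two")
})

test_that("Tukey controls the family-wise false-positive rate", {
  set.seed(35)
  fp <- vapply(seq_len(1000), function(i) {
    any(compare_many(list(a = rnorm(15), b = rnorm(15), c = rnorm(15)))$significant)
  }, logical(1))
  expect_lte(mean(fp), 0.07)
})
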