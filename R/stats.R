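#' Trim tail outliers from a sample
#'
#' For samples larger than 20, removes the `floor(0.025 * n)` smallest and
#' largest values before statistical testing (the trimming is for tests only;
#' plots keep all points, so the original sample is returned alongside).
#' Samples of 20 or fewer -- and sizes where the floor is zero, such as
#' n = 21 -- are returned unchanged.
#'
#' @param x Numeric sample.
#' @param trim_fraction Per-tail trim fraction, default 0.025.
#' @param n_threshold Trimming applies only when `length(x)` exceeds this.
#' @return List with `trimmed`, `original`, and `k` (values removed per tail).
#' @export
trim_outliers <- function(x, trim_fraction = 0.025, n_threshold = 20L) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort_input("trim_fraction must be in [0, 0.5)")
  }
  n <- length(x)
  k <- if (n > n_threshold) floor(trim_fraction * n) else 0L
  trimmed <- if (k > 0L) sort(x)[(k + 1L):(n - k)] else x
  list(trimmed = trimmed, original = x, k = as.integer(k))
}

#' Plan for a gated group comparison
#'
#' @param family_size Number of pairwise comparisons in the family; the
#'   Bonferroni-corrected alpha is `alpha / family_size`.
#' @param alpha Base significance level.
#' @param trim_fraction Per-tail outlier trim (applied when n > 20).
#' @param shapiro_alpha Level of the Shapiro-Wilk normality gate.
#' @param force_test Optional override: `"t_two_sample_unpaired"` or
#'   `"mann_whitney_u"` skips the normality gate.
#' @return List of class `stat_plan`.
#' @export
stat_plan <- function(family_size = 1L, alpha = 0.05, trim_fraction = 0.025,
                      shapiro_alpha = 0.05, force_test = NULL) {
  if (family_size < 1L) abort_input("family_size must be >= 1")
  if (!is.null(force_test) &&
      !force_test %in% c("t_two_sample_unpaired", "mann_whitney_u")) {
    abort_input("force_test must be t_two_sample_unpaired or mann_whitney_u")
  }
  structure(list(family_size = as.integer(family_size), alpha = alpha,
                 trim_fraction = trim_fraction, shapiro_alpha = shapiro_alpha,
                 force_test = force_test),
            class = "stat_plan")
}

shapiro_p <- function(x, alpha) {
  # constant samples are trivially non-normal for gating purposes
  if (length(unique(x)) < 3L) return(0)
  if (length(x) > 5000L) x <- sample(x, 5000L)
  stats::shapiro.test(x)$p.value
}

#' Gated two-group comparison
#'
#' The decision tree used for pairwise comparisons: trim tail outliers when
#' n > 20, gate on Shapiro-Wilk normality in each group, then Student's
#' two-sample unpaired t-test if both groups pass, otherwise the
#' Mann-Whitney U test; significance is judged against the
#' Bonferroni-corrected alpha `alpha / family_size`.
#'
#' @param group_a,group_b Numeric samples (n >= 3 after trimming).
#' @param plan A [stat_plan()].
#' @param comparison Label stored in the result.
#' @return Tibble row of class `stat_result` with `comparison`, `test_used`,
#'   `statistic`, `p_value`, `alpha_corrected`, `significant`,
#'   `n_a`, `n_b`, `n_trimmed_a`, `n_trimmed_b`, `normality_p_a`,
#'   `normality_p_b`.
#' @export
compare_two <- function(group_a, group_b, plan = stat_plan(),
                        comparison = "A vs B") {
  stopifnot(inherits(plan, "stat_plan"))
  ta <- trim_outliers(group_a, plan$trim_fraction)
  tb <- trim_outliers(group_b, plan$trim_fraction)
  a <- ta$trimmed; b <- tb$trimmed
  if (length(a) < 3L || length(b) < 3L) {
    abort_input("each group needs >= 3 values after trimming")
  }
  pa <- shapiro_p(a, plan$shapiro_alpha)
  pb <- shapiro_p(b, plan$shapiro_alpha)
  test_used <- plan$force_test %||%
    (if (pa >= plan$shapiro_alpha && pb >= plan$shapiro_alpha) {
      "t_two_sample_unpaired"
    } else "mann_whitney_u")

  if (test_used == "t_two_sample_unpaired") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
  }
  alpha_c <- plan$alpha / plan$family_size
  out <- tibble::tibble(
    comparison = comparison, test_used = test_used,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    alpha_corrected = alpha_c, significant = ht$p.value < alpha_c,
    n_a = length(a), n_b = length(b),
    n_trimmed_a = 2L * ta$k, n_trimmed_b = 2L * tb$k,
    normality_p_a = pa, normality_p_b = pb
  )
  class(out) <- c("stat_result", class(out))
  out
}

#' One-way ANOVA with post hoc Tukey comparisons
#'
#' For three or more groups: tail-trims each group, runs a one-way ANOVA, and
#' reports every pairwise comparison with Tukey honest-significant-difference
#' adjusted p-values (Tukey already controls the family-wise error rate, so
#' no further Bonferroni correction is applied on this path).
#'
#' @param groups Named list of numeric samples (>= 3 groups, each n >= 3
#'   after trimming).
#' @param plan A [stat_plan()] (`alpha` and `trim_fraction` are used).
#' @return Tibble with one row per pair: `comparison`, `test_used`,
#'   `statistic` (mean difference), `p_value` (Tukey-adjusted),
#'   `alpha_corrected`, `significant`; ANOVA omnibus F and p in attributes
#'   `"anova_F"` and `"anova_p"`.
#' @export
compare_many <- function(groups, plan = stat_plan()) {
  stopifnot(inherits(plan, "stat_plan"))
  if (!is.list(groups) || length(groups) < 3L) {
    abort_input("need >= 3 groups; use compare_two() for two groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  trimmed <- lapply(groups, function(g) trim_outliers(g, plan$trim_fraction)$trimmed)
  if (any(vapply(trimmed, length, integer(1)) < 3L)) {
    abort_input("each group needs >= 3 values after trimming")
  }
  df <- data.frame(
    value = unlist(trimmed, use.names = FALSE),
    group = factor(rep(names(trimmed), vapply(trimmed, length, integer(1))))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - plan$alpha)$group
  out <- tibble::tibble(
    comparison = rownames(tuk), test_used = "anova_tukey",
    statistic = unname(tuk[, "diff"]), p_value = unname(tuk[, "p adj"]),
    alpha_corrected = plan$alpha,
    significant = unname(tuk[, "p adj"]) < plan$alpha
  )
  attr(out, "anova_F") <- an[["F value"]][1L]
  attr(out, "anova_p") <- an[["Pr(>F)"]][1L]
  out
}
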