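#' Simulate co-sedimentation (bundling) gel densitometry
#'
#' Low-speed co-sedimentation separates bundled actin (pellet) from single
#' filaments (supernatant); equal-volume loading makes the pellet share of the
#' two band intensities an estimate of the fraction of actin bundled. Each
#' simulated lane draws a total intensity `total_intensity x LogNormal`
#' (unit mean, coefficient of variation `noise_cv`) and splits it between
#' pellet and supernatant with expected pellet share equal to the planted
#' fraction (Beta-distributed share with matching coefficient of variation;
#' exact split when `noise_cv = 0`).
#'
#' @param fraction_curve Data frame with `formin_nM` and `true_fraction`
#'   columns; fractions between 0 and 1.
#' @param total_intensity Expected per-lane total band intensity (a.u.).
#' @param noise_cv Coefficient of variation of the lane noise.
#' @param n_replicates Number of replicate gels.
#' @param seed RNG seed.
#' @return Long tibble with `gel_id`, `lane`, `formin_nM`, `band`
#'   (`"pellet"`/`"supernatant"`), `intensity_au`.
#' @export
simulate_cosedimentation <- function(fraction_curve, total_intensity = 1000,
                                     noise_cv = 0.05, n_replicates = 1,
                                     seed = 0) {
  if (!all(c("formin_nM", "true_fraction") %in% names(fraction_curve))) {
    abort_input("fraction_curve must have columns formin_nM and true_fraction")
  }
  f <- fraction_curve$true_fraction
  if (any(f < 0 | f > 1)) abort_input("true_fraction must be in [0, 1]")
  assert_scalar_num(noise_cv, "noise_cv", lo = 0)

  sdlog <- sqrt(log(1 + noise_cv^2))
  draw_share <- function(fi) {
    if (noise_cv == 0 || fi == 0 || fi == 1) return(fi)
    # Beta with mean fi and sd ~ noise_cv * fi (capped by the Beta support)
    target_sd <- min(noise_cv * fi, 0.9 * sqrt(fi * (1 - fi)))
    nu <- fi * (1 - fi) / target_sd^2 - 1
    stats::rbeta(1L, fi * nu, (1 - fi) * nu)
  }

  with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_replicates)) {
      for (i in seq_along(f)) {
        total <- if (noise_cv > 0) {
          total_intensity * stats::rlnorm(1L, -sdlog^2 / 2, sdlog)
        } else total_intensity
        share <- draw_share(f[i])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gel_id = sprintf("gel_%02d", g), lane = i,
          formin_nM = rep(fraction_curve$formin_nM[i], 2L),
          band = c("pellet", "supernatant"),
          intensity_au = c(total * share, total * (1 - share))
        )
      }
    }
    do.call(rbind, rows)
  })
}
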