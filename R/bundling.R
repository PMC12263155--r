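#' Percentage of actin pelleted from two band intensities
#'
#' Equal-volume loading of pellet and supernatant lanes makes the pellet
#' share of the summed band intensities the fraction of actin pelleted:
#' `100 * pellet / (pellet + supernatant)`. Scale-invariant in the two
#' intensities.
#'
#' @param pellet_au,supernatant_au Background-corrected band intensities
#'   (vectorized; both non-negative, not both zero).
#' @param total_load_au Optional total-load band intensity; when supplied the
#'   pellet-vs-total variant `100 * pellet / total_load` is returned instead.
#' @return Percent actin pelleted, bounded between 0 and 100.
#' @export
fraction_pelleted <- function(pellet_au, supernatant_au, total_load_au = NULL) {
  if (any(pellet_au < 0) || any(supernatant_au < 0)) {
    abort_input("band intensities must be non-negative")
  }
  if (!is.null(total_load_au)) {
    if (any(total_load_au <= 0)) abort_input("total_load_au must be positive")
    return(100 * pellet_au / total_load_au)
  }
  tot <- pellet_au + supernatant_au
  if (any(tot == 0)) abort_input("pellet and supernatant cannot both be zero")
  100 * pellet_au / tot
}

#' Bundling dose-response from replicated co-sedimentation gels
#'
#' Computes per-dose percent actin pelleted for each replicate gel and
#' summarizes mean and SD across replicates, flagging single-replicate doses
#' (no SD) and dose responses that are non-monotone beyond noise.
#'
#' @param gels Long tibble as produced by [simulate_cosedimentation()] or
#'   [read_traces()] with schema `"gel"`: columns `gel_id`, `formin_nM`,
#'   `band` (`"pellet"`/`"supernatant"`), `intensity_au`. All replicates must
#'   share the same dose grid.
#' @param reference_dose_nM Dose at which the headline summary is reported
#'   (default: the highest dose present).
#' @return List of class `bundling_result`: `per_dose` tibble
#'   (`formin_nM`, `mean_pct`, `sd_pct`, `n`), `reference_dose_nM`,
#'   `reference_pct_mean`, `reference_pct_sd`, and `flags`.
#' @export
bundling_curve <- function(gels, reference_dose_nM = NULL) {
  need <- c("gel_id", "formin_nM", "band", "intensity_au")
  if (!all(need %in% names(gels))) {
    abort_input("gels must have columns ", paste(need, collapse = ", "))
  }
  doses_by_gel <- lapply(split(gels$formin_nM, gels$gel_id),
                         function(x) sort(unique(x)))
  if (length(unique(vapply(doses_by_gel, paste, character(1),
                           collapse = ","))) > 1L) {
    abort_input("replicate gels have mismatched dose grids")
  }

  per_rep <- do.call(rbind, lapply(split(gels, list(gels$gel_id, gels$formin_nM),
                                         drop = TRUE), function(d) {
    p <- d$intensity_au[d$band == "pellet"]
    s <- d$intensity_au[d$band == "supernatant"]
    if (length(p) != 1L || length(s) != 1L) {
      abort_input("gel ", d$gel_id[1L], ", dose ", d$formin_nM[1L],
                  " nM: need exactly one pellet and one supernatant band")
    }
    tibble::tibble(gel_id = d$gel_id[1L], formin_nM = d$formin_nM[1L],
                   pct = fraction_pelleted(p, s))
  }))

  per_dose <- do.call(rbind, lapply(split(per_rep, per_rep$formin_nM),
                                    function(d) {
    tibble::tibble(formin_nM = d$formin_nM[1L], mean_pct = mean(d$pct),
                   sd_pct = if (nrow(d) > 1L) stats::sd(d$pct) else NA_real_,
                   n = nrow(d))
  }))
  per_dose <- per_dose[order(per_dose$formin_nM), ]

  flags <- character()
  if (any(per_dose$n == 1L)) flags <- c(flags, "single_replicate")
  # non-monotone beyond noise: a drop between consecutive doses larger than
  # twice the pooled replicate SD
  pooled_sd <- stats::median(per_dose$sd_pct, na.rm = TRUE)
  drops <- -diff(per_dose$mean_pct)
  if (length(drops) && any(is.finite(pooled_sd)) && !is.na(pooled_sd) &&
      any(drops > 2 * pooled_sd)) {
    flags <- c(flags, "non_monotone")
  }

  ref <- reference_dose_nM %||% max(per_dose$formin_nM)
  ref_row <- per_dose[per_dose$formin_nM == ref, ]
  if (nrow(ref_row) == 0L) abort_input("reference dose not in the dose grid")

  structure(
    list(per_dose = per_dose, per_replicate = per_rep,
         reference_dose_nM = ref, reference_pct_mean = ref_row$mean_pct,
         reference_pct_sd = ref_row$sd_pct, flags = flags),
    class = "bundling_result"
  )
}

#' @export
print.bundling_result <- function(x, ...) {
  cat("Bundling at", x$reference_dose_nM, "nM:",
      signif(x$reference_pct_mean, 3), "+/-",
      signif(x$reference_pct_sd, 2), "% actin pelleted\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
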