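#!/usr/bin/env Rscript
# Generate the synthetic datasets for all three assay classes, with planted
# ground truth, under results/data/. Everything downstream (02-05) reads
# these files, so the whole analysis is reproducible from this script alone.

suppressPackageStartupMessages({
  library(forminkinetics)
  library(tibble)
})

seed <- 0
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

## 1. Bulk pyrene assembly: 4 uM actin, twofold formin dilution series.
## The ODE family shows the qualitative signatures quantified later: earlier
## half-times and lower plateaus with increasing dose.
doses <- c(0, 3.75, 7.5, 15, 30, 60)
bulk <- simulate_bulk_assembly(bulk_params(), doses, seq(0, 4000, 5),
                               noise_sd = 0.5, seed = seed)
write_traces(bulk, "results/data/bulk_assembly.csv", "assembly")
cat("bulk assembly:", length(doses), "doses,",
    length(unique(bulk$time_s)), "frames each\n")

## 2. Deterministic logistic fixtures whose per-dose t_1/8 slopes lie exactly
## on 0.1 + 0.32 * dose (the wild-type nucleation strength).
slopes <- 0.1 + 0.32 * doses
fixtures <- simulate_bulk_from_slopes(
  tibble(formin_nM = doses, slope_au_per_s = slopes),
  plateau = 457 * slopes, t_grid = seq(0, 1200, 0.5)
)
write_traces(fixtures, "results/data/nucleation_fixtures.csv", "assembly")

## 3. Seeded elongation series for each construct at its published affinity.
kds <- c(FHOD3L_CT = 0.023, FHOD3S_CT = 0.750, I1163A = 4.9,
         K1193L = 0.470, GS_FH1 = 0.218)
for (nm in names(kds)) {
  kd <- kds[[nm]]
  tr <- simulate_seeded_elongation(
    kd = kd, a_offset = 1, b_scale = -4.5, barbed_ends = 0.1,
    formin_series = c(0, 0.1 * kd * 2^(0:10))
  )
  write_traces(tr, sprintf("results/data/seeded_%s.csv", nm), "assembly")
}
cat("seeded elongation:", length(kds), "constructs\n")

## 4. Single-filament TIRF ensembles: wild-type-like and K1193L-like
## (K1193L's single-filament behavior is indistinguishable from wild type,
## so the two ensembles share the event parameters and differ only in seed).
wt <- simulate_filament_ensemble(80, filament_params(), seed = seed)
write_traces(wt$traces, "results/data/tirf_traces_wt.csv", "filament")
write_traces(wt$truth_events, "results/data/tirf_truth_wt.csv", "events")
mut <- simulate_filament_ensemble(
  40, filament_params(v_burst_mean = 38, v_burst_sd = 12,
                      runlength_char = 1.11, pause_mean = 12.7),
  seed = seed + 1
)
write_traces(mut$traces, "results/data/tirf_traces_k1193l.csv", "filament")
write_traces(mut$truth_events, "results/data/tirf_truth_k1193l.csv", "events")
cat("TIRF:", nrow(wt$truth_events), "WT events,",
    nrow(mut$truth_events), "K1193L events planted\n")

## 5. A rendered kymograph of one wild-type filament (16-bit TIFF).
ky <- render_kymograph(wt$traces[wt$traces$filament_id == "fil_001", ],
                       noise_sd = 20, seed = seed)
write_kymograph_tiff(ky, "results/data/kymograph_fil_001.tif",
                     max_value = 1500)

## 6. Co-sedimentation gels: 5 uM actin, 0-60 nM formin, 3 replicates,
## saturating to the wild-type 81.7% pelleted at 60 nM.
curve <- tibble(formin_nM = doses,
                true_fraction = c(0.05, 0.15, 0.35, 0.55, 0.72, 0.817))
gels <- simulate_cosedimentation(curve, noise_cv = 0.05, n_replicates = 3,
                                 seed = seed)
write_traces(gels, "results/data/bundling_gels.csv", "gel")
cat("gels: 3 replicates x", nrow(curve), "doses\n")
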