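# forminkinetics

Quantification of formin-mediated actin assembly from in vitro kinetics
data. The package implements, as tested and reusable R functions, the
measurement pipeline used to characterize a formin's four core activities —
nucleation, barbed-end capping, processive elongation, and bundling — from
three assay classes:

* **bulk pyrene assays**: the *t*₁/₈ nucleation-strength statistic (slope of
  the assembly curve where it reaches one-eighth of its amplitude, regressed
  against formin dose) and seeded-elongation initial rates;
* **single-filament TIRF microscopy**: segmentation of length-vs-time traces
  into free growth, pauses (capping), and dim fast "bursts" (processive
  formin runs), with burst elongation rates, run lengths, capping durations,
  and filaments-per-field counting;
* **low-speed co-sedimentation**: percent actin pelleted from band
  densitometry and its dose response.

It is written for quantitative biochemists analyzing plate-reader traces,
TIRF filament tracks, or gel densitometry of actin-assembly experiments, and
for anyone who needs a fully synthetic, ground-truthed testbed for such
pipelines: every assay class has a matching generator with planted truth, so
each estimator is validated by parameter recovery.

## The statistics at the core

**Nucleation strength.** For each trace, find
*t*₁/₈ = min{ t : F(t) ≥ F₀ + (F∞ − F₀)/8 } and the local slope dF/dt there
(20 s window). Nucleation strength is the OLS slope of those per-dose slopes
versus formin concentration, in a.u./s per nM.

**Barbed-end affinity** (tight-binding / quadratic equation). With barbed
ends *B* ≈ 0.1 nM and formin dose *F* comparable to *B*, the normalized
seeded-elongation initial rate is fit by

    r = a + b[(B + F + K_d) − sqrt((B + F + K_d)² − 4BF)]

by multi-start nonlinear least squares over (K_d, a, b), *B* fixed.

**TIRF events.** Pauses are runs lasting ≥ 5 s with slopes in (−10, 5)
subunits/s; bursts are dim runs whose line fit has R² > 0.5 and a slope
above the free-growth rate; boundaries are refined to sub-frame precision by
intersecting segment lines (370 subunits/µm). The characteristic run length
is the exponential MLE (sample mean of uncensored runs); the capping
duration estimate corrects the detected pause mean for the 5 s detection
gate, which for a memoryless distribution biases the raw mean upward by
exactly the gate.

**Gated comparisons.** Trim `floor(0.025 n)` values per tail when n > 20 →
Shapiro–Wilk gate → Student's unpaired t (both normal) or Mann–Whitney U,
at Bonferroni-corrected alpha; one-way ANOVA + Tukey HSD for ≥ 3 groups.

## Worked example

Recover a construct's barbed-end affinity from a simulated noise-free
seeded-elongation dose series (twofold dilutions spanning 0.1–100× K_d):

```r
library(forminkinetics)

kd_true <- 0.470   # nM
doses <- c(0, 0.1 * kd_true * 2^(0:10))
traces <- simulate_seeded_elongation(kd = kd_true, a_offset = 1,
                                     b_scale = -4.5, barbed_ends = 0.1,
                                     formin_series = doses)
rates <- do.call(rbind, lapply(unique(traces$trace_id), function(id) {
  tr <- traces[traces$trace_id == id, ]
  tibble::tibble(formin_nM = tr$formin_nM[1], rate = initial_rate(tr))
}))
norm <- normalize_rates(rates, rates$rate[rates$formin_nM == 0])
fit_barbed_end_affinity(norm, barbed_ends_nM = 0.1)
#> Quadratic-binding fit (B = 0.1 nM):
#>   Kd = 0.471 +/- 1.7e-05 nM
#>   a  = 1   b = -4.5   RSS = 7.42e-10  n = 12
```

The fitted K_d (0.471 nM) recovers the generating value within 0.3%; the
offset a = 1 confirms the normalization. The TIRF side works the same way:

```r
ens <- simulate_filament_ensemble(80, filament_params(), seed = 0)
det <- detect_events(ens$traces)
event_statistics(det$events, ens$traces)
#> TIRF event summary: 339 events over 80 filaments
#>   average elongation: 11.3 +/- 1.34 subunits/s
#>   burst rate: 39.1 +/- 12.3 subunits/s
#>   run length: 1.15 +/- 1.03 um (characteristic 1.15 um, 334 uncensored)
#>   pause: detected mean 16.3 s; capping duration estimate 11.3 s over 203 pauses
```

with planted generating values of 39 ± 13 subunits/s, 1.10 µm, and 12 s.

## Analysis scripts

`analysis/01_simulate_assays.R` … `05_bundling_and_stats.R` are thin
narrative drivers that generate all synthetic datasets (`results/data/`) and
produce the per-assay tables and summaries (`results/`): nucleation
strength, the five-construct affinity table and the I1163A/wild-type
affinity ratio, TIRF event summaries with detection sensitivity/FDR against
planted truth, the bundling dose response, and the gated statistical
comparisons. Run them in order with `Rscript`.

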