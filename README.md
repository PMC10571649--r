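# ranoedema

Response assessment of stereotactically irradiated brain metastases that
tracks **both** the contrast-enhancing tumor core and the surrounding
FLAIR-hyperintense peritumoral edema. Diameter-based criteria (RANO-BM)
read response from the longest axial diameter (LD) of the enhancing core;
edema — often the driver of neurological symptoms — is ignored, although
its volume can move independently of the core. This package is for
neuro-imaging researchers who want to study that relationship
reproducibly: it measures, classifies and summarizes per-lesion response
curves for core and edema side by side, and ships a calibrated synthetic
cohort generator so the whole pipeline is testable without patient data.

## What it computes

* **Mask geometry** — from binary segmentation masks with voxel spacing
  (NIfTI or in-memory): the RANO-style longest axial diameter (maximum
  in-plane voxel-center distance over axial slices), the in-slice
  perpendicular diameter, measurability (LD ≥ 10 mm and perpendicular
  ≥ 5 mm), and exact voxel-sum volumes in cm³.
* **Per-lesion classification over follow-up windows**
  (0–90, 91–180, 181–270, 271–365, > 365 days):
  * RANO-BM category with evaluation order NEW → CR → PD → PR → SD, where
    PR is an LD decrease ≥ 30% from baseline, PD an LD increase ≥ 20% from
    the nadir (progression trumps response), and CR a disappeared core;
  * edema grading: stable (|change| < 25%), decreased / increased
    (≥ 25%), resolved;
  * direction pairs and **congruence** — a window is congruent when core
    diameter and edema volume are concurrently increasing, decreasing or
    remitted, otherwise incongruent;
  * whole-series trajectory patterns: continuous decrease/increase,
    waxing-and-waning, paradoxical-then-decrease, complete remission.
* **Cohort statistics** — median/IQR window summaries, exact/approximate
  Wilcoxon signed-rank and Mann-Whitney tests, Spearman correlation of LD
  versus edema volume pooled over lesion-timepoints, patient-level sums of
  up to five target-lesion LDs, steroid-stratified descriptives.
* **Synthetic data** — ellipsoid core/edema phantoms with analytic volume
  oracles, and simulated cohorts calibrated to the published cohort
  structure (baseline LD median 14 mm IQR 11–17, baseline edema 8.1 cm³
  IQR 0.8–50, median 4 lesions per patient, 3–7 follow-ups every 6–12
  weeks) with per-lesion ground-truth labels.

## Worked example

```r
library(ranoedema)

sim <- simulate_cohort(30, seed = 7)   # cohort table + hidden truth labels
fit <- assess_cohort(sim$cohort)
fit
#> <bm_response> 29 patients, 157 lesions (38 excluded, 0 edema-excluded)
#> Congruence of core vs edema response by window:
#>  window   n n_congruent n_incongruent pct_incongruent
#>      W1 157         105            52           33.12
#>      W2 157         145            12            7.64
#>      W3 126         124             2            1.59
#>      W4 122         121             1            0.82
#>      W5 113         113             0            0.00
#> Pooled Spearman LD vs edema volume: rho = 0.49 (p = 3.01e-41, n = 671)
```

29 of 30 simulated patients survive screening with 157 analyzable lesions
(38 lesions were excluded, here all for a baseline LD under 10 mm, each
logged with its rule in `fit$exclusions`). About a third of lesions change
incongruently at the first follow-up — the generator's default injection
rate — and congruence dominates later windows. `summary(fit)` adds window
summaries, pattern counts and the rank tests; `plot(fit)` draws the paired
response curves; `as.data.frame(fit)` returns the one-row-per-lesion-window
label table.

Geometry works the same way from masks:

```r
ph <- generate_phantom(phantom_spec("ellipsoid", c(10, 8, 6), c(20, 16, 12),
                                    spacing = 0.5))
d <- longest_axial_diameter(ph$core)
c(d$ld_mm, d$perp_mm, lesion_volume(ph$edema)$volume_cm3)
#> [1] 16.000 12.000 16.064
```

Semi-axes are ordered slice × row × column, so the 10 mm semi-axis runs
through-plane and the longest *axial* extent is the 8 mm in-plane semi-axis:
LD = 16 mm with a 12 mm perpendicular, exactly what an axial caliper should
report. The measured edema volume of 16.064 cm³ is within 2% of the
analytic `4/3·π·20·16·12 / 1000 ≈ 16.085` cm³.

See the vignette (`vignettes/edema-response-assessment.Rmd`) for the model,
its assumptions and the design choices.

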