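---
title: "Assessing irradiated brain metastases: RANO-BM diameters and peritumoral edema volumetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing irradiated brain metastases: RANO-BM diameters and peritumoral edema volumetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranoedema)
```

## The problem

Brain metastases (METS) treated with stereotactic radiotherapy (SRT) are
followed with serial MRI. The reference standard for radiographic response,
RANO-BM, is diameter-based: each lesion's longest axial diameter (LD) is
measured on a single post-contrast T1 slice, a lesion is *measurable* when
LD ≥ 10 mm with an in-slice perpendicular ≥ 5 mm, and per-lesion response is
read from relative LD change. The FLAIR-hyperintense peritumoral edema that
surrounds (and here, by convention, includes) the enhancing core is not part
of that standard, although edema drives much of the neurological burden and
its volume can change independently of the core. This package implements a
reproducible pipeline for studying exactly that relationship: per-lesion 2-D
diameters and 3-D edema volumes from segmentation masks, per-window response
classification, an edema-volume grading, core-versus-edema congruence over
follow-up windows, trajectory pattern labeling, and the accompanying cohort
statistics — all exercised end-to-end on synthetic phantoms and simulated
cohorts, since no patient-level dataset is distributed.

## Geometry from binary masks

A `mask_volume` is a binary slice × row × column array with strictly
positive voxel spacing in mm. Diameters are **voxel-center to voxel-center**
distances: per axial slice the maximum in-plane center distance is found
(convex-hull pruning for large slices, which is exact — the diameter of a
point set is attained on its hull), and the lesion LD is the maximum over
slices. The perpendicular diameter is the extent of the LD slice's voxel
centers projected on the unit normal of the LD segment. Center-based
calipers underestimate an edge-to-edge caliper by at most one in-plane
pixel; we accept this bias for reproducibility and document it rather than
modeling pixel boundaries. Ties across slices resolve to the lowest slice,
endpoint ties to lexicographic order, so measurements are deterministic.
Masks with no in-plane extent (a single voxel, or a line along the slice
axis) return 0 mm diameters with a warning instead of an error: such lesions
are simply non-measurable.

Volumes are exact voxel sums: `volume_cm3 = count × prod(spacing) / 1000`.
On digitized ellipsoid phantoms (voxel included iff its center is inside the
analytic surface) the voxelization error at 0.5 mm spacing is well under 2%
of `4/3·π·abc` and shrinks as spacing refines — the property the test suite
checks at 2, 1 and 0.5 mm.

Automated mask calipers stand in for the manual caliper placements of a
clinical workstation; readers place calipers on the image, not on a mask, so
individual measurements will differ even when both are correct.

## The longitudinal data model

The cohort table is long-format, one row per lesion-timepoint, with days
from SRT as the only time axis (negative = pre-treatment). Baselines follow
the study design: tumor-core LD from the treatment-day scan; edema volume
from a pre-treatment scan within 30 days, the one closest to day 0 if
several exist (it best reflects the immediately pre-treatment state).
Lesions first appearing after treatment are *new lesions*: their first
appearance seeds their baseline and they are flagged, never contributing a
relative value at their appearance timepoint.

Follow-up is binned into five windows after treatment, half-open on the
left — (0, 90], (90, 180], (180, 270], (270, 365], (365, ∞) days. The
half-open convention keeps the windows disjoint and exhaustive (day 90 is
W1, day 91 is W2; the fourth window is equivalent to 271–365 in whole
days). If two scans fall into one window — possible at 6–12-week intervals —
the earliest is analyzed; this is a declared convention, not something the
study specifies.

Exclusions mirror the study's screening, checked in order with the first
matching rule logged per lesion: (3) slice thickness ≥ 3 mm or missing
FLAIR; (4) non-NSCLC histology; (5) baseline LD < 10 mm. Lesions with
confluent peritumoral edema are kept for LD analyses but excluded from all
edema-volume analyses, because confluent edema cannot be attributed to a
single core.

## Classification

**RANO-BM per lesion.** With evaluation order NEW → CR → PD → PR → SD:
a lesion absent from all prior scans is NEW; a disappeared core (an explicit
reader/mask flag, not a size heuristic) is CR; an LD increase ≥ 20% from the
nadir (the running minimum LD including baseline) is PD; an LD decrease
≥ 30% from baseline is PR; otherwise SD. PD is checked before PR — the RANO
convention that progression trumps response, so a lesion regrowing from a
deep nadir is progressive even while still 30% below baseline. After a CR
the nadir is 0 and any reappearance is progression. Both thresholds are
inclusive (the printed criteria say "≥").

**Edema grading.** Relative to the pre-treatment edema baseline: *stable*
when the absolute change is below 25% (strictly — the exact 25% boundary is
directional), *decreased* / *increased* beyond the band, and *resolved* when
edema is gone. Grade, band and the RANO thresholds are configuration values
(`analysis_config()`) with these defaults.

**Numerical boundary handling.** Threshold comparisons use an absolute
tolerance of 1e-9 on the percent/mm scale. This is not a loosening of the
criteria: a 30.0% decrease from 14 mm is `(14 − 9.8)/14`, which in binary
floating point evaluates to 0.29999999999999993, and the comparison must
still classify it as a partial response. The tolerance is far below the 0.1
mm resolution of any real caliper.

**Direction and congruence.** Response curves are read as direction labels
between consecutive analyzed timepoints (the baseline before the first
follow-up): increasing / decreasing beyond a configurable dead-band
(default 0: any strict change is directional), remitted at disappearance,
unchanged otherwise. A window is *congruent* when core and edema move the
same way and that way is increasing, decreasing or remitted. The published
definition does not address a jointly unchanged pair; the strict reading
(incongruent) is the default, and `stable_congruent = TRUE` gives the
lenient reading, since a qualitative curve reader may well have treated
near-flat pairs as congruent. Directions from the second window onward use
the previous analyzed timepoint rather than baseline, reproducing
curve-slope congruence as drawn.

**Trajectory patterns.** Whole-series labels, evaluated in a declared
precedence (the source describes the patterns narratively): complete
remission (final value 0), continuous decrease (no successive increase),
continuous increase (no successive decrease, final above baseline),
paradoxical-then-decrease (up at the first follow-up, down at the second,
never up again), waxing-and-waning (a decrease, a regrowth, a later
decrease, never exceeding the pretreatment baseline), else other. Patterns
are computed on the full measurement sequence, not the window-collapsed one,
so a regrowth squeezed into an already-occupied window still counts.

**Patient-level sum of LD.** Up to five target lesions — the largest
measurable at baseline, fixed thereafter; CR contributes 0; a missing target
scan leaves the window sum undefined. Patient-level *overall* RANO-BM
response (which additionally needs clinical status and steroid dosing) is
out of scope.

## Statistics

Summaries are medians with IQRs; quartiles interpolate linearly between
order statistics (`quantile(type = 7)`), a declared convention — printed
IQRs cannot adjudicate the convention used upstream. Pre/post comparisons
use the two-sided Wilcoxon signed-rank test with zero differences dropped
(documented because it changes n), exact for n ≤ 25 without tied absolute
differences and the tie-corrected normal approximation otherwise. Group
comparisons use the two-tailed Mann-Whitney test, exact when the smaller
group has ≤ 8 observations without ties. Spearman's rho uses average ranks;
its p-value is an exact permutation enumeration for n ≤ 10 and the
t-approximation on n − 2 degrees of freedom otherwise. Cross-window paired
comparisons are paired on the intersection of lesions present in both
windows — the published analysis does not explain its pairing across
different subsets, so this is the package's declared choice. The pooled
LD-versus-edema correlation uses all lesion-timepoint pairs across patients,
ignoring within-lesion dependence; reports flag this as the upstream
convention. No multiple-testing correction is applied, matching the
analysis being reproduced; α = 0.05 throughout.

All exact p-value paths are verified in the test suite against brute-force
enumeration oracles (sign assignments, label assignments, permutations)
written independently of the implementation.

## The synthetic cohort generator

`simulate_cohort()` emulates the published cohort structure so that every
downstream stage can be tested against known truth:

* **Baselines** are log-normal, parameterized by matching the printed median
  and IQR on the log scale (median fixes `meanlog`; IQR width fixes
  `sdlog`): LD median 14 mm (IQR 11–17), edema 8.1 cm³ (IQR 0.8–50),
  lesions per patient median 4 (IQR 3–10). A log-normal has log-symmetric
  quartiles, so the asymmetric printed IQRs are matched in width, not
  endpoint by endpoint. Baseline LD is drawn untruncated; lesions below
  10 mm are then removed by the exclusion rules exactly as in the study's
  screening.
* **Patterns** are drawn from a mixture calibrated to the published
  taxonomy: 24/31 decreasing (of which 6/24 waxing-and-waning, 4/24
  paradoxical, 3/24 remission) and 7/31 increasing. Pattern-specific
  multiplicative steps build the relative edema trajectory; waxing
  trajectories are constructed never to exceed baseline, with the regrowth
  at the second or third follow-up (half each, as reported).
* **Core coupling.** The core LD trajectory is the edema trajectory raised
  to `1/elasticity` (default 3: diameter tracks the cube root of volume), a
  minimal mechanism that yields a moderate pooled correlation. With
  probability 0.32 the first follow-up is made incongruent by moving the
  core opposite to the edema — reproducing the reported 32% first-follow-up
  incongruence (in the reported cohort those lesions had shrinking cores
  with growing edema, which the injection mirrors when edema increases).
* **Schedule.** Scans every 6–12 weeks; each patient completes between 3
  and 7 follow-ups, stopping early with per-scan hazard 0.16 after the
  third — calibrated so about half of the patients reach the seventh scan,
  as reported. The three-scan minimum lets every pattern express itself.
  `dropout_hazard = 0` makes everyone complete.
* **Noise.** Measurements get multiplicative log-normal noise with
  coefficient `noise_cv`; the default 0.05 is a declared assumption — no
  within-lesion repeat-measurement variability is published.
* **Truth.** The generator records each lesion's generating pattern and the
  per-window congruence derived from the *noiseless* trajectory signs with
  its own arithmetic, independent of the classifier code path. At
  `noise_cv = 0` with no dropout the pipeline recovers both for 100% of
  lesions; at `noise_cv = 0.05` pattern recovery stays above 90% (both are
  regression-tested on a 500-patient cohort at a fixed seed).

What the generator does **not** emulate: image intensities or segmentation
error (masks are geometric), new-lesion appearance and confluent edema (the
schema and classifiers support both flags, exercised by hand-built fixtures;
the analyzed published cohort excludes confluent lesions), steroid effects
on edema (steroid flags are drawn for descriptive stratification only, with
no causal coupling), and any correlation between lesions of one patient
beyond the shared scan schedule. Passing the recovery tests therefore shows
the pipeline is faithful to its own definitions on data with the published
cohort's marginal structure — not that it reproduces any patient-level
result, which would require the unreleased measurements.

Problem sizes used by the test suite — 500 simulated patients for recovery,
50 random masks for the caliper oracle, ellipsoids at 0.5 mm spacing for
volumetrics, full enumeration for n ≤ 8 — were chosen as the smallest scales
at which the respective properties are meaningfully exercised.

## Worked example

```{r example}
sim <- simulate_cohort(30, seed = 7)
fit <- assess_cohort(sim$cohort)
fit
head(fit$congruence_by_window)
subset(fit$window_summaries, variable == "rel_edema_pct")
table(fit$patterns$edema_pattern)
```

```{r curves, fig.width = 7, fig.height = 4}
plot(fit)
```

## Known limitations

* Caliper placements on masks are not reader placements; LDs carry a
  ≤ 1-pixel center-to-center bias and depend on segmentation quality.
* Disconnected components in one mask are treated as a single lesion —
  lesions are assumed pre-identified by a reader; no connectivity analysis.
* The congruence of near-flat curve pairs is convention-dependent; both
  readings are available but they can differ materially in cohorts dominated
  by stable lesions.
* The pooled correlation ignores within-lesion clustering; its p-value is
  anti-conservative and should be read descriptively.
* Window-level analyses discard later scans sharing a window with an
  earlier one; sensitivity to the "earliest" rule can be probed by editing
  the window breaks in `analysis_config()`.
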