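---
title: "Methods: quantitative fingerprint quality-consistency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative fingerprint quality-consistency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A batch's fingerprint at one detection wavelength is the vector
x = (x₁, …, xₙ) of integrated areas of the n peaks common to every batch of
the cohort; the reference fingerprint y is the peak-wise arithmetic mean
over **all** batches, including the one under evaluation. This choice makes
the self-similarity identity exact — the reference evaluated against itself
gives S_m = 1, P_m = 100 %, α = 0, grade 1 — which is the anchor row of any
published evaluation table and is asserted by the test suite.

The systematic quantitative fingerprint method (SQFM) summarizes a batch by
three quantities:

* **S_m = (S_F + S_F′)/2.** S_F is the cosine between x and y. Cosines are
  dominated by large peaks, so S_F′ is the cosine between the peak-ratio
  vector (x₁/y₁, …, xₙ/yₙ) and the unit vector, giving every peak the same
  weight. S_m therefore degrades both when large constituents swap
  proportions and when many trace peaks drift.
* **P_m = (C + P)/2**, in percent. C = 100·Σxy/Σy² projects x onto y
  (content as seen through the big peaks); P = 100·S_F·Σx/Σy is the total
  content corrected by compositional similarity. Both equal 100 when the
  batch matches the reference content; a uniformly diluted batch k·y gives
  S_m = 1, P_m = 100k %, α = 0 (the scale law, also under test).
* **α = |1 − P/C|.** C and P react differently to composition shifts, so
  their disagreement is a sensitive disproportion detector: in the bundled
  reference data the two composition-shifted batches carry α ≈ 0.17–0.25
  while the rest of the cohort stays below ≈ 0.1.

All area vectors must be non-negative with at least two peaks and a
non-zero norm; S_F′ requires yᵢ > 0, which holds by construction for common
peaks. If a zero sneaks in, the default is an error; the `"drop"` policy
discards the offending pair with a warning instead.

## Grading

Each of S_m, P_m, α receives the best grade whose band it satisfies and the
final grade is the **worst** of the three. The eight bands shipped as
`inst/extdata/sqfm_grade_bands.csv` are a reconstruction: grade g ∈ 1…7
requires S_m ≥ 0.95/0.90/0.85/0.80/0.70/0.60/0.50, P_m within
95–105/90–110/80–120/75–125/70–130/60–140/50–150 % and
α ≤ 0.05/0.10/0.15/0.20/0.25/0.30/0.35, with grade 8 as catch-all. This
table reproduces the three canonical worked examples
((0.96, 95.6, 0.02) → 1, (0.89, 89.5, 0.07) → 3, (0.87, 104.6, 0.25) → 5)
and every non-boundary per-wavelength row of the bundled 23-batch
evaluation table. Values exactly on a band edge resolve to the better
grade; since published inputs are rounded (2 dp for S_m and α, 1 dp for
P_m), rows within one rounding unit of an edge are excluded from grade
checks — the original grading was done from unrounded values, and a few
edge rows are genuinely undecidable from the printed digits. Alternative
band tables load from CSV via `read_grade_table()` and are validated for
strict nesting.

Multi-wavelength integration uses the quadratic mean over the m channels
(S_m′ = √(ΣS²/m), likewise P_m′ and α′), generalizing the published m = 5
form; it is bounded between the per-channel arithmetic mean and maximum and
equals the single value at m = 1. Because the published per-channel values
are rounded, RMS of the printed values occasionally rounds one unit away
from the printed integrated value (e.g. the outlier batches' α′); the
acceptance targets use batches where printed inputs reproduce printed
outputs exactly.

## Common-peak matching

The original study does not state its alignment procedure, so the package
uses a transparent one: pool all peaks of a wavelength, sweep in
retention-time order, and let a peak join the open cluster while it lies
within `rt_tolerance` (default 0.2 min) of the cluster's running median RT.
A cluster is a common peak only when every batch contributes exactly one
member: a batch contributing two raises an ambiguity error naming batch and
retention times (silent tie-breaking would corrupt the area vectors), and a
missing batch drops the cluster, mirroring the "common to all samples"
definition. Peak areas enter the similarity formulas as-is — no
normalization — because the quantitative similarities are ratios of raw
areas by design.

## Marker quantitation conventions

Calibration is ordinary least squares of area on injected concentration;
LOD and LOQ are 3σ/slope and 10σ/slope. Back-calculated concentrations are
flagged (never rejected) below LOQ or outside the linear range. The
injected-to-preparation unit conversion is an explicit `dilution_factor`
supplied by the user — the original workup factor is not recoverable from
the publication, so the package refuses to guess.

Percent contents divide each content by the unrounded across-batch column
mean with not-detected (ND) treated as 0 — the convention validated by the
bundled table, whose AD column mean is only consistent with ND = 0 over all
23 batches. P_7C is the row mean of a batch's marker percents (ND counted
as 0 over all seven markers; the ND batch's published P_7C confirms this).
RSD uses the n−1 standard deviation. One caveat the tests document rather
than hide: the published summary cells were computed from unrounded
contents, so recomputation from the printed 2-dp table reproduces means to
±0.01 and percents to ±0.2, and the printed RSD(AD) = 53.10 is not exactly
recoverable (recomputation gives 53.13); the acceptance suite asserts the
printed value and leaves that single expectation red by design.

## DPPH antioxidant metrics

Off-line: %inhibition = 100·(A_control − A_sample)/A_control; negative
values are returned with a warning, not clamped (they indicate sample
colour interference worth seeing). IC50 inverts a least-squares line of
inhibition on concentration over the tested range (1–6 mg/mL is close to
linear); a four-parameter logistic would demand more dose levels than the
assay provides and is deliberately out of scope. When 50 % is not bracketed
by the observations the estimate is flagged `extrapolated`. A non-positive
slope is a computation error — no dose response, no IC50.

On-line: the 517 nm trace baseline is a rolling median over a 2 min window
(robust to the narrow negative peaks); contiguous sub-baseline excursions
deeper than `min_depth` (recommended ≈ 3× the trace noise SD) are activity
peaks, apex at the deepest sample. Parent 260 nm peaks are shifted by the
post-column delay — by default the reaction-coil volume over the combined
flow, π(0.09 mm)²·5000 mm / 1.1 mL min⁻¹ ≈ 0.116 min, overridable by a
measured offset — and matched greedily, closest pair first, one-to-one
within a tolerance. Unmatched parents map to NA, the signature of a
component without detectable scavenging.

## Chemometrics

PCA is mean-centred SVD (optionally unit-variance scaled) with Hotelling
T² score distances; batches beyond the F-based limit at the chosen
confidence (default 95 %) are flagged. Flagging never removes anything:
exclusion from downstream modelling happens only when the pipeline config
says `exclude_outliers = TRUE`, and is logged.

PLS is NIPALS on centred, unit-variance-scaled data (the originating
software's default; centre-only and Pareto are available), with
coefficients back-transformed to raw areas so predictions are a plain
linear form. OPLS removes up to k X-components orthogonal to the response,
then fits one predictive component; the orthogonal filter is folded into
the returned coefficient vector, and k = 0 reduces exactly to 1-component
PLS (a tested contract). At full rank PLS reproduces least squares to
1e-8, the dual-route oracle check against the normal equations. Model
quality is R²/RMSEE on training and Q²/RMSECV from seeded 7-fold
cross-validation in which every fold refits scaling and components from
scratch; RMSEP comes from a disjoint test set (default split 16/5 as in
the reference study design). Jack-knife 95 % intervals use leave-one-out
refits with SE = √((B−1)/B·Σ(θᵢ−θ̄)²) and a t(B−1) quantile. The original
study's R²/Q²/RMSE values depend on its unpublished 49-peak area matrix
and exact software defaults and are not reproduction targets; the package
validates the machinery by property and recovery tests instead.

## The synthetic generator

`synthetic_spec()` states a world shaped like the reference study: 23
batches, five wavelengths with 49/46/38/39/33 common peaks, a log-normal
per-batch content scale (8 % SD, matching the published P_m spread of
roughly 83–120 %), log-normal per-peak noise (3 % CV, a typical area
repeatability), and two planted outliers whose class-wise fold changes
follow the published pattern (nucleoside ≈ 0, phenolic acids ×0.3–0.4,
flavonoids ×1.7–1.8). Marker peaks carry fixed base areas proportional to
the published mean contents (so the big phenolic and flavonoid peaks
dominate the chromatogram, which is what makes α respond to the outlier
pattern as strongly as in the real data); minor peaks are drawn once per
seed. Activity is linear in the 260 nm areas with positive coefficients on
phenolics (strongest), flavonoids and two unassigned peaks, two small
negative coefficients, and zero for nucleosides; absorbance series are
constructed to invert exactly through the off-line pipeline, and 517 nm
traces carry inverted Gaussians (width 0.05 min) only for positive
coefficients, shifted by the coil delay.

What the generator does **not** emulate: retention-time drift beyond small
jitter, co-elution and peak-shape distortion, detector saturation, baseline
drift on the fingerprint channels, correlated biochemical covariance
between constituents, and inter-manufacturer variation. A green test on
synthetic data therefore establishes that the arithmetic, grading, and
model machinery behave as specified under the stated noise model — not that
the method would survive a badly drifting chromatographic system; that is
what the bundled published tables, with their exact derived-arithmetic
checks, complement.

## Numerical conventions

All internal computation is full precision; report rendering rounds
half-away-from-zero (`round_half_up()`) to 2 dp for similarity-type values,
1 dp for percent-type values and 2 dp for α, matching the published table
format. Seeds: every stochastic step (CV partition, generator, train/test
split) takes an explicit integer seed and restores the caller's RNG state.
Zero-variance predictor columns are dropped with a warning before
modelling; a constant response is an error. Degenerate fingerprints
(all-zero vectors, single peaks) are rejected at construction rather than
propagated.

## Known limitations

The published common-peak counts cannot be re-derived without raw
chromatograms, so matching is validated on synthetic tables only. The grade
bands are a reconstruction constrained by the worked examples and the
evaluation table, not the original supplementary table. Printed-table
rounding limits some published summary cells to ±1 in the last digit, as
detailed above. IC50 is a range-restricted linear estimate, not a full
dose-response fit.
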