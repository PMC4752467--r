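# fingerqc

Quantitative quality-consistency analysis of multi-component herbal
preparations from multi-wavelength HPLC fingerprints.

Batch release of preparations such as *Ixeris sonchifolia* (Bunge) Hance
injectable (ISHI) is monitored by chromatographic fingerprints: the vector
**x** = (x₁, …, xₙ) of integrated areas of the n peaks common to all batches
at one detection wavelength, compared against a reference fingerprint
**y** (the all-batch mean). Plain cosine similarity answers only the
qualitative question ("same composition?"); `fingerqc` implements the
systematic quantitative fingerprint method (SQFM), which scores each batch
on three axes and turns them into an 8-grade quality call:

- **Macro qualitative similarity** S_m = (S_F + S_F′)/2, where
  S_F = Σxᵢyᵢ / (√Σxᵢ² √Σyᵢ²) is the cosine of the area vectors and
  S_F′ = Σrᵢ / (√n √Σrᵢ²) with rᵢ = xᵢ/yᵢ is the cosine of the peak-ratio
  vector against (1, …, 1), which restores equal weight to small peaks.
- **Macro quantitative similarity** P_m = (C + P)/2 (percent), where
  C = 100·Σxᵢyᵢ/Σyᵢ² is the projection content similarity and
  P = 100·S_F·Σxᵢ/Σyᵢ the S_F-corrected total-content ratio. P_m = 100
  means the batch carries the reference's overall content.
- **Leveling coefficient** α = |1 − P/C|, a sensitive detector of
  disproportion between sample and reference composition.

Each quantity is graded against nested bands (grade 1 best … 8 worst) and
the final grade is the **worst** of the three. Multi-wavelength fingerprints
are integrated by the quadratic mean, e.g. S_m′ = √(Σ S_m,i²/m) over the m
channels. Around this core the package provides common-peak matching,
calibration-curve quantitation (LOD/LOQ at S/N = 3/10), percent contents and
P_7C, off-line DPPH IC50 estimation, on-line (post-column DPPH) activity
fingerprint detection, PCA outlier screening, NIPALS PLS / OPLS regression
of activity (1/IC50) on peak areas with jack-knife coefficient intervals,
and a synthetic fingerprint generator with known ground truth.

## Worked example

Integrate the five published per-wavelength scores of batch S1 of the
bundled 23-batch ISHI reference tables, then evaluate a synthetic cohort:

```r
library(fingerqc)

t3 <- ishi_sqfm_table()
integrate_channels(t3[t3$batch_id == "S1" & t3$wavelength != "integrated", ])
#> <integrated_sqfm> S1 over 5 channels: Sm'=0.94 Pm'=91.8% alpha'=0.06 grade=2

spec <- synthetic_spec(seed = 42)        # 23 batches x 5 wavelengths,
fp   <- generate_fingerprints(spec)      # 2 planted outlier batches
res  <- sqfm_evaluate_matrix(fp$matrices[["260"]])
format_sqfm(res)[c(1, 21, 23), c("batch_id", "s_m", "p_m", "alpha", "grade")]
#>  batch_id  s_m   p_m alpha grade
#>        S1 1.00  99.8  0.01     1
#>       S21 0.94 103.6  0.22     5
#>       S23 0.93 110.7  0.26     6

pca_screen(fp$matrices[["260"]]$areas, k = 2)
#> <pca_result> 2 components (99.9% variance); 2 outlier(s) at 95%

act <- generate_activity(spec, fp)
keep <- setdiff(1:23, c(21, 23))         # confirmed outliers excluded
fit_pls(fp$matrices[["260"]]$areas[keep, ], act$inv_ic50[keep],
        n_components = 2, cv_folds = 7, seed = 42)
#> <latent_model> PLS: 2 predictive + 0 orthogonal; R2=0.9909 Q2=0.9653
#>                RMSEE=0.00183 RMSECV=0.003302
```

Reading: S1 sits at grade 1–2 (composition identical to the reference,
content within a few percent), while the two planted composition-shifted
batches show the study's outlier signature — α an order of magnitude above
the cohort, grade ≥ 5, flagged by the PCA screen — and the PLS model links
the 49-peak fingerprint to antioxidant activity with cross-validated
Q² ≈ 0.97.

## Full pipeline / CLI

```r
cfg <- run_config(out_dir = "report", spec = synthetic_spec(seed = 1), seed = 1)
run_pipeline(cfg)   # sqfm_wavelength.csv, sqfm_integrated.csv,
                    # marker_table.csv, ic50.csv, model.json, run_log.txt
```

or from the shell:

```sh
Rscript -e 'fingerqc::fingerqc_cli()' simulate --out data --seed 1
Rscript -e 'fingerqc::fingerqc_cli()' run --input data --out report --seed 1
```

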