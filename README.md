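# cartex

Noise-corrected cartilage T2 relaxometry, GLCM texture quantification,
morphologic (WORMS-style) lesion scoring, reliability metrics, and
covariate-adjusted group statistics — the complete computational chain of a
two-group observational knee-MRI study, with a seeded synthetic
phantom/cohort generator so the whole pipeline runs end to end without
access to restricted clinical images.

## Who this is for

Quantitative-MRI and osteoarthritis-imaging researchers who need a tested,
reproducible implementation of:

* **Pixel-wise T2 mapping** from multi-slice multi-echo (MSME) magnitude
  stacks using the three-parameter squared-signal model

  S(TE)² = S₀² · exp(−2·TE/T₂) + B²,

  where B² absorbs the Rician noise floor (B² = 2σ² for channel noise SD
  σ). The fit minimises Σₑ (Sₑ² − model)² over the echoes with the first
  echo excluded (stimulated-echo contamination), solved by variable
  projection: S₀² and B² are profiled out in closed form and T₂ found by a
  global log-grid bracket plus golden-section refinement, vectorised over
  all masked pixels.

* **GLCM texture features** of the T2 map per cartilage compartment
  (patella, medial/lateral femur, medial/lateral tibia): contrast
  Σ P(i,j)(i−j)², entropy Σ P(i,j)(−ln P(i,j)), and variance
  Σ P(i,j)(i−μ)², at pixel offset 1, averaged over the 0°/45°/90°/135°
  orientations, slice by slice, with strict both-pixels-in-mask counting.

* **WORMS-style scoring**: scale validation (cartilage 0–6 with the 2.5
  half grade, meniscus 0–4, bone-marrow lesions 0–3), per-subject maximum
  scores, and lesion prevalence at the >0 and ≥2 thresholds with unread
  subjects excluded from denominators.

* **Reliability**: RMS coefficient of variation for repeated
  segmentations, two-way single-measure ICC (absolute agreement or
  consistency), quadratic-weighted kappa — with the ICC ≈ kappa
  equivalence property-tested.

* **Group statistics**: OLS group comparisons adjusted for age, sex and
  BMI (control − incidence sign convention), logistic prevalence odds
  ratios, partial correlations, standardized differences, Pearson
  chi-square.

Everything user-facing takes and returns tibbles and chains with the pipe;
fitted comparisons have `tidy()`/`glance()` methods and `autoplot()`.

## Worked example

Simulate a small cohort, fit every subject's T2 map, compute compartment
texture, and compare groups:

```r
library(cartex)

cfg <- sim_config(n_incidence = 12, n_control = 8, seed = 42)
res <- run_study(cfg)

dplyr::select(res$cohort, subject_id, group, mean_t2_mf,
              contrast_mf, entropy_mf, variance_mf)
#> # A tibble: 20 x 6
#>   subject_id group     mean_t2_mf contrast_mf entropy_mf variance_mf
#> 1 I001       incidence       37.5        158.       5.09        79.9
#> 2 I002       incidence       31.7        141.       5.05        72.9
#> 3 I003       incidence       35.7        139.       5.07        73.4
#> ...

adjusted_group_difference(res$cohort, "mean_t2_mf")
#>   outcome    mean_incidence sd_incidence mean_control sd_control coefficient
#> 1 mean_t2_mf          35.64         2.41        35.76       2.23    -0.04853
#>   ci_low ci_high p_unadjusted p_adjusted  n
#> 1 -2.324   2.227       0.9078     0.9672 20
```

The comparison row reports group means ± SD of the per-subject medial-femur
mean T2 (ms), the adjusted group coefficient (control − incidence; at this
toy size the groups are indistinguishable, p ≈ 0.97), and its Wald 95%
interval. Lesion prevalence from the simulated WORMS scores:

```r
prevalence_table(res$worms)
#> # A tibble: ... tissue    threshold group     n_with_lesion n_readable proportion
#> 1 cartilage gt0       incidence            10         12      0.833
#> 2 cartilage ge2       incidence             6         12      0.5
```

Reliability helpers work on long tables or plain vectors:

```r
d <- tibble::tibble(subject = rep(c("s1", "s2"), each = 3),
                    value = c(98, 100, 102, 49, 50, 51))
rms_cv(d)                                      # 2  (% RMS CV)
standardized_difference(32.65, 32.07, 1.55, 1.38)  # 0.396
```

`run_pipeline(cfg, outdir)` writes the full report bundle (cohort CSV,
feature CSV, comparison and prevalence tables, optional per-subject NIfTI
echo stacks/masks/T2 maps, YAML config and a JSON manifest with the seed),
byte-reproducibly for a fixed configuration.

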