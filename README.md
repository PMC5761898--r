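# cd8sample

How much tissue is enough to call a tumor "CD8-high"? Immunohistochemistry
(IHC) for CD8+ cytotoxic T cells is usually quantified on one full-face
section of one block — or, in practice, on a needle core biopsy covering a
couple of square millimetres. `cd8sample` is an R package for asking, by
simulation and resampling, whether those limited samples adequately
represent a tumor's true infiltration. It is aimed at pathologists,
biomarker statisticians and assay developers designing tissue-sampling
strategies for immune-infiltrate readouts.

The package implements a complete, testable analysis pipeline:

1. **Synthetic cohorts** — section-level tables of percent CD8+ cells per
   patient and step section, generated from a hierarchical Gaussian model
   (patient effect + section noise, clipped to [0, 100]), and full spatial
   slides: tumor-ROI polygons in µm with point-located cells, uniform or
   margin-enriched CD8 distributions, Poisson cell counts, and optional
   tissue-loss sections.
2. **Quantification** — boundary-inclusive point-in-polygon cell counting
   and percent-positive computation for any region.
3. **Variance components** — fixed-effects ANOVA (`y_ij ~ patient +
   section`, sequential SS with patient first) and a one-way
   random-intercept model with the intraclass correlation coefficient
   ICC = σ²_patient / (σ²_patient + σ²_residual), estimated by
   zero-truncated method of moments (identical to REML for balanced
   designs).
4. **Section resampling** — classify each patient CD8-high/low against the
   cohort-median cutoff from k resampled sections, under two schemes:
   sections-only (technical reproducibility) and patients-then-sections
   (future-cohort variability); agreement, sensitivity, specificity with
   percentile CIs.
5. **Virtual core biopsies** — tessellate each slide into rectangles of
   ~2 mm², keep cores with ≥ 0.7 mm² ROI overlap and ≥ 33% tumor fraction,
   and score percent CD8 per core.
6. **Core subsampling** — draw 1–5 cores without replacement, summarize by
   mean or max, and quantify performance: within-1-SD rates, out-of-bag
   (selected minus unselected) differences, loess curves of variability vs
   mean staining, and ROC (sensitivity/specificity/accuracy) against
   slide- or block-level truth at 1/2/5/10% cutoffs.

## Worked example

```r
library(cd8sample)

# a study-like cohort: 6 ductal + 6 medullary breast, 13 colorectal,
# 8 step sections per block
m  <- generate_section_measurements(default_group_specs(), seed = 1)
random_intercept_icc(m)$icc                      # 0.990
fixed_effects_anova(m)$pct_var_patient           # 99.1

# is one section enough to classify against the cohort median?
resample_section_classification(m, k_sections = 1, summary_stat = "mean",
                                scheme = "sections_only",
                                n_reps = 1000, seed = 2)
#> Section resampling (sections_only, k = 1, mean, 1000 reps)
#>   cutoff: 5.03% CD8+
#>   agreement: 97.5% (95% CI 92.0-100.0%)
#>   sensitivity: 96.2%  specificity: 98.9%

# virtual core biopsies on a synthetic slide
sp    <- slide_spec(cell_density = 400, target_percent = 8)
sl    <- generate_slide(sp, seed = 3)
cores <- score_cores(generate_core_grid(sl$geometry), sl$cells, sl$geometry)
nrow(cores)                                      # 64 retained cores
sub <- subsample_cores(cores$percent_cd8, k = 2, summary_stat = "mean",
                       n_reps = 1000, seed = 4)
sub$within_1sd_rate                              # 0.868
sub$oob_diff_mean                                # -0.007 (unbiased)
```

The ICC near 1 and the ~99% patient share of the sums of squares say that
essentially all variation is between patients, not between sections — so a
single section classifies almost as well as all eight (97.5% agreement
here). At the core level, two 2-mm² cores land within one SD of the slide
mean ~87% of the time, and the out-of-bag mean difference centred on zero
confirms the subsample estimate is unbiased.

`run_pipeline(default_run_config(seed = 1, out_dir = "out"))` runs every
stage on the default synthetic cohort and writes all tables (ANOVA, variance
components, section agreement, per-core CSV, subsampling summaries, loess
curves, ROC) plus seed metadata.

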