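---
title: "Sampling adequacy of CD8 IHC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling adequacy of CD8 IHC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd8sample)
```

# The problem

A tumor's CD8+ T-cell infiltration is measured by immunohistochemistry as
the percentage of CD8-positive cells among all nucleated cells in an
annotated region. Clinical decisions increasingly dichotomize this number
("CD8-high" vs "CD8-low"), yet the measurement is made on a tiny sample of
the tumor: one step section of one block, or a needle core of a couple of
square millimetres. `cd8sample` quantifies, by simulation, how much that
sampling costs: how concordant limited samples are with block-level truth,
how variable core-based estimates are, and how summary choices (mean vs
maximum of several cores) change bias and classification performance.

# The generative model

## Section-level cohorts

Percent CD8 for patient $i$, section $j$ follows a one-way hierarchical
Gaussian model on the raw percent scale:

$$y_{ij} = \mu_g + b_i + e_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad e_{ij} \sim N(0, \sigma_w^2),$$

clipped to $[0, 100]$. We model raw percents (not logits) because that is
the scale on which the assay is reported and analyzed downstream; clipping
events are counted and attached to the output, and the default parameters
make them rare. The default cohort (`default_group_specs()`) has three
groups chosen to resemble a mixed breast/colorectal IHC study: 6 ductal
adenocarcinoma patients (mean 8.8%, within-patient SD 1.2), 6 medullary
carcinoma (mean 24.0%, SD 1.7) and 13 colorectal (mean 3.8%, SD 0.4),
8 step sections per block. Published summaries of such cohorts report group
means and pooled intrapatient SDs but not between-patient SDs, so the
defaults $\sigma_b$ = 8, 14 and 3 percent are *calibrated* values chosen to
reproduce each group's plausible dynamic range (ductal from under 1% to
tens of percent; medullary up to the 50s; colorectal mostly under 10%) —
they are a modelling choice, not quoted parameters.

Tissue loss: with probability `tissue_loss_rate` (default 0.05) a section is
flagged and keeps only 30% of its cells, with unchanged expected percent.
This emulates deeper step levels where part of the block face is exhausted;
keeping the percent scale unchanged lets analyses that include or exclude
flagged sections be compared directly.

## Spatial slides

A slide is a tumor-ROI polygon in micrometres (origin top-left, x rightward,
y downward) plus a point process of cells. The cell count is
Poisson(density × ROI area) — not fixed — so simulated core-level counts
vary realistically; positions are uniform on the ROI. Positivity is an
inhomogeneous Bernoulli marking with piecewise-constant probability:
constant for the `uniform` pattern, and for `margin_enriched` multiplied by
an enrichment factor within `margin_width` µm of the ROI boundary, then
rescaled so that the *area-weighted* mean equals `target_percent`/100
exactly. The margin band's area is computed exactly by insetting the ROI
polygon (intersection of inward-shifted edge half-planes), which is why the
margin-enriched pattern requires a convex ROI; when the margin width reaches
the inradius the whole ROI is margin and the pattern degenerates to uniform,
as it should. The margin pattern emulates the heterogeneous slides seen in
practice where cytotoxic T cells concentrate at the invasive margin — the
main spatial failure mode of single-core sampling.

What the generator does *not* emulate: nucleus morphology and segmentation
error, staining chemistry and batch effects, non-convex or multifocal tumor
masks for the margin pattern, spatial clustering of cells beyond the margin
band, and correlation between adjacent step sections (sections are
exchangeable given the patient effect). Passing tests therefore demonstrate
that the *analysis machinery* is correct and that its qualitative
conclusions hold under a realistic hierarchical/spatial model — not that any
particular real cohort will show the same numbers.

# Estimators and procedures

## Variance components

`fixed_effects_anova()` fits `percent ~ patient + section` by least squares
with both terms as factors (section levels are the common step depths) and
reports sequential type-I sums of squares with **patient entered first**.
"Percent of variability explained" is defined as $100\,SS_{term}/SS_{total}$
from that decomposition; the patient-first ordering matches the scientific
question (is there any section effect left once patients are accounted
for?). `random_intercept_icc()` estimates the one-way random-intercept model
by method of moments: $\hat\sigma^2_w = MSW$,
$\hat\sigma^2_b = \max\{0, (MSB - MSW)/n_0\}$ with the harmonic correction
$n_0 = (N - \sum n_i^2/N)/(a-1)$ for unbalanced data, and
$ICC = \hat\sigma^2_b/(\hat\sigma^2_b + \hat\sigma^2_w)$. Method of moments
was preferred over iterative REML because it is closed-form, deterministic,
fully specified, and identical to REML for balanced one-way designs (the
test suite verifies the agreement with `lme4` to 1e-6 on balanced data).
Zero-truncation keeps the ICC in $[0, 1]$; when total variance is zero the
ICC is undefined and returned as `NA`.

## Section resampling

Truth per patient is the mean over all its sections; the cutoff is the
cohort median (midpoint convention for even cohorts); classification uses
the `>=` rule — ties go to "high". Ties have measure zero under the
continuous model, but the rule matters for degenerate test cases and is
fixed and documented. Scheme (i) resamples k sections with replacement
within the fixed patient set; scheme (ii) resamples patients with
replacement first, then sections. In both schemes the cutoff stays fixed
from the original cohort — it is a *candidate* cutoff determined by the full
sample, and re-deriving it per bootstrap replicate would answer a different
question. Agreement CIs are 2.5/97.5 percentiles over replicates.
Replicates in which a class is absent (possible under scheme (ii), or in
single-class cohorts) contribute no sensitivity or specificity value; they
are skipped for that metric and the skip count is reported rather than
zero-filled.

## Virtual cores

The ROI bounding box is tiled by non-overlapping rectangles of
`core_area` = 2 mm² (squares of side √2 mm by default; the aspect ratio is
configurable), anchored at the bounding-box minimum corner with a
configurable offset for anchor-sensitivity checks. Each tile's tumor
overlap is the exact Sutherland–Hodgman clip area against the ROI polygons;
tiles are kept when overlap ≥ 0.7 mm² **and** tumor fraction ≥ 33%. With
the defaults the overlap floor is the operative filter (0.7/2.0 = 35% >
33%), which the tests assert as a consistency check. Tumor fraction is
defined against the annotated ROI (tumor plus adjacent stroma) because that
is the only tumor mask the pipeline has.

Cell membership in cores uses a half-open tie rule — a cell exactly on a
shared tile edge belongs to the tile with the smaller row-major index — so
that partition counts are conserved exactly; a cell on the ROI boundary
counts as inside (boundary-inclusive convention, declared since the source
assays do not state one). Retained cores with zero cells have undefined
percent and are dropped from resampling with a warning.

## Core subsampling, out-of-bag differences, ROC

For each slide (or block, pooling all its slides' cores unweighted — a
cell-weighted pooled mean is available as an option), k of n cores are drawn
without replacement, 1000 times by default. The estimate is the mean or the
maximum of the drawn percents; the reference is the parent mean and sample
SD (n−1) of all the unit's cores; the out-of-bag difference is
summary(drawn) − summary(not drawn). Slide-level analysis is restricted to
units with at least `min_cores` = 15 cores (and k < n so the out-of-bag set
is nonempty); an unrestricted mode exists for small enumerable test cases.
ROC analysis classifies each per-replicate estimate against cutoffs of 1, 2,
5 and 10% with truth = unit core mean; per-replicate sensitivity,
specificity and accuracy are averaged over replicates (headline numbers),
with pooled-count versions also reported. Cutoffs that leave one class empty
yield `NA`, never a zero fill.

Loess curves of out-of-bag SD versus mean staining use tricube-weighted
local quadratic regression with span 0.75 (classic defaults, configurable),
computed by exact direct fitting and evaluated on an even predictor grid;
the log2 scale uses $\log_2(x + 0.1)$, the 0.1 offset keeping zero-percent
units finite. The bandwidth convention (the `floor(span · n)` nearest
neighbours) is pinned by a direct weighted-least-squares oracle in the test
suite.

# Reproducibility and numerical choices

Every stochastic function takes an explicit seed and restores the caller's
RNG state. `run_pipeline()` expands one master seed into per-stage seeds by
a fixed affine map (`derive_stage_seed()`), so stages can be rerun
independently yet reproducibly; identical config and seed give identical
output tables. Numerical tolerances: the sequential SS identity holds to
1e-8 relative; the balanced ICC closed form to 1e-10; tile overlap areas sum
to the ROI area to 1e-6 relative; the marking-probability identity is exact
to 1e-9 by construction.

Problem sizes: the default demo configuration is 25 patients × 8 sections,
3 slides per block at 400 cells/mm² on a 10√2 × 6√2 mm ROI (60 cores of
2 mm² per slide), and 1000 resampling replicates throughout — under half a
minute on one core. The test suite uses smaller replicate counts
(60–500) and 2 slides per block, which is ample for the directional and
oracle checks it performs.

# Limitations

- The margin-enriched pattern is exact only for convex ROIs; non-convex or
  multifocal margin geometry would need a numeric inset.
- The ICC estimator covers the one-way (patient) random effect the analysis
  needs; it is not a general mixed-model engine.
- Core shapes are axis-aligned grid rectangles; needle-shaped or randomly
  placed cores are out of scope.
- All performance statements are conditional on the Gaussian-with-clipping
  generative model; heavy-tailed or zero-inflated infiltration distributions
  would widen the resampling intervals.
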