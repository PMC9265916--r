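---
title: "Stepwise origin authentication of Manila clams: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise origin authentication of Manila clams: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamtrace)
```

## The problem

The Manila clam *Ruditapes philippinarum* is a high-value bivalve whose
domestic (Korean) product commands a premium over imports, which invites
origin fraud. Genetic markers cannot settle the question — clam seed has
been imported and cultivated in Korean waters for years, so the DNA of
"domestic" and "imported" stocks is largely identical. What does differ is
the habitat signal accumulated in the animal's tissue:

* **Bulk stable isotopes.** The carbon isotope ratio
  ($\delta^{13}\mathrm{C}$, per mil vs VPDB) of the adductor muscle tracks
  the particulate organic matter the clam filtered; the nitrogen ratio
  ($\delta^{15}\mathrm{N}$, per mil vs atmospheric N$_2$) tracks the
  nitrogen baseline of the coastal water, including anthropogenic loading.
  Cheap to measure, but regionally overlapping.
* **Fatty-acid (FA) profiles.** Clams cannot synthesize most
  polyunsaturated FAs; the relative composition of a 15-FA panel therefore
  fingerprints the local plankton community (diatom vs dinoflagellate vs
  bacterial food sources). Richer, but slower and costlier to assay.
* **Compound-specific isotope analysis (CSIA).** $\delta^{13}$C measured
  on individual FAs combines both kinds of information.

The package implements the *stepwise* protocol built on these three assay
tiers: classify everything with the cheap tier, escalate only the samples
(in practice: all sites of every imperfectly predicted region, as
triplicates) that the tier failed to authenticate, and stop as soon as the
material is resolved.

## Models and procedures

### Delta notation

Isotope ratios are handled in delta notation,
$\delta = (R_\mathrm{sample}/R_\mathrm{standard} - 1)\times 1000$ (per
mil), with VPDB as the carbon reference and atmospheric N$_2$ for
nitrogen. `delta_from_ratio()` / `ratio_from_delta()` are exact inverses
(round-trip error below $10^{-12}$ over the physical range), and deltas at
or below $-1000$ per mil are rejected as nonphysical. The two references
are deliberately kept as explicit arguments: mixing a VPDB-referenced
value into a nitrogen computation is a unit error, not a numerical one.

### Fatty-acid features

`relative_composition()` normalizes raw FA quantities to percent of total
identified FAs (the compositional convention throughout; absolute
concentrations are accepted wherever a profile is, since the
normalization is scale-invariant). The panel is fixed at five SFAs (14:0,
15:0, 16:0, 17:0, 18:0), five MUFAs (16:1n-7, 18:1n-7, 18:1n-9, 20:1n-7,
20:1n-9) and five PUFAs (18:2n-6, 18:3n-3, 20:4n-6, 20:5n-3, 22:6n-3).
Fourteen of the fifteen identities are fixed by the assay panel this
mirrors; 14:0 is our assumption completing the saturated five, as only
four SFAs are named individually in the source material.
`biomarker_summary()` derives the diet indices used for interpretation:
diatom (20:5n-3 + 16:1n-7), flagellate (18:1n-9 + 22:6n-3) and bacterial
(17:0 + 18:1n-7) sums, DHA/EPA, and PUFA/SFA. A zero EPA yields an `NA`
ratio rather than an error, because a compositional sampler can legally
produce vanishing components and a whole-table summary should not crash
on one row.

### Min–max scaling

Before discriminant analysis every feature is rescaled to
$x' = (x - \min A)/(\max A - \min A)$, mapping the training range onto
$[0, 1]$ so that features with different units and signs (per-mil deltas
vs percentages) contribute comparably. Design choices:

* A constant column maps to 0 with a warning, not `NaN` — it carries no
  discriminant information either way, and LDA input must stay finite.
* Held-out values outside the training range are returned as computed
  (possibly outside $[0, 1]$) and counted in a warning; clipping would
  silently distort fold evaluation.

### Linear discriminant analysis

`fit_lda()` implements the shared-covariance Gaussian classifier from
first principles: class means $\mu_k$; pooled within-class covariance
$\Sigma = \sum_k \sum_{i \in k}(x_i-\mu_k)(x_i-\mu_k)^\top/(N-K)$;
discriminant scores
$\delta_k(x) = x^\top\Sigma^{-1}\mu_k -
\tfrac12\mu_k^\top\Sigma^{-1}\mu_k + \log\pi_k$; posteriors as the
softmax of the scores (exact under the shared-covariance model); and up to
$\min(K-1, p)$ canonical axes from the generalized eigenproblem of
between- vs within-class scatter, solved symmetrically through a Cholesky
whitening of $\Sigma$ so eigenvalues come out real and nonincreasing.

Numerical choices:

* **Ridge stabilization.** When the pooled covariance has condition
  number above $10^{10}$ (or a nonpositive eigenvalue), $\lambda I$ with
  $\lambda = 10^{-8}\,\mathrm{tr}(\Sigma)/p$ is added. Triplicate-per-site
  tiers make near-singular pooled covariances a practical reality, not an
  edge case. The `lambda` actually applied is stored on the fit.
* **Priors** default to class frequencies (`"proportional"`), the common
  default of R's discriminant tooling; `"uniform"` is available since the
  protocol never states priors.
* **Ties** in the discriminant scores break deterministically toward the
  earliest class label (labels are kept sorted), and tied predictions are
  counted and messaged.

`loocv()` refits the model $n$ times, each excluding one sample, and pools
the held-out predictions into a confusion matrix (rows = true class,
columns = predicted). Every class needs at least 3 samples so folds keep
at least 2. Scaling policy: the default `"prefit"` fits the min–max
scaler once on the full table before the loop, matching the stated order
of the original workflow (normalize, then internally cross-validate the
LDA); `"per_fold"` refits the scaler inside every fold and is the
leakage-free variant for honest evaluation. Both are exposed because the
original order is stated but its leakage control is not.

### Report arithmetic

`prediction_rates()` reproduces the reporting conventions of the
reference tables exactly: per-class rates are $100\times$
diagonal/row-sum rounded **half-up** to one decimal (73.077 prints as
73.1), while pooled totals are $100\times$ trace/total **truncated** at
two decimals (56/57 prints as 98.24, not 98.25). The truncation is not
our preference; it is the only convention consistent with the printed
totals, and unrounded values are returned alongside.

## The synthetic-data generator

Raw per-sample measurements behind the reference analysis are not
deposited, so `generate_samples()` emulates them from site-level
structure (`builtin_fixtures()`):

* `"korea_table1"` — 17 Korean sites, regions CC/JB/JN/GN, total
  $n = 102$, per-site mean ± SD of bulk $\delta^{13}$C and
  $\delta^{15}$N. These means and SDs are the published site rows.
* `"csia_table4"` — the same sites, mean ± SD of $\delta^{13}$C for six
  individual FAs, three clams per site ($17 \times 3 = 51$).
* `"countries_table6"` — country-level bulk isotopes for China
  ($n = 15$), DPR Korea ($n = 16$) and Korea ($n = 102$).
* `"fa_profiles_synthetic"` — per-site 15-FA mean compositions. These are
  **constructed, not transcribed**: the per-site abundances were never
  published. The construction keeps every site inside the reported
  compositional envelope (SFA between 26.20 and 65.48 % of total FAs,
  PUFA between 10.23 and 32.33 %), makes 16:0/18:0 the dominant SFAs and
  EPA/DHA the dominant PUFAs, gives GN (and only GN) a DHA/EPA ratio
  above 1 — the dinoflagellate-leaning diet reported there — and
  separates regions by a few percentage points across several FAs, which
  is what lets the FA tier authenticate regionally, as the reference
  analysis found. Within a region, sites differ by a small 16:0-vs-18:0
  trade so class totals stay fixed.

Gaussian features are drawn independently per feature; only marginal
site moments are public, so no assay covariance exists to honor — a real
dataset's correlated measurement structure is **not** emulated, and
passing tests on generated data say nothing about covariance-driven
effects. FA compositions are drawn from a Dirichlet with parameter
(dispersion × mean composition), guaranteeing nonnegativity and unit sum
while centering on the site profile; the dispersion default of 1200 puts
the SD of a 10 % component near 0.9 percentage points, a realistic
within-site assay + biological spread. Seeds are explicit arguments
everywhere (default 0), never global state, and the caller's RNG is
restored after generation.

## The cascade

`run_cascade()` evaluates tier 1 on all samples by LOOCV and routes
unauthenticated material onward. Two readings of "unauthenticated" are
provided because the source protocol is internally ambiguous (triplicates
from *all* 17 sites were escalated, including well-classified regions):

* `"site_rate_below"` (default, with `tau = 100`): all samples of every
  site whose region's per-class prediction rate is below `tau` percent.
  With `subsample_k = 3` this reproduces the triplicate design — 17
  routed sites × 3 = 51 samples.
* `"sample_misclassified"`: exactly the LOOCV-misclassified individuals —
  the stricter reading.

Samples authenticated at a tier keep that tier's LOOCV label; the final
tier's predictions are final (no "unresolved" end state exists, since the
protocol defines none — our interpretation, recorded here). Samples of a
routed site beyond `subsample_k` are marked `subsampled_out` in the
ledger and keep their current-tier label, so final labels always
partition the input. `mode = "parallel"` evaluates tiers 2+ each
independently on the fixed tier-1 subsample rather than nesting them —
the arithmetic of the three-country stepwise summary works this way
(cohorts of 133, then 57, 57).

## Worked example

```{r example}
specs <- merge_specs(
  merge_specs(builtin_fixtures("korea_table1"),
              builtin_fixtures("csia_table4")),
  builtin_fixtures("fa_profiles_synthetic")
)
samples <- generate_samples(specs, seed = 0)
cascade <- run_cascade(samples, policy = "site_rate_below",
                       tau = 100, subsample_k = 3)
cascade
cascade_summary(cascade)
```

On this draw the dual-isotope tier resolves about two-thirds of the
clams (regional overlap in bulk isotopes is real), every region routes
its triplicates, and the FA-profile tier authenticates the 51 escalated
samples, short-circuiting the CSIA tier.

## Problem sizes and tests

The test-suite simulations use the fixture sample sizes themselves
(102-sample bulk tier, 51-sample escalated tiers), 10 replicate seeds for
parameter-recovery checks, 20 for the null-calibration check (two
identical 50-sample classes must stay at chance accuracy), and
1000-case randomized sweeps for the delta and scaling invariants —
ample for the properties checked while keeping the whole suite in
seconds. The classifier is verified two independent ways: against a
quadratic-form Gaussian-posterior oracle on small random instances
(exact agreement), and against `MASS::lda` on fixture-generated data
(equal means and predictions) — the reference implementation is a
cross-check only, never the computation.

## Known limitations

* Site features are independent draws; real isotope–FA covariance, and
  any site-internal structure beyond marginal moments, is absent.
* The synthetic FA compositions are plausible, not measured; FA-tier
  accuracies on generated data characterize the pipeline, not the
  reported assay.
* Seasonality, tide/temperature covariates and baseline (POM/DIN)
  gradients — the mechanisms *behind* the regional signal — are not
  modeled; the generator reproduces the signal's summary statistics only.
* Published confusion matrices cannot be regenerated exactly without the
  raw data; they are carried as fixtures for report arithmetic, and the
  statistical tests target the qualitative structure (partial tier-1
  separation, near-perfect FA tier) instead.
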