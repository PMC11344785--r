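---
title: "Cross-study trait synthesis with full error propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study trait synthesis with full error propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccotraits)
```

## The problem

Coccolithophores are calcifying marine phytoplankton whose contribution to
ocean carbon cycling has to be inferred from cell counts: field surveys
report abundances (cells per litre), while the quantities of
biogeochemical interest are standing stocks of particulate organic and
inorganic carbon (POC, PIC). Converting one into the other requires
per-taxon cellular carbon quotas, and those quotas are only directly
measured for a handful of culturable species. Everything else must be
inferred from cell size through allometry, and cell-size knowledge is
itself scattered across decades of literature in which every study reports
differently: some give raw per-cell values, some a mean with a standard
error or standard deviation, some only a min--max range, and some a bare
mean.

`coccotraits` implements this synthesis as a single, seeded pipeline: it
reconstructs an uncertainty distribution from whatever each study reports,
merges studies, fills gaps with allometric Gamma GLMs, and converts and
grids abundance observations into stock distributions, carrying the
uncertainty through every step.

## Replicate sets: the uncertainty currency

Every trait estimate is represented as a *replicate set*: a sample (by
default `R = 10000` values) of possible trait values for one taxon. The
reconstruction rule depends on the reporting mode:

* **raw values** -- Bayesian bootstrap. Flat-Dirichlet weight vectors are
  drawn over the observed values and values are resampled with those
  probabilities, one fresh weight vector per block of `length(values)`
  draws. This preserves the empirical distribution without any normality
  assumption, smooths relative to the classical bootstrap, and the
  replicate mean concentrates on the sample mean as `R` grows.
* **mean + SE** -- draws from a normal distribution truncated at zero.
  Trait values are physical quantities; negative draws are redrawn
  (rejection, the default, which preserves the mean up to truncation bias)
  or clipped to zero (`truncation = "clip"`, which reproduces the
  behaviour of clipping-based implementations and leaves a point mass at
  zero when the spread is large relative to the mean).
* **mean + SD** -- the SD is first converted to an SE assuming a sample
  size of three (`n_assumed = 3`), reflecting the very small cell counts
  behind such literature reports.
* **min--max** -- the SD is estimated by the conservative range rule
  `SD = (max - min)/2`, then converted as above. The centre is the
  reported mean when present, otherwise the range midpoint (the symmetric
  choice under the normality assumption).
* **bare mean** -- a normalized SE (SE/mean, a coefficient-of-variation
  form chosen because it is scale-free across taxa spanning orders of
  magnitude in size) is bootstrapped from other measurements of the same
  taxon, falling back to the global cross-taxon pool, and rescaled by the
  target mean.

Merging across studies concatenates the studies' replicate sets -- each
study contributes its full error distribution with equal per-replicate
weight; no precision weighting is attempted -- and smooths the pooled set
with one more Bayesian-bootstrap pass before summarising with a mean and
percentile CI (2.5/97.5 by default).

### Why divide the range by two?

The classical range rule divides by four (extremes taken as two SDs from
the mean). Simulation with `range_rule_simulation()` shows why that is the
wrong choice here: the studies that report only ranges measured few cells,
and for a normal sample of size `n` the expected range is `E[range] =
d_n * sigma` with `d_2 = 2/sqrt(pi) ~ 1.13` and `d_5 ~ 2.33`. Division by
four therefore *underestimates* sigma badly at small `n` (about -44% at
`n = 5`), while division by two overestimates it moderately (+16% at
`n = 5`) -- a deliberately conservative error bar. The simulation seeds
draws per `n` only, so the divisor-4 curve is exactly half the divisor-2
curve and the comparison is free of Monte-Carlo noise.

## Cell-size geometry

Cell volumes come from linear measurements under simple solids: spheres
for all taxa except a configured pair (`prolate_taxa()`) treated as
prolate spheroids. Light microscopy (LM) measures the cell directly; SEM
sees only the coccosphere exterior, so SEM sizes are converted either by a
taxon-specific volume fraction (0.3--0.9 across taxa; a fixed universal
ratio can be off several-fold) or by subtracting twice the coccolith
thickness from the coccosphere diameter, applied to both axes for prolate
taxa since no axis-specific rule is defensible from the data. LM and SEM
replicate sets are merged unless their median cell sizes disagree more
than 5-fold, in which case only LM (the more accurate method) is kept and
the taxon is flagged. The fold rule is applied to reconstructed replicate
sets rather than raw measurements, so it sees each method's pooled
central tendency.

Haploid-phase taxa without measurements inherit size from their associated
diploid (HET) phases -- the two phases of a species tend to be similar in
size -- using the replicate-wise mean when there are several associations
(sets are paired by replicate index, which the shared derived-seed scheme
makes meaningful).

## Allometric gap-filling

Cellular carbon scales with volume as a power law. We fit it as a Gamma
GLM with log link on natural-log volume,

$$\mathrm{carbon} \sim \mathrm{Gamma},\quad
\mu = \exp(\alpha + \beta \ln V [+ \gamma\,\mathrm{haploid}]),$$

so that `beta` is the base-free allometric exponent (identical to the
slope of a log10--log10 plot) and predictions are strictly positive with
residual spread growing with the mean -- both appropriate for quota data.
The PIC model carries a one-hot haploid indicator because haploid
morphologies calcify far less at equal volume; heterococcolith and
nannolith morphologies are labelled diploid, holococcolith, ceratolith and
polycrater morphologies haploid.

Model uncertainty is propagated by refitting on `B = 1000` case-resampled
training sets (degenerate resamples -- a single distinct volume, or a
ploidy class absent from a PIC resample -- are redrawn). Quota prediction
then samples, per output replicate, a coefficient vector from the
ensemble, a volume from the taxon's volume replicate set, and a value from
the fitted Gamma predictive distribution at that conditional mean,
stacking model, trait and residual uncertainty.

The conventional Gaussian comparator is fitted as an identity-link linear
model on log10--log10 axes. Because that models the response on a
different scale, its AIC is mapped back onto the natural response scale
via the change-of-variables Jacobian before comparison; the Cox--Snell
pseudo-R^2 (`1 - exp((2/n)(l0 - l1))`, against the intercept-only fit of
the same family) is scale-difference-free and needs no correction. On
Gamma-generated data the Gamma family wins this comparison in the clear
majority of realisations.

## Stocks and gridding

Stocks are `abundance x quota / 10^6` (pg to ug C per litre). Gridding
bins by `floor(lat)`, `floor(lon)` (longitude normalised to
`[-180, 180)`), 5-m depth level, year, month and taxon -- half-open
intervals, lower edge inclusive, labels at the lower edge; these
conventions are arbitrary but must be fixed for reproducible cell counts.
Cells with several observations take the arithmetic mean. Stock CIs are
the quota replicate distribution scaled by the cell's mean abundance:
count uncertainty is deliberately not modelled, only trait uncertainty is
propagated.

The paired LM/SEM abundance comparison (`lm_sem_bias()`) uses the
convention `100*(LM - SEM)/SEM` with SEM as the reference method (LM
misses lightly calcified cells), summarised by Bayesian bootstrap over
pairs; the convention travels in the result metadata because the sign
depends on it.

## The synthetic-data generator

The generators exist so every stage is testable without any external
download, and their defaults are fixed study conditions, not tuning knobs:

* `gen_size_study()` draws cells from a zero-truncated normal (or
  log-normal, to exercise violation of the normality assumption) and then
  reports them in a chosen mode, discarding exactly what that mode hides.
* `gen_allometric_taxa()` draws volumes log-uniform over 10--1000 um^3 and
  carbon from a Gamma around the power law. The default exponent is 0.72
  and the default shape is 1 (residual CV of 1), matching the magnitude of
  the relative prediction errors seen in cross-study quota compilations,
  where scatter is of the same order as the quota itself. Organic-carbon
  presets centre quotas near 67 pg C per cell, inorganic near 16 pg C.
* `gen_abundance_field()` places stations with a northern-hemisphere bias,
  ~75% of casts in the upper 50 m, summer-skewed months, log-normal
  abundances with structural zeros, and a 30% station-revisit fraction
  emulating the time-series and repeat-transect structure that makes
  gridding aggregate in real compilations.

What passing tests on these fixtures does *not* show: robustness to the
taxonomic messiness of real source tables (the registry handles the
mechanics, but curation quality is a data problem), to non-normal size
distributions beyond the log-normal option, or to the spatial covariance
of real oceanographic sampling. The generator makes no attempt to clone
the real archives statistically.

## Numerical choices and problem sizes

* Replicate counts default to `R = R_out = 10000`, which stabilises the
  2.5/97.5 percentiles; the test suite and the reproduction script scale
  down to 400--10000 replicates and 50 recovery seeds, sizes chosen to
  keep a full run in tens of seconds while leaving Monte-Carlo error well
  inside the asserted tolerances.
* All randomness flows from one master seed through `derive_seed()`, a
  rolling string hash modulo 2^31 - 1 over task labels (task, taxon,
  variable, source), so results are independent of processing order and
  safe to parallelise per taxon.
* Zero-truncation is asserted on every replicate set; a constant set
  yields a degenerate (point) CI by construction.
* Gamma GLM fits use `stats::glm` with up to 200 IRLS iterations;
  noise-free fits drive the dispersion to zero, whose known-benign NaN
  warning from the family's internal AIC is muffled, and quota prediction
  degenerates cleanly to the conditional mean when dispersion falls below
  1e-12.
* Ties at bin edges follow lower-edge inclusion everywhere (a depth of
  exactly 5 m is in the 5--10 m bin).

## Known limitations

* Studies are pooled by concatenation, not by a hierarchical
  meta-analytic model; precise studies are not up-weighted.
* The assumed sample size of three behind SD-only reports is a convention,
  and the SE-imputation pool is a coefficient-of-variation heuristic.
* Gridded output is long-format CSV; no interpolation of unsampled cells
  and no climatological averaging across years is performed.
* Allometric predictions outside the fitted volume range extrapolate the
  power law; the model card records the training range but no hard guard
  is imposed.
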