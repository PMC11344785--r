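# coccotraits

Trait synthesis and carbon stock estimation for coccolithophores — an R
package for reconstructing per-taxon cell-size and cellular POC/PIC
distributions from heterogeneous multi-study measurements, with full error
propagation, allometric gap-filling, and conversion of abundance
observations into gridded carbon-stock distributions.

## Who this is for

Plankton ecologists and ocean biogeochemists who need per-taxon cellular
carbon quotas — and honest uncertainty on them — to turn cell counts into
carbon stocks. The machinery (cross-study error propagation by sample
reconstruction, Bayesian-bootstrap merging, Gamma-GLM allometry with
bootstrap ensembles) is general and applies to any plankton group whose
trait literature mixes reporting conventions.

## The core method

Each study's report of a trait is reconstructed into a *replicate set* — a
sample of possible values representing that study's error distribution:

| reported as  | reconstruction |
|---|---|
| raw values   | Bayesian bootstrap (flat-Dirichlet weights, blockwise) |
| mean ± SE    | zero-truncated normal |
| mean ± SD    | SE = SD/√3 (assumed n = 3), then truncated normal |
| min–max      | SD = (max − min)/2 (conservative range rule), then as above |
| bare mean    | SE borrowed by bootstrapping normalized SEs (SE/mean) from the same taxon, else globally |

Studies are merged by concatenating their replicate sets and smoothing
with one Bayesian-bootstrap pass, summarised as mean and 2.5/97.5
percentile CI. For taxa without direct carbon measurements, quotas come
from an allometric Gamma GLM with log link,

    carbon ~ Gamma,  mu = exp(alpha + beta * ln V [+ gamma * haploid]),

where `beta` is the allometric exponent (equal to the slope on log10–log10
axes) and the haploid offset enters the PIC model because haploid
morphologies calcify far less. Model uncertainty is carried by an ensemble
of case-resampled refits; prediction stacks model, trait and residual
(Gamma) uncertainty. Stocks are `abundance × quota` (pg → µg C L⁻¹),
gridded at 1° × 5 m × month with half-open bins and per-bin means.

See the vignette `vignettes/trait-synthesis.Rmd` for the full account of
the model, its assumptions and its numerical choices.

## Worked example

Two studies report the cell diameter of *Gephyrocapsa oceanica* HET in
different modes; we reconstruct, merge, predict an organic-carbon quota
allometrically, and convert an abundance into a stock:

```r
library(coccotraits)

study_a <- measurement("Gephyrocapsa oceanica HET", "diameter_um", "mean_se",
                       mean = 10, se = 2, method = "LM", source = "study_a")
study_b <- measurement("Gephyrocapsa oceanica HET", "diameter_um", "min_max",
                       min = 8, max = 16, method = "SEM", source = "study_b")
sets <- lapply(list(study_a, study_b), function(m)
  reconstruct(m, R = 10000, seed = derive_seed(42, m$source)))
merged <- merge_replicates(sets, R_out = 10000, seed = derive_seed(42, "merge"))
merged$estimate
#> <merged_estimate> mean 10.98, CI [6.582, 15.63] (R=10000, 2 studies)

pts <- gen_allometric_taxa(alpha = log(1.6), beta = 0.72, n_points = 42, seed = 1)
fit <- fit_glm(pts, "POC", B = 200, seed = 2)
fit
#> <allometric_model> POC, gamma family: exponent 0.845, intercept -0.288, dispersion 1.04, n=42
#>   bootstrap ensemble: B=200 refits
#>   MAE 59 / RMSE 115 pg C (rel. 84% / 164%), Cox-Snell R2 0.57, AIC 401.5

vol <- replicate_set("Gephyrocapsa oceanica HET", "volume_um3",
                     volume_sphere(merged$set$values))
quota <- predict_quota(fit, vol, R = 10000, seed = derive_seed(42, "quota"))
summary(quota)
#> <merged_estimate> mean 207.7, CI [3.316, 983.2] (R=10000, 1 studies)

stock <- abundance_to_stock(50000, quota)
sprintf("POC stock: %.2f ug C/L [%.2f, %.2f]",
        mean(stock), quantile(stock, 0.025), quantile(stock, 0.975))
#> "POC stock: 10.38 ug C/L [0.17, 49.16]"
```

Reading the numbers: the merged diameter distribution (mean ~11 µm) folds
together both studies' error distributions; the 42-point training set
yields an exponent of 0.845 with an SE near 0.12 (the true generating
exponent is 0.72 — at this sample size and quota-scale scatter that is the
honest precision); the quota CI spans two orders of magnitude because
size uncertainty, model uncertainty and natural quota variability are all
propagated, and the stock CI inherits all of it.

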