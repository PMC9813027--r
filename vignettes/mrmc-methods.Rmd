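---
title: "Methods: multireader multicase ROC analysis with a two-way clustered bootstrap"
author: "mrmcboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multireader multicase ROC analysis with a two-way clustered bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcboot)
```

## The study design this package analyses

`mrmcboot` analyses fully crossed multireader multicase (MRMC)
diagnostic-accuracy studies of breast imaging: every reader rates every
breast under every reading mode. The reference design the package is
built around has 388 breasts in 194 patients (both breasts of each
patient, MLO view only), four readers, and two sequential reading
sessions — a 2D image read alone and then re-read with the
tomosynthesis (DBT) stack, once with the conventional digital mammogram
(`DM`, `DM_DBT`) and once with an AI-CAD-enhanced synthesized mammogram
(`AICAD_SM`, `AICAD_SM_DBT`). Each rating is a forced five-point BI-RADS
category, and a probability-of-malignancy (POM, 0–100) is elicited only
when the BI-RADS score is 3 or higher. The case mix is fixed by design:
84 cancers, 83 biopsy-proven benign lesions, and 221 normal or benign
breasts that were negative at follow-up; benign and normal breasts
together form the non-diseased class for every accuracy metric.

Three analysis layers sit on this design:

* **Empirical ROC / AUC** per reader × mode, on either the POM scale or
  the forced BI-RADS scale.
* **Random-reader random-case inference** on reader-averaged AUC
  differences between paired modes, via a two-way bootstrap (patient
  clusters × readers) with percentile confidence intervals and bootstrap
  P values.
* **Sensitivity / specificity** at the BI-RADS 4–5 positivity rule,
  overall and within breast-density and lesion-type strata.

A latent-score simulator generates complete synthetic studies with this
structure so that every stage is testable with known ground truth; no
raw reader ratings from any real study are distributed or required.

## Scores and the empirical ROC

Scores are oriented so larger = more suspicious, and a case is called
positive when its score is at or above the sweeping threshold.

**POM scale completion.** POM is elicited only for BI-RADS ≥ 3, yet the
POM-based ROC runs over all breasts. The package maps BI-RADS 1 → −2 and
BI-RADS 2 → −1, below every legal POM value (0 is a legal POM and must
outrank both). Any strictly order-preserving completion yields the same
empirical ROC; this one keeps the 1 < 2 distinction and is declared as
the reference. A `pool_negatives` switch collapses 1 and 2 to a single
tie group for sensitivity analysis, since it is equally defensible that
a study's analysts pooled them.

**Ties.** The AUC is the trapezoidal area over the operating points,
identical to the tie-corrected Mann–Whitney statistic
\[(\#\{x_+>x_-\} + \tfrac12\#\{x_+=x_-\}) / (n_+ n_-).\]
Ties get half credit and are never broken randomly, so every result is
deterministic. The test suite proves the trapezoid/pair-statistic
identity exhaustively on small instances and on random tied instances,
and cross-checks against an independent ROC implementation.

## Random-reader random-case inference

The reader-averaged AUC difference between two modes is the inferential
target. Both readers and cases are treated as random samples:

1. **Case resampling.** Patients — not breasts — are resampled with
   replacement; a drawn patient contributes both breasts with all their
   ratings. This respects the within-patient correlation of the two
   breasts, which is the stated reason for the random-case model.
   Breast-level resampling is available behind the `cluster` flag for
   sensitivity analysis. Resampling is not stratified by truth class;
   case resamples on which an AUC is undefined (single truth class) are
   redrawn, with the count reported in every result object.
2. **Reader resampling.** Nested within each of the 1000 case resamples,
   100 reader resamples draw the reader identities with replacement; a
   duplicated reader contributes its AUC multiply to the mean. The
   reference analysis therefore uses 1000 × 100 = 100,000 resamples.
3. **Pairing.** Both modes are evaluated on the *same* case and reader
   draws in every iteration, so shared variation cancels exactly as in
   the paired design.

**Percentile interval.** Nearest-rank quantiles of the sorted bootstrap
differences: ranks `ceiling(alpha/2 * B)` and `ceiling((1-alpha/2) * B)`,
clamped to `[1, B]`. With `B = 100` and `alpha = 0.1` this is the 5th
and 95th order statistic.

**P value.** The two-sided +1-corrected percentile form
\[p = 2\min\Big(\frac{\#\{d^* \le 0\}+1}{B+1},\ \frac{\#\{d^* \ge 0\}+1}{B+1}\Big)\]
capped at 1. The correction keeps P strictly positive (minimum
`2/(B+1)`); the exact convention is declared here because percentile
P values can be computed in several near-equivalent ways.

**Randomness.** One master seed drives a single sequential RNG stream
(`set.seed` once, then strictly ordered draws). The bootstrap loops are
sequential, so this is exactly reproducible: identical spec and dataset
give identical CIs and P values. Per-iteration substreams would only be
needed for out-of-order (parallel) execution, which the implementation
does not do.

## Binary metrics

Positivity is BI-RADS ≥ 4 (categories 4–5); BI-RADS 1–3 is negative.
Sensitivity and specificity are pooled over readers (total counts) —
with a fully crossed design this coincides with the reader average, but
pooling is the declared reference. Strata:

* `overall`, `non_dense`, `dense`: sensitivity over the stratum's
  malignant breasts, specificity over all its non-malignant breasts.
* `soft_tissue` (mass, mass with calcifications, focal asymmetry) and
  `calcification`: finding type is a lesion attribute, so the
  specificity denominator is the *benign lesions* of that group only;
  normal-negative breasts do not enter. `distortion` is available
  descriptively but is outside the two named groups.

An empty denominator yields a flagged `NA`, never a silent `NaN`. The
stratum conventions are declared, not inferred; published stratified
specificities computed under unknown denominator conventions are
therefore not treated as reproduction targets.

## The synthetic-data generator

For breast $k$ in patient $p$, reader $j$, mode $m$:
$$x_{jkm} = \mu_m\,[\text{malignant}_k] + \delta_b\,[\text{benign}_k]
  + r_j + c_k + (rc)_{jk} + \varepsilon_{jkm}$$
with $r_j \sim N(0, \sigma^2_r)$,
$c_k = \sigma_c(\sqrt{\rho}\,u_p + \sqrt{1-\rho}\,w_k)$,
$(rc)_{jk} \sim N(0, \sigma^2_{rc})$ shared across modes, and
$\varepsilon \sim N(0, \sigma^2_\varepsilon)$ independent per mode. The
forced BI-RADS category comes from four ordered cutpoints on the latent
scale; the POM is a deterministic monotone probit squash of the latent
score, rounded to an integer, emitted only when BI-RADS ≥ 3. A
deterministic map (rather than jittered) is used so that POM order
provably agrees with latent order within every reader × mode; integer
rounding already supplies realistic coarseness.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| composition | 84/83/221 in 194 patients | the reference design, exact counts not expectations |
| density | 206 non-dense / 182 dense | assigned per patient (103/91 patients), preserving the 53% non-dense margin |
| finding margins | 49/15/2/4/14 malignant, 34/1/3/6/39 benign | the reference lesion mix |
| $\sigma^2_r,\sigma^2_c,\sigma^2_{rc},\sigma^2_\varepsilon$ | 0.05, 1, 0.1, 1 | small reader effect, case variance comparable to residual — the usual regime of latent-score reader-study models |
| $\rho$ | 0.5 | moderate within-patient correlation; the motivation for patient-level resampling |
| $\delta_b$ | 0.8 | biopsy-proven benign lesions drew suspicion in reality, so they sit between normal and malignant |
| cutpoints | 0.5, 1.5, 2.6, 3.5 | put the BI-RADS ≥ 4 operating point of a 0.87-AUC mode at roughly 94% specificity, a plausible diagnostic-setting regime |
| target AUC | 0.871 / 0.902 / 0.895 / 0.909 (POM) | the reference per-mode reader-averaged operating points |

Composition, density and finding margins are generated *exactly* (draws
are permutations of fixed label multisets), and the full 388 × 4 × 4
rating grid is always emitted — 3104 two-rating session reports with no
missing data.

**Calibration.** `calibrate_mu()` inverts the model's population AUC for
a target. On the latent scale this is binormal:
$\mathrm{AUC} = \Phi\big(\mu/\sqrt{2(\sigma^2_c+\sigma^2_{rc}+\sigma^2_\varepsilon)}\big)$,
mixture-weighted when benign lesions are shifted. The generator's
default, however, calibrates on the *observed* POM scale: because
BI-RADS 1–2 cases carry no POM and collapse to two tie groups, the
POM-scale AUC is systematically about 0.02 below the latent AUC at these
operating points. The observed-scale inversion (numerical root of a
semi-analytic tie-corrected AUC, marginalized over the reader effect)
makes the generator's population AUC equal the target on the scale the
analysis actually uses; with it, the mean reader-averaged POM AUC across
replicate studies reproduces the target within Monte-Carlo error, which
is exactly what the parameter-recovery tests assert.

**What the generator does not emulate.** No reading-order or wash-out
effects; no within-session correlation beyond the shared case and
reader terms (the 2D and +DBT scores of a session share $c_k$, $(rc)_{jk}$
and differ by $\mu_m$ and fresh residuals); no reader × modality
heterogeneity (every reader gets the same $\mu_m$); POM coarseness only
via integer rounding; lesion sizes and histology are decorative
covariates, not drivers of the latent score unless a per-finding mode
adjustment is configured. Passing tests therefore demonstrate the
pipeline's arithmetic and its statistical calibration *under this
model* — not that any particular real study's numbers are recoverable,
which they are not, since raw ratings of the reference study were never
released.

## Operating characteristics and a known limitation

The test suite measures the inference layer's operating characteristics
on replicate synthetic studies (problem sizes chosen to keep the suite
fast: 200 null replicates with a 200 × 50 bootstrap for size; 100
replicates for parameter recovery; 120 replicates with a 250 × 40
bootstrap for coverage):

* the built-in reader-averaged AUC difference of 0.031 is recovered in
  the mean across replicates within Monte-Carlo error;
* the null rejection rate at nominal 0.05 measures about 0.015, and the
  95% percentile interval covers the true difference in essentially all
  replicates — i.e. the two-way bootstrap is **conservative** under
  these conditions.

The conservatism has a clean mechanism. The reader-resampling dimension
estimates the between-reader variance of the per-reader AUC difference
from its empirical dispersion. On any finite case set, that dispersion
mixes true reader × modality heterogeneity with reader-specific residual
noise — and the residual noise is *also* captured by the case-resampling
dimension, so it is counted twice. In the generator's null world the
true reader × modality heterogeneity is exactly zero, making the double
count maximally visible (bootstrap SD about 1.7× the true sampling SD
of the difference). In real studies, where readers genuinely differ in
how much a modality helps them, the reader dimension captures mostly
real variance and the method sits closer to nominal. The package
implements the naive two-way bootstrap deliberately — it is the declared
inference method of the study design it reproduces — and reports the
measured conservatism rather than substituting a variance-corrected
(e.g. ANOVA-based) MRMC estimator, which is out of scope.

## Numerical conventions

* Full precision everywhere internally; rounding only at serialization,
  half-up (0.8945 → 0.895 at 3 dp): 3 dp for AUCs, 1 dp for
  percentages, 2 dp for per-lesion mean BI-RADS.
* Degenerate bootstrap resamples: redrawn with a bounded retry budget
  (default 1000), then an error; the redraw count is part of every
  result.
* `calibrate_mu` root-finding: `uniroot` on $[-2, 25]$ at tolerance
  1e-8; the observed-scale AUC integrates tie corrections with
  `integrate` (rel.tol 1e-9) and marginalizes the reader effect on a
  41-point ±4.5 SD grid.
* CSV dialect: UTF-8, comma-separated, mandatory header, lower-snake
  categoricals, absent POM as an empty field (never 0).

## Command-line use

`inst/cli/mrmcboot.R` is a thin wrapper over the package functions:

```
Rscript $(Rscript -e 'cat(system.file("cli","mrmcboot.R",package="mrmcboot"))') \
  simulate --out study/ --seed 7
... validate --truth study/truth.csv --ratings study/ratings.csv
... analyze  --truth study/truth.csv --ratings study/ratings.csv \
             --comparisons DM:AICAD_SM --boot 1000x100 --seed 7 --out cmp.json
... report   --truth study/truth.csv --ratings study/ratings.csv --out report/
```

Logs (timestamped, with seeds and degenerate-resample counts) go to
stderr; artifacts are byte-identical across runs with the same seed.

## A worked micro-example

```{r example}
cfg <- sim_config_small()
ds <- simulate_study(cfg, seed = 1)
validate_completeness(ds)$complete
fit <- mrmc(ds, comparisons = list(c("DM", "AICAD_SM")),
            spec = boot_spec(200, 20, seed = 1))
coef(fit)
fit$comparisons[[1]]
```
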