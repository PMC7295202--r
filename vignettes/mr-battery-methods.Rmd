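---
title: "Methods: the two-sample MR estimator battery"
author: "mrbattery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-sample MR estimator battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbattery)
```

# The inferential problem

Two-sample Mendelian randomization estimates the causal effect of an exposure
on an outcome from GWAS summary statistics alone. The data are per-SNP pairs
$(\hat\beta_{Xj}, \sigma_{Xj})$ and $(\hat\beta_{Yj}, \sigma_{Yj})$ from two
non-overlapping samples. Under the three instrumental-variable assumptions
(relevance, independence from confounders, exclusion restriction), each Wald
ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal effect
$\beta$, and pooling the ratios across independent instruments yields a
precise estimate. Because the exclusion restriction is untestable per SNP,
practice runs several estimators whose validity fails in different ways, plus
diagnostics; agreement across the battery is the evidential standard, and
this package reproduces that whole workflow.

# Harmonization and conventions

Exposure and outcome records are matched by rsid only (instrument sets arrive
pre-pruned and positionally annotated data are carried but unused). Outcome
records with swapped allele labels have $\hat\beta_Y$ negated; labels that
match neither directly nor swapped are tried on the complementary strand
before being dropped, and every drop is itemized by reason. Palindromic (A/T,
C/G) variants are kept but flagged by default — when both datasets come from
one genotyping pipeline a shared strand convention makes them unambiguous —
and `drop_palindromic = TRUE` gives the conservative alternative. We do not
infer strand from allele frequency, which is often absent.

Each pair is re-expressed on the exposure-increasing allele
(`orient_beta_x_positive`, default on). This is neutral for every estimator
but fixes the sign convention the Egger intercept needs and makes plots
comparable. Estimates are computed per unit *later* exposure and reversed at
reporting time (`reverse_direction()`: negate, swap the negated interval);
binary-outcome results are exponentiated to odds ratios afterwards, never
before. A SNP whose oriented $\hat\beta_X$ is exactly zero is retained —
regression-form estimators handle it — but cannot contribute a Wald ratio and
is excluded from ratio-based estimators with a warning.

# Estimators

**IVW.** $\hat\beta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
\hat\beta_{Xj}^2$ with $w_j = \sigma_{Yj}^{-2}$; fixed-effect SE
$(\sum w_j \hat\beta_{Xj}^2)^{-1/2}$. The random-effects variant (battery
default) scales the SE by $\max\{1, \sqrt{Q/(L-1)}\}$ — multiplicative
overdispersion floored at one, so balanced pleiotropy widens intervals
without moving the point estimate, and the model can never claim more
precision than the fixed-effect fit.

**MR-Egger.** Weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ with a
free intercept, weights $\sigma_{Yj}^{-2}$, inference on $t_{L-2}$ with the
*estimated* multiplicative dispersion. We deliberately do not floor the Egger
dispersion at one: with normal errors and known relative weights the
unfloored $t$-test is exactly calibrated, whereas the floored variant used by
some toolkits suppresses rejections whenever the dispersion estimate falls
below one and empirically rejects a true null intercept at ~0.04 instead of
0.05. The floored convention remains available (`floor_dispersion = TRUE`);
its one practical advantage — a nonzero SE when the points are exactly
collinear — matters only in degenerate inputs. The slope requires InSIDE;
the intercept estimates the mean direct effect per instrument.

**Weighted median.** Per-SNP ratios with first-order weights
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$; the estimate is the 50% point of the
cumulative normalized weights over the sorted ratios, linearly interpolated
between the bracketing ratios. SE by parametric bootstrap (resampling
$\hat\beta_X, \hat\beta_Y$ from their sampling distributions; default
`b_boot = 1000`, seeded). The description sometimes given as "the estimate
with the median inverse-variance weight" is a misreading of this standard
definition, which is what we implement.

**Mode-based estimate.** Normal-kernel density over the ratios (weights as
above, or uniform), bandwidth $\varphi\, s$ with
$s = 0.9\min(\mathrm{sd}, \mathrm{MAD}/0.6745)\,L^{-1/5}$ on the ratio
sample and $\varphi = 0.5$ by default; maximized on a 512-point grid spanning
the ratio range padded by $3h$, ties broken toward the smaller $|\beta|$. A
degenerate ratio sample (zero spread) returns the common value. SE by the
same parametric bootstrap.

**Allele-score meta-analysis.** Fixed-effects inverse-variance pool of the
aligned SNP–outcome effects; units are outcome change per additional
exposure-increasing allele, not per unit exposure, which is why the battery
reports it separately.

**Ratio SE.** First-order delta method $\sigma_{Yj}/|\hat\beta_{Xj}|$
throughout; the second-order form is available behind a flag.

# Diagnostics and the SIMEX correction

Cochran's $Q$ is computed in the residual form
$\sum_j (\hat\beta_{Yj} - \hat\beta\,\hat\beta_{Xj})^2/\sigma_{Yj}^2$ at the
fixed-effect IVW solution — algebraically the first-order-weighted ratio form
but defined also at $\hat\beta_{Xj}=0$ — with $L-1$ df. Radial MR regresses
$\hat\beta_Y/\sigma_Y$ on $\hat\beta_X/\sigma_Y$ through the origin; the
squared standardized residuals are per-SNP $Q$ contributions (summing exactly
to $Q$) and exceed the upper-$\alpha$ $\chi^2_1$ quantile for flagged
outliers. The default $\alpha = 0.05/L$ is Bonferroni-corrected; the
uncorrected level is a parameter. Mean F is the mean squared exposure
$t$-statistic.

$I^2_{GX}$ quantifies how much sampling error in $\hat\beta_X$ dilutes the
Egger slope: with $v_j = \sigma_{Xj}^{-2}$ and $m$ the $v$-weighted mean of
$|\hat\beta_X|$, $Q_{GX} = \sum v_j(|\hat\beta_{Xj}|-m)^2$ and $I^2_{GX} =
\max\{0, (Q_{GX}-(L-1))/Q_{GX}\}$. The weighted variant folds the Egger
weights into the variables (applies the same statistic to
$|\hat\beta_X|/\sigma_Y$ with errors $\sigma_X/\sigma_Y$); the unweighted
variant is the default and gates the correction: whenever unweighted
$I^2_{GX} < 0.9$ the battery runs SIMEX on the *unweighted* Egger fit.

SIMEX adds noise $N(0, \lambda\sigma_{Xj}^2)$ to each $\hat\beta_{Xj}$ for
$\lambda \in \{0, 0.5, 1, 1.5, 2\}$, averages the unweighted Egger fit over
`b_reps = 200` pseudo-datasets per $\lambda$, and extrapolates a quadratic in
$\lambda$ to $-1$. Variances follow the jackknife construction: per
$\lambda$, the mean model-based variance minus the between-pseudo-dataset
variance, extrapolated on the same grid and floored at a numerical epsilon.
We chose this over the simpler spread-of-pseudo-estimates SE because the
latter measures only simulation noise and vanishes as `b_reps` grows — it is
not a standard error of anything. A grid containing only $\lambda = 0$
returns the naive unweighted fit exactly. SIMEX trades bias for variance:
the correction reliably lowers the mean absolute error when the instrument
is large (hundreds of SNPs, as in the larger instrument this package's
checks emulate), while for very small instruments the extrapolation variance
can swamp the bias removed.

# Phenotype derivation

`derive_outcomes()` applies the questionnaire recoding rules: sexual-debut
ages earlier than menarche are blanked (we blank the debut age — the
implausible report — not menarche; `blank_both` flips this, and the choice is
deliberately configurable because the raw records do not say which field is
wrong); a never-attended-school sentinel blanks the education age; counts of
children and sexual partners are blanked strictly above their within-sample
99.99th percentile (linear-interpolation quantile, values equal to it kept —
note that on very small samples the interpolated quantile sits below the
maximum, so unit fixtures pin the cutoff explicitly); the reproductive period
is defined only beyond the first child; childlessness, ever-smoking (any
non-"never" answer on either question; a lone "never" with the other
question missing stays missing), alcohol frequency (never = 6 … daily = 1),
risk taking (yes = 1) and partner counts conditional on sexual debut follow
the stated codings. Trimming is applied after the other recodings; the order
is configurable via precomputed cutoffs.

`snp_outcome_assoc()` fits, per SNP, outcome ~ dosage + birth year + PC1–10
(+ genotype array on request): linear for continuous outcomes, logistic for
binary ones (so the coefficient is the log odds ratio per effect allele),
complete cases per outcome with the per-SNP N recorded. A separated logistic
fit is kept as a flagged record with missing coefficients rather than
silently reported.

# The synthetic-data generator

`sim_config()` encodes the generative model: $L$ independent biallelic SNPs
with frequencies in `maf_range`; per-allele effects $\gamma_j$ rescaled so
the instruments jointly explain exactly `target_r2` of the unit-variance
exposure; a standard-normal confounder loading on exposure and outcome; the
outcome as $\beta X$ + confounding + per-SNP direct effects + noise, with a
logistic link for binary outcomes. Summary statistics are drawn directly as
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj} \sim N(\beta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ with SEs
from $\sigma \approx (2p_j(1-p_j)n)^{-1/2}$ (information-based for binary
outcomes), independent across the two sides as in a non-overlapping design.

Defaults mirror the emulated study arm: 116 instruments explaining 3% of
exposure variance with a discovery sample of 182,416, and an outcome sample
of 120,000 (the middle of the per-outcome complete-case range such cohort
analyses report); the stronger-instrument checks use the alternative arm of
305 instruments, 7% variance explained, discovery N 329,345. Confounder
loadings default to 0.3 on each trait — moderate confounding of the kind MR
is deployed against.

Two generator choices deserve emphasis. First, effect magnitudes are drawn
from a half-normal truncated below at 0.25 SD (then rescaled to `target_r2`):
instruments are genome-wide significant by construction, so effects
indistinguishable from zero — which would make orientation by the estimated
sign error-prone and spuriously shrink directional pleiotropy toward balance
— do not occur; the truncation point is kept low because MR-Egger's
identification lives off the *spread* of instrument strengths, which heavier
truncation would destroy. Second, direct (pleiotropic) effects are defined on
the exposure-increasing allele, so a directional mean survives orientation;
`inside_violating` correlates them with instrument strength (default
correlation 0.5) to create the failure mode MR-Egger cannot handle. The
NOME-violating regime inflates the exposure-side sampling error (reported in
the SEs — the violation is *non-negligible* error, not hidden error), which
drags $I^2_{GX}$ down and dilutes the Egger slope.

All randomness flows from one seed through a named-stream splitter
(`split_seed`), so each operation is reproducible in isolation and streams
do not collide across battery stages.

What the generator does *not* emulate: linkage disequilibrium between
instruments (they are independent by design), sample overlap between the two
GWAS (a documented caveat of weighted analyses, handled in the emulated
design by the allele-score route rather than modelled), selection into the
cohort, and assortative mating or dynastic effects. Passing tests therefore
demonstrate the statistical machinery under the stated generative model, not
robustness to those real-data complications.

# Numerical choices and checks

- MBE grid: 512 points, range padded by three bandwidths; exact density ties
  resolved toward the smaller absolute effect.
- Weighted-median interpolation: cumulative-weight midpoints, clamped at the
  extreme ratios when 50% falls outside them.
- Bootstrap draws with $\hat\beta_X^* = 0$ are dropped within that resample.
- SIMEX extrapolation is quadratic (linear if the grid has fewer than three
  points); the extrapolated variance is floored at $10^{-12}$.
- p-values: two-sided normal for ratio/IVW/meta and bootstrap-based methods,
  $t_{L-2}$ for Egger.

The test suite checks the estimators against independently coded oracles
(weighted regression via `lm`, brute-force weighted-quantile enumeration, a
fine-grid kernel-mode search, `metafor`'s fixed-effect model), and the
statistical properties by simulation: IVW interval coverage and Egger
intercept type-I error within the exact binomial band at 1000 null
replicates of 50-SNP studies; recovery of a causal effect of 0.3 by all four
estimators within three Monte-Carlo SEs at 500 replicates of the
stronger-instrument arm (30 SNPs drawn at the 7%/329k conditions, where
weak-instrument dilution is negligible relative to Monte-Carlo error);
Egger-intercept recovery of a 0.02 directional pleiotropy mean; weighted
median unbiasedness under 30% invalid weight with balanced direct effects
(under one-sided direct effects the median's quantile shift scales with the
ratio sampling error exactly as the Monte-Carlo error does, so the honest
demonstration there is that its bias is several-fold smaller than IVW's,
which is also asserted); MBE unbiasedness with a 60% invalid majority split
into two symmetric minority clusters; and the SIMEX mean-absolute-error
improvement at the 305-SNP scale in an $I^2_{GX} \approx 0.6$ regime. These
problem sizes are the package's chosen demonstration conditions and are
stated here so they can be judged, not tuned.

# Limitations

No multivariable MR, MR-PRESSO, contamination-mixture or Steiger filtering;
no LD-aware clumping or proxy lookup (instruments must arrive pruned); no
second-order radial weights or Rücker model selection; no correction for
sample overlap. The battery reports unadjusted p-values per outcome —
multiple-testing control across outcomes is left to the analyst, matching
the reporting convention of the studies this package serves.
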