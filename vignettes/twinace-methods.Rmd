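---
title: "Bivariate twin/sibling liability models for endophenotype validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate twin/sibling liability models for endophenotype validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The model

`twinace` fits a bivariate ACE model to pairs of relatives, jointly over a
continuous cognitive measure $y$ and a binary diagnosis $d$. Each trait is
decomposed into additive genetic (A), shared environmental (C) and unique
environmental (E) latent factors. A factors correlate $R_A$ across the two
members of a pair ($R_A = 1$ for MZ twins, $\tfrac12$ for DZ twins and full
siblings), C factors correlate 1, E factors 0. The diagnosis is the
indicator that a latent standard-normal liability $\ell$ exceeds a
threshold $\tau = \Phi^{-1}(1-K)$, where $K$ is the population prevalence.
Cross-trait dependence enters through factor correlations $r_g$, $r_c$,
$r_e$. The implied covariance of $(y_1, y_2, \ell_1, \ell_2)$ is assembled
by the usual path rules, e.g.
$\mathrm{cov}(y_1, \ell_1) = r_g a \sqrt{h^2_d} + r_c c \sqrt{c^2_d} +
r_e e \sqrt{e^2_d}$ and
$\mathrm{cov}(y_1, \ell_2) = R_A r_g a \sqrt{h^2_d} + r_c c \sqrt{c^2_d}$.

Non-twin siblings are stored as their own zygosity class (`SIB`) but share
DZ expectations for A and C; no extra twin-specific correlation parameter
is fitted. Opposite-sex DZ pairs are retained, with sex handled as a
member-level covariate on the cognitive mean.

### Likelihood

Each pair contributes the likelihood of exactly what was observed
(full-information maximum likelihood, so missing data need no imputation):
the observed cognitive sub-vector contributes a 1- or 2-variate normal
density, and the observed affection pattern contributes the probability of
the corresponding orthant of the *conditional* normal distribution of the
liabilities given the observed cognition. Orthant probabilities use an
in-package implementation of the standard hybrid bivariate-normal CDF
algorithm (arcsine-transformed Gauss–Legendre quadrature for
$|\rho| \le 0.925$, an asymptotic expansion near $|\rho| = 1$), accurate to
about $5\times10^{-16}$; the unit tests verify it against
`stats::integrate`, and an acceptance test verifies the whole pair
likelihood against independent brute-force quadrature over the latent
liabilities to $10^{-6}$.

### Ascertainment correction by fixed parameters

Because study samples are recruited through affected probands, nothing
about the disease side is estimable from them without bias. The package
therefore never estimates $h^2_d$, $c^2_d$, $e^2_d$ or $\tau$: they are
fixed at published population values, shipped as named profiles
(`maudsley_sz`, `maudsley_bd1`, `maudsley_broad` for the main analysis;
`polderman_sz`, `polderman_bd1` for the sensitivity analysis). One printed
sensitivity set (SZ: $h^2=0.77$, $c^2=0.01$, $e^2=0.21$) sums to 0.99; the
package takes $e^2 = 1 - h^2 - c^2 = 0.22$ so the liability variance is
exactly 1 — the fixed cross-twin correlations (0.78 MZ, 0.395 DZ/sibling)
are unchanged by this.

Covariates (centred age and education, 0/1 sex, research centre as
reference-coded indicators) act on the cognitive mean only. The liability
threshold carries no covariate shift: every disease-side parameter is
fixed, and adding covariate effects there would contradict the fixed
prevalence. Centring is for optimizer conditioning only; estimates are
invariant to affine rescaling of the measure (a tested property).

An `ace_fit` with `free_disease_h2 = TRUE` deliberately breaks the
correction by estimating $h^2_d$; on ascertained samples this inflates it
(see "What the tests establish"), which is the empirical argument for
fixing it.

### Parameterization and optimization

Internally the cognitive trait uses log total variance plus a
stick-breaking map for $(h^2, c^2)$ (logistic transforms, $e^2 \ge 10^{-3}$)
and $\tanh$ maps for the correlations, so the optimizer (`nlminb`,
quasi-Newton with numerical gradients) works on an unconstrained scale.
Fits use five starts by default — one from moment estimators (MZ/DZ
intraclass correlations), the rest jittered deterministically from the
user's seed — and report the best converged solution with its gradient
norm. When the active disease profile has $c^2_d = 0$ (all shipped
profiles except `polderman_sz`), $r_c$ is structurally unidentified and is
fixed at 0, and $r_{ph\text{-}c}$ is reported as exactly 0. Published
tables instead show $r_c$ pinned at a bound with an uninformative CI; the
convention here is declared rather than matched, and makes the
non-identification explicit.

### Confidence intervals and tests

Intervals are profile-likelihood based: the endpoint is where the profile
deviance $2(\hat\ell - \ell_p)$ crosses $\chi^2_1(0.95) = 3.841$, found by
an expanding search plus root bisection, each profile point refit from
both the warm previous solution and the MLE (single-start profile refits
under-maximize often enough to truncate intervals measurably — this was
caught by a coverage simulation). When the profile never crosses before a
parameter bound, the bound is returned with a `boundary` flag — the
analogue of printed intervals with NA endpoints. Derived quantities
($r_{ph\text{-}a}$) are profiled by substitution: fixing
$r_{ph\text{-}a}$ determines $r_g$ given the current $h^2$, and the
correlation bound makes infeasible values drop out automatically.
Significance of a parameter can equivalently be judged by likelihood-ratio
tests (`ace_submodel_tests()` refits with $r_g = 0$,
$r_{ph\text{-}a} = 0$, $h^2 = 0$).

### The constrained correlation model

`fit_constrained_correlations()` estimates the saturated 4-variate normal
with the study's equality constraints: one within-twin cross-trait
correlation shared across zygosity and birth order (the phenotypic-overlap
gate of criterion 1), zygosity-specific cross-twin cross-trait and
cross-twin within-cognition correlations, and the liability cross-twin
correlations fixed at $h^2_d + c^2_d$ (MZ) and $\tfrac12 h^2_d + c^2_d$
(DZ/sibling) from the active profile.

### The four-criterion decision rule

A measure is validated as an endophenotype for a phenotype when all of:
(1) significant within-twin cross-trait correlation — failure excludes the
measure from the genetic stage entirely; (2) significant $h^2$ whose point
estimate exceeds 0.10; (3) significant $r_g$; (4) significant
$r_{ph\text{-}a}$. "Significant" is operationalized as the 95% profile CI
excluding zero. The 10% rule is applied to the *point* estimate together
with significance (the published footnotes read "statistically
non-significant and/or < 10%", which is compatible with either reading;
this one reports both sub-conditions so the other is recoverable). Report
tables round half away from zero to 2 decimals; full precision is kept
internally.

## The synthetic-data generator

`simulate_population()` draws the model exactly: correlated A/C/E factor
pairs per twin pair, cognition as intercept + covariate effects + scaled
latents, affection as the thresholded liability. Declared defaults — an
IQ-like scale (mean 100, SD 15, $h^2 = 0.70$, $c^2 = 0.10$,
$r_g = -0.30$, $r_e = -0.05$), age uniform on 16–65 (twins share age;
siblings differ by N(0, 3.6) years), sex Bernoulli(½) (shared for MZ),
education N(13, 2.5) truncated to [6, 22], three centres (0.45/0.35/0.20)
with mean shifts (0, −2, +2), age slope −0.15 and education slope +1.2
points/year, sex effect +1.5 — are realistic for a multi-centre adult
cognition cohort; the true covariate–cognition effect sizes behind the
published analysis are unpublished, so these are declared, not calibrated.

`ascertain_study_sample()` implements stratified pair selection: exact
numbers of concordant-affected, discordant and screened control pairs, the
frame a clinical-register twin study recruits under (not single-proband
sequential sampling; the scheme name is recorded in the output metadata).
`cohort_composition()` reproduces the study-like complete-pair structure —
64 concordant, 129 discordant, 311 control pairs (1008 individuals),
derived from the cohort's printed participant counts — scalable for fast
tests. The enrichment ratio matters for the ascertainment-bias
demonstration: at this composition a naive fit that frees $h^2_d$ inflates
it to ≈0.89–0.90 against the true 0.84, while weaker concordant enrichment
can leave the naive fit near truth.

What the generator does **not** emulate: non-psychotic comorbidity,
IQ-floor exclusion dynamics, item-level task structure, measurement
non-invariance across centres (centre shifts the mean only), age-dependent
genetic effects, or assortative mating. A green recovery test therefore
establishes internal consistency — the estimator recovers the model that
generated the data, under the study's sampling frame — not robustness to
violations of the ACE liability model itself.

## What the tests establish

- Decomposition identities: $r_{ph\text{-}a} = r_g\sqrt{h^2_x h^2_d}$ and
  $100 r_g^2$ reproduce published summary values from their printed inputs
  (2-dp inputs propagate up to ±0.01 in three rows; exact elsewhere).
- Oracle equivalence: the pair likelihood matches brute-force quadrature
  to $10^{-6}$ on 100 randomized pairs; thresholds invert a numerically
  integrated normal CDF to $10^{-10}$.
- Calibration (scaled down, declared): over 50 replicates at 400 pairs per
  zygosity class, mean $\hat h^2$ and $\hat r_g$ are within ±0.05 of truth
  and the 95% profile CI for $h^2$ covers at a rate in [0.90, 0.99].
  Coverage is nominally sample-size free, which is why replicates may be
  smaller than the full-size single run (2000 pairs/zygosity) that checks
  point accuracy.
- Ascertainment premise: on 30 study-composition replicates the
  fixed-parameter analysis keeps $|\mathrm{bias}(\hat r_g)| < 0.05$ while
  the naive free-$h^2_d$ fit shows directional inflation.

## Numerical choices

- Probabilities are floored at $10^{-320}$ before logging; non-PSD
  covariance candidates return an invalid-point signal (objective $10^{10}$)
  rather than crashing the optimizer.
- Profile refits run at `rel.tol = 1e-7` (endpoints are only needed to
  ~$10^{-3}$); main fits use `nlminb` defaults.
- $e^2$ is floored at $10^{-3}$: E includes measurement error, so exactly
  zero unique variance is outside any realistic model and would make the
  likelihood degenerate.
- Report rounding is half-away-from-zero, matching the apparent convention
  of the published tables.

## Known limitations

- Two traits only (one cognitive measure at a time against one phenotype);
  no ADE/dominance models; no G×E moderation; no covariate effects on the
  liability threshold.
- Profile CIs assume a locally quadratic-ish profile; near-flat profiles
  at bounds are reported as boundary-flagged endpoints, not finite limits.
- The correlation-model CI method (profile likelihood) is a declared
  choice; the original analysis does not state its interval algorithm.
- With prevalences below 1%, population samples carry little information
  about $r_g$; study-style ascertained samples (many affected pairs) are
  the informative design, which is exactly why the fixed-parameter
  correction matters.
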