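---
title: "Measurement-invariance testing and growth modelling for early repetitive behaviors"
author: "rrbmnlfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-invariance testing and growth modelling for early repetitive behaviors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbmnlfa)
```

## The problem

Parent-report questionnaires of restricted and repetitive behaviors
(RRBs) in infants and toddlers are used both to characterize normative
development and to screen for emerging neurodevelopmental conditions.
Before modelling change in such a questionnaire across the second and
third year of life, one has to ask whether the instrument measures the
same construct at 9 months as at 36 months. If an item such as
"mouths, bites, licks, or sucks objects" relates differently to the
underlying construct in young infants than in three-year-olds, raw
scores confound real developmental change with measurement drift.

`rrbmnlfa` implements the full analysis chain for this question on a
34-item, 0--4 frequency-scaled instrument with four validated
subscales (repetitive motor: 9 items; ritual/routine: 10; restricted
interests: 8; self-directed: 7):

1. preprocessing (exclusion filters, per-item median-split
   binarization, subscale views),
2. a configural structure check in two age bins,
3. moderated nonlinear factor analysis (MNLFA) with an automated
   invariance-testing workflow producing DIF-adjusted factor scores,
4. mixed-effects growth-curve analysis of those scores, and
5. a synthetic accelerated-longitudinal data generator with known
   ground truth against which every stage is testable.

## The measurement model

For binary (median-split) item $y_{ij}$ of person-visit $i$, with
covariate vector $x_i$ (centered age in months, sex, cohort, and the
age-by-cohort product) and latent factor $\eta_i$:

$$
P(y_{ij} = 1 \mid \eta_i, x_i)
  = \mathrm{logit}^{-1}\!\big(\nu_j(x_i) + \lambda_j(x_i)\,\eta_i\big),
$$

with linearly moderated intercepts and loadings

$$
\nu_j(x) = \nu_{0j} + \kappa_j^\top x, \qquad
\lambda_j(x) = \lambda_{0j} + \delta_j^\top x,
$$

and a moderated latent distribution

$$
\eta \mid x \sim N\!\big(\alpha(x), \psi(x)\big), \qquad
\alpha(x) = \gamma^\top x, \qquad \psi(x) = \exp(\omega^\top x).
$$

Nonzero $\gamma$ or $\omega$ is *impact* (true covariate differences in
the construct); nonzero $\kappa_j$ or $\delta_j$ is *differential item
functioning* (measurement bias in item $j$). The model is identified by
fixing $\alpha(0) = 0$ and $\psi(0) = 1$ at the covariate reference
(18-month-old male in the first cohort), which leaves every loading
free and hence every loading's moderation estimable.

Assumptions worth stating plainly: a logit link (the analogous probit
parameterization would rescale all coefficients by roughly 1.7);
local independence of items given $\eta$; linear moderation of
item parameters and log-linear moderation of the variance; and missing
item responses ignorable given the model (they are simply dropped from
the likelihood product — no imputation).

### Estimation

The marginal likelihood integrates $\eta$ out by fixed Gauss–Hermite
quadrature (21 nodes by default, configurable; nodes/weights normalized
for a standard-normal expectation and shifted/scaled per row by
$\alpha(x), \sqrt{\psi(x)}$). The optimizer is BFGS with the analytic
score; the score and likelihood are computed in compiled code because
the invariance workflow refits the model hundreds of times in
simulation studies. Standard errors come from the inverse observed
information, obtained as the central-difference Jacobian of the
analytic gradient. Convergence requires a relative log-likelihood
change below `tol` (default `1e-8`) and a small scaled gradient norm;
non-convergence is flagged on the returned object, not thrown.

Numerical choices: starting values are $\nu_{0j} =
\mathrm{logit}(\text{endorsement rate})$, $\lambda_{0j} = 1$, all
moderation at 0; items endorsed by everyone or no one are reported and
frozen at their starting values (quasi-separation); per-node Bernoulli
products are accumulated directly with a log-space fallback for rows
that underflow; and coefficients on centered age are given an optimizer
scale of 0.1 (months are the reporting unit — a mean-impact coefficient
of $-0.107$ means the latent mean falls by 0.107 reference-SD units per
month — but age spans roughly $[-10, +19]$ centered months, so age
coefficients live on a scale about ten times smaller than the
baselines; `parscale` supplies exactly the conditioning that dividing
age by 10 internally would).

Expected-a-posteriori (EAP) scores are the posterior mean and SD of
$\eta$ under the fitted parameters, by the same quadrature. A row with
no observed items scores at its prior $\alpha(x)$ with SD
$\sqrt{\psi(x)}$ — with moderated parameters this is informative, which
is precisely the point of scoring under the final model.

## The invariance workflow

`finalize_and_score()` automates the five-stage cascade on a
calibration sample of one visit per participant (so that measurement
parameters are estimated free of within-person dependence):

1. **Calibration sampling** (`draw_calibration_sample()`): greedy
   age-decile matching — participants are visited in seeded random
   order and each contributes the visit falling in the currently most
   under-filled decile of the full-sample age distribution. This
   operationalizes pseudo-random selection with a matched age
   distribution; any scheme with that property would do.
2. **Impact model**: all four covariates on the factor mean, age only
   on the log variance (a conventional restriction — variance
   moderation by several covariates is poorly identified at these
   sample sizes), no DIF. Effects with two-sided Wald $p < 0.1$ are
   retained.
3. **Item-wise DIF scan**: for each item in turn, its intercept and
   loading DIF coefficients for all candidate covariates are freed
   (other items' DIF fixed at 0) in the presence of the retained
   impact effects. A scan needs at least 3 items; an item whose scan
   fit fails to converge is skipped and marked untested.
4. **Trim and simultaneous refit**: every impact and DIF effect with
   stage $p < 0.05$ enters one joint model; fresh Wald $p$ per effect.
5. **Benjamini–Hochberg step-up** at $\alpha = 0.05$ over all
   moderation effects of the trim model, pooled within the subscale
   (baseline $\nu_0, \lambda_0$ are never part of the family — they
   are not hypotheses under test). Survivors form the final model,
   fitted on the calibration rows; EAP scores are then computed for
   every row of the longitudinal table with parameters fixed.

The pipeline is deterministic given the data and the calibration seed.
`stability_check()` runs it twice under different calibration seeds and
correlates the two score sets; `score_vs_raw_mean()` correlates EAP
scores with raw subscale means.

Procedural choices that published descriptions of this workflow
typically leave open, resolved here:
BH is applied within subscale, not pooled across subscales; retention
tests are two-sided; medians for binarization are computed after all
exclusions, over all retained person-visits (the instrument is
binarized once for the pooled sample, not per age bin).

## Configural structure check

`configural_check()` splits the data at 17 months, keeps one seeded
random row per participant per bin, and fits an unmoderated two-factor
binary model (2-D tensor-product quadrature, 15 nodes per dimension;
the latent correlation is optimized on the `atanh` scale with the SE
delta-method-mapped back). The ritual/routine and restricted-interest
factors are collapsed into a single higher-order factor when the
estimated correlation exceeds 0.75 in both bins — a threshold chosen
strictly below the correlation estimates (0.872 and 0.777) that
motivate the merge under the default generating truth. Full categorical-CFA fit indices (RMSEA,
CFI) are deliberately out of scope: only the inter-factor correlation
feeds a modelling decision here, so only it is computed. Residual
covariances among merged-factor indicators are not modelled; with the
merge decision driven by the correlation alone this is a declared
simplification.

## Growth models

Factor scores are analysed with linear mixed models fit by **maximum
likelihood** (not REML) via `lme4`, because the taxonomy compares
fixed-effect structures by likelihood-ratio tests and small-sample AIC,
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$. The taxonomy
(`taxonomy_search()`) fits: random intercept; + fixed linear age;
+ random linear slope (tested on 2 df — slope variance plus
intercept–slope covariance — ignoring the boundary conservatism of
that test, to match the conventional df accounting of this workflow); + fixed quadratic
age. The quadratic is always examined on top of the linear model, and
marginality keeps the linear term under a retained quadratic: a flat
average trend can coexist with real curvature, and gating the
quadratic on a significant linear term would make that pattern
undiscoverable. Sex and cohort main effects and their age interactions
are then tested by LRT ($\alpha = 0.05$, with a lower-AICc
requirement) and non-significant covariate terms are pruned backward.

`effect_in_within_person_sd()` expresses the fixed-effect change over
an age span in units of the residual (within-person) SD.
`variance_explained()` is the squared Pearson correlation between
conditional predictions (fixed plus predicted random effects) and
observations — one of several defensible pseudo-$R^2$ definitions, and
the choice is recorded here prominently because alternatives
(marginal/conditional variance decompositions) can differ
systematically.

## The synthetic generator

`generate_cohort()` emulates the accelerated longitudinal design of
the motivating study design: two cohorts of 110 and 70 participants; visit
counts from rounded normals with means 3.85 and 2.6 (clamped to 1–7
and 1–3); entry ages normal with means 11.0 and 13.8 months (SDs 3.8,
3.2); inter-visit gaps around 3.2 months (SD 1, minimum 1.5 — values
chosen once as realistic for a monthly-to-quarterly questionnaire
protocol; a gap distribution is not part of the published design summary); visits capped at
36.5 months; about half female per cohort.

Each subscale's latent trajectory is
$\eta_{it} = \beta_0 + \beta_1 a_{it} + \beta_2 a_{it}^2 + b_{0i} +
b_{1i} a_{it} + e_{it}$ with $a$ centered age, person-level random
intercepts/slopes (SDs 1 and 0.03) and a visit-level residual
(SD 1 — a free knob: a within-person residual SD on the factor-score
scale is not a published design quantity). Items are then emitted from the
measurement model with the published final-model moderation
estimates for this instrument as generating truth (`default_true_params()`): repetitive motor — mean
impact $-0.107$/month, log-variance impact $0.068$, mouthing loading
DIF $-0.147$; self-directed — mean impact $-0.054$; higher-order —
log-variance impact $0.043$ and six loading-DIF effects (arranging
$0.214$, placement $0.152$, restricted media $0.109$, preoccupation
with parts $-0.303$, visual inspection $-0.145$, fascination with
movement $-0.261$). Baseline intercepts are spread over
$[-1.4, -0.1]$ logits (endorsement roughly 0.20–0.48 at the
reference) with unit baseline loadings; these baselines are package
defaults, not published values.

Two generating modes matter and should not be conflated. In **cohort
mode** the trajectory's fixed age slope *is* the age impact, so the
structural $\gamma$ age coefficient is not applied again (sex, cohort
and age-by-cohort shifts are), and variance moderation is not applied
— the person-level random effects already make the marginal latent
variance age-dependent. In **cross-sectional mode**
(`simulate_calibration()`, used for parameter-recovery simulations)
independent respondents are drawn directly from
$\eta \sim N(\alpha(x), \psi(x))$, so the identification constraint
$\psi(0) = 1$ holds exactly and recovery of the printed coefficients
is a well-posed check.

`emit_ordinal()` maps the binary emission to the 0–4 frequency scale
through per-item level probabilities arranged so that the empirical
median split returns the binary data; it exists to exercise the
binarization path, not to model ordinal responses.

What the generator does *not* emulate — and hence what passing tests
do not establish about real data: informative missingness,
residual longitudinal dependence beyond person-level random effects
(items are conditionally independent given $\eta$), rater effects,
floor/ceiling artifacts of the original frequency scale, and any
non-logit true response process.

## Problem sizes used by the test-suite simulations

Chosen to give stable operating characteristics at desk scale:
parameter recovery uses 10 replicates of 1000 calibration respondents
per subscale model; the null false-discovery check uses 200 replicates
of a 9-item, 500-respondent design through the full scan–trim–BH
cascade; stability and scoring checks use the default 180-participant
synthetic cohort; growth recovery uses 20 replicates of the two-cohort
visit design. Oracle-equivalence checks compare 101-node quadrature
against dense-trapezoid integration (grid of 6001 points over
$[-12, 12]$) on 5–10-item fixtures.

## Known limitations

- Binary measurement only; the ordinal 0–4 metric is supported solely
  as input to the median split.
- One factor per subscale in the moderated model; the two-factor code
  exists only for the configural check (no moderation there).
- Wald tests drive retention decisions, as in the automated pipelines
  this mirrors; profile-likelihood or score tests would be more robust
  near boundaries.
- MNLFA analyses of this kind have historically been run through
  Mplus-based pipelines whose exact parameterization (link function,
  covariate coding, sign conventions) is rarely printed; logit and
  the codings documented in `moderator_design()` are this package's
  declared conventions, so individual coefficient signs involving
  sex/cohort may differ from other implementations even when
  magnitudes agree.
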