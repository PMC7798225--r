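# rrbmnlfa

Measurement-invariance testing and growth-curve modelling for early
restricted and repetitive behaviors (RRBs), as measured by a 34-item
parent-report questionnaire of 8–36-month-olds with four validated
subscales (repetitive motor, ritual/routine, restricted interests,
self-directed; the latter two middle scales merge into a single
"higher-order" factor when their latent correlation warrants it).

The package is for developmental and clinical researchers who want to
model change in a binary-item questionnaire over an age range in which
the instrument itself may drift: before interpreting a decline in
"mouths, bites, licks, or sucks objects" as a decline in repetitive
motor behavior, one has to separate true change in the construct
(*impact*) from age-dependent item bias (*differential item
functioning*, DIF).

## The model

For item *j* of person-visit *i* with covariates *x* (age centered at
18 months, sex, cohort, age×cohort) and latent factor η:

P(y<sub>ij</sub> = 1 | η, x) = logit⁻¹( ν<sub>j</sub>(x) + λ<sub>j</sub>(x)·η ),
  ν<sub>j</sub>(x) = ν<sub>0j</sub> + κ<sub>j</sub>ᵀx,
  λ<sub>j</sub>(x) = λ<sub>0j</sub> + δ<sub>j</sub>ᵀx,

η | x ~ N( α(x), ψ(x) ),  α(x) = γᵀx,  ψ(x) = exp(ωᵀx),  α(0) = 0, ψ(0) = 1.

This is a moderated nonlinear factor analysis (MNLFA) for binary
items, estimated by marginal maximum likelihood with Gauss–Hermite
quadrature (analytic gradients in compiled code). On top of the
estimator sits the automated invariance workflow: a one-visit-per-
participant calibration sample; an impact model (p < 0.1 retention);
an item-wise DIF scan; trimming at p < 0.05 with a simultaneous
refit; Benjamini–Hochberg correction across all moderation effects;
and expected-a-posteriori (EAP) factor scoring of the full
longitudinal sample under the final model. Factor scores then feed
maximum-likelihood linear mixed growth models compared by
likelihood-ratio tests and AICc.

A synthetic accelerated-longitudinal generator (two cohorts, 180
participants, 1–7 visits each, known impact/DIF/trajectory truth)
makes every stage testable without access to any external dataset.

## Worked example

```r
library(rrbmnlfa)

gen   <- generate_cohort(generator_config(), seed = 2024)
tab   <- subscale_view(gen$table, "repetitive_motor")   # 601 rows, 180 participants
calib <- draw_calibration_sample(tab, rng_seed = 1)
res   <- finalize_and_score(tab, calib, moderator_design())

res$trace[res$trace$stage == "final", c("block","item","covariate","estimate","se","p")]
#>    block        item covariate estimate     se        p
#>  loading rm_mouthing     age_c  -0.1789 0.0546 0.001054
#>  loading       rm_09     age_c  -0.1196 0.0533 0.024988
#>     mean                 age_c  -0.0688 0.0187 0.000242

score_vs_raw_mean(res$scores, tab)                      # 0.97
cor(res$scores$eta, gen$truth$eta$eta_repetitive_motor) # 0.884
```

The pipeline recovers the generated age DIF on the mouthing item
(truth −0.147, estimated −0.179 ± 0.055) and a declining factor mean
with age; `rm_09` is a false positive that survived this replicate's
BH step. EAP scores track the generating latent values (r = 0.88) and
the raw subscale means (r = 0.97).

```r
gd <- growth_data(res$scores, tab)
tx <- taxonomy_search(gd)
tx$form                       # "linear"
tx$best$fixed
#>         term estimate      se      z        p
#>  (Intercept)   0.1855 0.06080   3.05 2.28e-03
#>        age_c  -0.0724 0.00581 -12.48 1.01e-35
#>       cohort  -0.3023 0.09985  -3.03 2.47e-03
variance_explained(tx$best)                  # 0.638
effect_in_within_person_sd(tx$best, 29)      # 3.29
```

The taxonomy selects the generating linear form: repetitive-motor
scores decline by about 0.07 units/month, a ~3.3 within-person-SD
drop across the 8–37-month span, with conditional predictions
explaining ~64% of score variance. (The cohort term is a sampling
artifact of this replicate — the generator contains no cohort effect —
and illustrates why covariate retention is itself studied by
simulation in the test suite.)

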