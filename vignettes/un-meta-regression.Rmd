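---
title: "Weighted meta-regression of urinary nitrogen on milk urea nitrogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted meta-regression of urinary nitrogen on milk urea nitrogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(munpredict)
```

## The problem

Urinary nitrogen excretion (UN, g/d) of lactating dairy cows drives
nitrate leaching, nitrous oxide and ammonia emissions, but measuring it
requires total urine collection — laborious, invasive, and impossible at
commercial scale. Milk urea nitrogen (MUN, mg/dL) is measured at every
milking and, because urea equilibrates across blood, milk and urine, is a
practical proxy. `munpredict` implements a meta-regression workflow over
*treatment means* extracted from published feeding experiments: each row
of the data frame is one experimental group's mean UN together with its
standard error (SEm) and covariates (MUN, body weight BW, dry matter
intake DMI, dietary crude protein CP), grouped by source study and
stratified into two diet types — total mixed ration (TMR) confinement
diets and fresh-forage/pasture diets.

The workflow has four stages:

1. **Bias assessment of published equations.** For a candidate equation,
   residuals (observed − predicted UN) are regressed on the
   grand-mean-centered predictions with a diet-type interaction, a random
   study intercept, and SEm-derived weights. The per-diet intercept is
   the *mean prediction bias* and the per-diet slope the *linear
   prediction bias*; RMSEP and the relative prediction error
   (RPE = 100·RMSEP/mean observed) summarize precision.
2. **Study-level train/test split**, stratified by diet type, so the
   evaluation set shares no study with the development set.
3. **Model development.** Four candidate families — UN/BW ~ MUN,
   UN ~ MUN+CP+DMI, UN ~ MUN+CP+DMI+BW, UN/BW ~ MUN+CP+DMI, each with
   diet-type interactions — are fitted by weighted REML and backward
   elimination removes non-significant terms.
4. **Agreement on the test set**: Pearson r, Lin's concordance
   correlation (CCC) with its location/scale decomposition, RMSEP and
   RPE.

## The mixed model and its weights

Every regression in the workflow is the same model: for treatment mean
$i$ in study $s$,

$$y_{is} = \mathbf{x}_{is}^\top \beta + u_s + \varepsilon_{is}, \qquad
  u_s \sim N(0, \sigma^2_u), \qquad
  \varepsilon_{is} \sim N(0, \sigma^2_e / w_{is}),$$

with one random intercept per study and per-record weights

$$w_{is} = \frac{1/\mathrm{SEm}_{is}^2}{\operatorname{mean}_j(1/\mathrm{SEm}_j^2)}.$$

Normalizing the inverse squared SEm by its mean centers the weights
around 1, which keeps the variance components on the scale of the
response — so the residual SD and the study/residual variance partition
are directly interpretable in g/d (or g/d per kg BW). If no record has
an SEm the weights are all 1; a mixture of present and absent SEm is an
error rather than a silent partial weighting.

`fit_wlmm()` estimates this model by REML, profiling the variance ratio
$\lambda = \sigma^2_u / \sigma^2_e$. For fixed $\lambda$ the marginal
covariance is block diagonal by study and each block is a rank-one
update of a diagonal, so generalized least squares and the profiled
criterion are closed-form and $O(n)$ per evaluation; $\lambda$ is then
found by a deterministic bounded search (log-spaced bracketing on
$[10^{-8}, 10^6]$, golden-section refinement to $10^{-10}$, always
compared against the $\lambda = 0$ boundary). There is no randomness
anywhere in the fit. With `fix_lambda = 0` the model collapses to
weighted least squares, which the test suite exploits as a closed-form
oracle; the suite also cross-checks coefficients, standard errors,
variance components and the REML criterion against `lme4::lmer` on
simulated data.

Fixed-effect p-values are two-sided t tests on the between-within
denominator degrees of freedom $n - \mathrm{rank}(X) - q + 1$ (with $q$
studies). No single convention for mixed-model denominator df is
canonical; this one is simple, deterministic, and in simulation holds
the type-I error of a null covariate near the nominal 5% (the suite
checks the rejection rate over 1000 refits stays inside 3–7%). Exact
agreement with a Satterthwaite-type approximation is not claimed, which
is why downstream decisions are phrased in terms of significance at a
threshold rather than exact p-values.

## Bias decomposition conventions

Three choices here are genuinely open and are fixed as follows:

* **Grand-mean centering.** Predictions are centered at the mean over
  the *pooled* evaluation set, not per diet. Interaction p-values (does
  the mean or linear bias differ between diet types?) depend on this
  choice; pooling keeps the per-diet intercepts comparable at the same
  reference point.
* **Sign convention.** The report stores the signed mean residual
  (observed − predicted): negative means the equation over-predicts.
  `describe_mean_bias()` translates into "over/under predicted by …"
  prose, so the stored numbers are unambiguous even though spoken
  language often quotes magnitudes.
* **RMSEP/RPE on raw residuals.** RMSEP and RPE are computed per diet
  subset from unweighted residuals, alongside (not inside) the weighted
  regression — they describe prediction error in the data as observed.

## Backward elimination

Starting from a family's full model, the single removable term with the
largest p-value above `alpha` (default 0.05) is dropped and the model is
refitted, until every removable term is significant. Ties break on the
term name, so the procedure is deterministic and invariant to record
order. Marginality is enforced for covariates: a covariate main effect
cannot leave while a covariate-by-diet interaction survives. The diet
main effect is treated as intercept-like — it encodes per-diet
intercepts and may be removed while interactions survive, which is what
allows the zero-intercept, diet-specific-slope form (per-diet slopes
with no per-diet intercepts) that the MUN-only per-BW family can reach.
When neither an intercept nor a diet main effect remains, R's dummy
coding expands a covariate-by-diet interaction to one slope per diet and
the covariate main effect is absorbed into it; the implementation
handles this re-coding explicitly rather than tripping over the
aliasing. A `block` mode that removes all non-significant removable
terms per refit is also provided, since published descriptions of such
procedures rarely state whether elimination was one-at-a-time or joint.

`finalize_equation()` converts the surviving fit into a prediction-ready
coefficient set. Per-BW responses are re-expressed on the g/d scale by
multiplying through by BW — the coefficients are unchanged, only the
prediction is scaled. Standard errors of diet-combined coefficients are
propagated from the full coefficient covariance.

## Agreement statistics

For observed $o$ and predicted $p$, with population moments
($n$ denominator): $u = (\bar p - \bar o)/\sqrt{s_p s_o}$ (location
shift), $v = s_p/s_o$ (scale shift), $C_b = 2/(v + 1/v + u^2)$, and
$\mathrm{CCC} = r \cdot C_b$. Population moments are the default because
they preserve the covariance-form identity
$\mathrm{CCC} = 2\,\mathrm{cov}(o,p) / (s_o^2 + s_p^2 + (\bar o - \bar
p)^2)$ exactly, which the test suite uses as a second, independent route
to the same number. The sample convention (n−1) is exposed as an option;
it changes only $u$, by the factor $\sqrt{(n-1)/n}$. Descriptive
summary tables use the sample SD, matching common summary-table
practice.

## The synthetic generator

No public accession exists for the literature-compiled data frame the
workflow was designed around, so the package ships a generator,
`simulate_study_table()`, that emulates its structure and is itself
first-class, tested code. Defaults are fixed once:

* **Design**: 38 TMR and 7 pasture studies, 2–5 treatment means each
  (≈150 means) — the training-set scale.
* **Covariate profiles** (per-diet mean/SD): TMR MUN 13.2/3.17 mg/dL,
  BW 647.5/64.74 kg, DMI 22.1/2.65 kg/d, CP 16.7/1.85%; pasture MUN
  18.5/2.46, BW 508.6/63.60, DMI 17.0/3.25, CP 19.5/3.40.
* **Two-level covariate structure**: each study draws a mean vector
  (70% of the covariance) and treatment means add within-study
  deviations (30%) — treatment means within a study share animals and
  diets, so most variation is between studies. The within-study
  correlations (BW–DMI +0.6, MUN–CP +0.5, others 0) are fixture
  conventions chosen for plausibility, not literature estimates.
* **Truth**: the per-BW MUN+CP equation with coefficients (−0.253,
  0.00932, 0.0260); variance components back-derived from that model's
  reported residual SD (0.019 on the UN/BW scale) and 82.9/17.1
  study/residual split, i.e. $\sigma^2_e = 0.019^2$,
  $\sigma^2_u = \sigma^2_e \cdot 82.9/17.1$.
* **SEm** ~ Gamma(shape 20, mean 10 g/d), giving the inverse-SEm²
  weights a coefficient of variation near 0.5, so the weighting is
  exercised non-trivially.
* **Truncation**: covariates are clamped to physiological bounds
  (MUN 2–40 mg/dL, BW 300–900 kg, DMI 5–35 kg/d, CP 8–30%), and the
  rare response draw at or below 5 g/d has its noise redrawn — UN is
  physically positive and the validator enforces that.

What the generator does *not* emulate: real between-study heterogeneity
in covariate ranges, publication-driven covariate–SEm correlation,
non-Gaussian residuals, breed or days-in-milk structure. Passing
recovery tests therefore show the *machinery* is correct under the
stated model — not that the model is correct for any particular real
data set.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to the
study's own scale: coefficient recovery uses 200 replicates of 45
studies/≈150 means (each coefficient covered by ±2 SE in ≥90% of
replicates; measured 92–97%), elimination-recovery checks use 20
replicates, and the covariate-profile convergence check uses 5000
studies because with 70% of covariate variance between studies the
study count, not the record count, drives moment convergence.
Degenerate inputs are handled explicitly: a table where every study has
one record confounds the study variance with the residual (reported as
var_study = 0 with a warning); a rank-deficient design fails naming the
aliased columns; perfect predictions short-circuit the bias regression
to an all-zero report rather than fitting a zero-variance response; and
negative predictions from affine equations at extreme covariates are
returned untruncated with a warning, because prediction equations of
this form are never clipped at source.

## A worked run

```{r, eval = FALSE}
sim <- simulate_study_table(sim_config(seed = 1))
res <- run_un_pipeline(table = sim$table, outdir = "un_reports", seed = 1)
res$validation$agreement
```

The pipeline writes `evaluate_published.json`, `developed_models.json`,
`validation.json`, a human-readable `summary.txt`, and a `manifest.json`
from which the artifacts are bit-identically regenerable.

## Known limitations

* Only a single random study intercept is supported — no random slopes,
  crossed effects, or ML (non-REML) estimation; the workflow needs none
  of them.
* Coefficient SEs of published equations are stored for reporting, not
  propagated into prediction intervals.
* No multiple-testing correction is applied across the
  residual-vs-covariate regression grid, by design.
* Denominator degrees of freedom are between-within, not Satterthwaite;
  p-values near a decision threshold should be read accordingly.
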