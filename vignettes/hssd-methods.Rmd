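---
title: "Hierarchical SSD modelling for nano- and microplastics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical SSD modelling for nano- and microplastics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hssd)
```

## The model

A species sensitivity distribution (SSD) treats the chronic effect
concentrations of different species as draws from a common distribution —
here log-normal, so log10 concentrations are normal. For nano- and
microplastic (NMP) particles a single SSD conflates particles and test
systems with very different potencies, so the SSD mean is modelled as a
function of the particle and test covariates:

$$\log_{10}(\mathrm{LOEC}_i) \sim \mathrm{Normal}(\mu_i, \sigma), \qquad
\mu_i = \alpha + \beta_{size} x_{size,i} + \beta_{media} x_{media,i} +
\beta_{polymer} x_{polymer,i} + r_{j(i)}, \qquad
r_j \sim \mathrm{Normal}(0, \sigma_{Ref}).$$

- $x_{size}$ is the log10 particle diameter in µm (midpoint of the
  reported range when only a range is given);
- $x_{media}$ codes the test medium (freshwater 0, marine 1);
- $x_{polymer}$ codes polystyrene and polystyrene–polyethyleneimine
  mixtures (PS, 1) against all other polymers (0); PS dominates the
  available chronic data, so finer polymer resolution is not estimable;
- $r_j$ is a random intercept for the reference (study) observation $i$
  belongs to, with spread $\sigma_{Ref}$. It absorbs study-specific
  influences the three predictors cannot express — particle pre-treatment
  (e.g. stabiliser removal), organism origin or developmental stage, water
  chemistry.

$\sigma$ is assumed common across covariate values: the covariates shift
the SSD, they do not reshape it. With the sparse chronic data available
this is a necessity, not a finding; a covariate-dependent $\sigma$ is a
natural extension once more data exist.

All $2^3 = 8$ subsets of the three fixed-effect predictors are candidate
models (`enumerate_models()`); the random intercept is part of every
candidate, since between-study heterogeneity is a property of the data
collection, not of any particular mean structure.

## Preprocessing

`prepare_hssd_data()` chains four steps, each available separately:

1. **Conversion to chronic LOECs** (`convert_to_chronic_loec()`). Reported
   LC50/EC50/NOEC/LOEC values are divided by an extrapolation factor
   resolved from the effect-concentration type and an acute/chronic
   duration class. The factor table is user-editable CSV constrained to
   [1, 30]; the table shipped in `inst/extdata/` is an illustrative
   default, and regulatory users should substitute the factor table of
   their framework. Durations of at least 7 days are classed chronic by
   default — a conventional cut-off for invertebrate/algal chronic tests —
   and the threshold is an argument. The applied factor is kept in an
   `extrapolation_factor` column for audit.
2. **Shape filter and medium recategorisation**
   (`filter_and_recategorize()`). Only spherical-particle tests are
   retained: fibre and irregular shapes are too sparse in compiled chronic
   NMP data to support a shape term, and mixing shapes would confound the
   size coefficient. Brackish tests do not fit the binary medium coding;
   they are reassigned to marine except for species in a configurable
   freshwater-override list (by default *Hyalella azteca*, an amphipod
   assayed at low salinity). Counts of dropped and reassigned records are
   reported.
3. **Geometric-mean aggregation** (`aggregate_geometric_mean()`).
   Replicate effect concentrations for one species under identical
   conditions (size, polymer category, medium) are collapsed to their
   geometric mean — the natural mean on the log scale the model works on.
   The grouping key deliberately includes the reference: every aggregated
   record must belong to exactly one study for the random effect to be
   well defined. Should the same species/condition combination occur in
   two studies, the records stay separate and a message reports the
   overlap; silently merging across studies would misattribute
   between-study variance to the residual.
4. **Encoding** (`encode_predictors()`). Builds `y`, the dummy columns and
   `ref_index` (consecutive integers by first appearance of the reference
   id). PS matching is case- and whitespace-insensitive over a
   configurable synonym list, because polymer naming in compiled datasets
   is inconsistent. Units are fixed at µg/L and µm at the I/O boundary; a
   `units` column declaring anything else is rejected rather than
   silently converted.

## Priors and sampling

The priors are noninformative: flat on $\alpha$ and each $\beta$, flat on
$\sigma > 0$ and $\sigma_{Ref} \ge 0$. To keep the posterior proper under
any backend these are implemented as wide proper uniforms — ±50 on
location parameters and (0, 50] on scales, in log10-µg/L units — wide
enough (fifty orders of magnitude of concentration) that they are never
active on real toxicity data; the bounds are exposed in
`sampler_config()`.

Under these priors every full conditional distribution is available in
closed form, so `fit_hssd()` uses a blocked Gibbs sampler:

- fixed effects jointly, $b \mid r, \sigma^2 \sim \mathrm{N}(\hat b,
  \sigma^2 (X'X)^{-1})$ with $\hat b$ the least-squares solution on the
  random-effect-adjusted response;
- each reference intercept from its precision-weighted normal conditional;
- $\sigma^2$ and $\sigma_{Ref}^2$ from inverse-gamma conditionals whose
  shapes, $(n-1)/2$ and $(J-1)/2$, include the Jacobian of the
  flat-on-standard-deviation prior;
- prior bounds enforced by rejection.

A centred parameterisation with conjugate blocked updates mixes well here
because the conditionals are exact — there is no step-size tuning and no
rejection in the interior of the support. The funnel pathologies that
affect gradient samplers on hierarchical models at small $J$ show up, if
at all, as slower mixing of $\sigma_{Ref}$, which the split-chain
$\widehat R$ check monitors. The sampler's results are cross-checked in
the test suite against an independent JAGS fit of the same model and, in
the $\sigma_{Ref} = 0$ limit, against ordinary least squares.

The default configuration retains 1,000 draws per chain from 3 chains
(20,000 burn-in, 10,000 iterations thinned by 10 — 3,000 draws total);
thinning at this rate is a draw-budget convention carried by the study
design this package follows rather than a statistical necessity.
Convergence is declared when the split-chain Gelman–Rubin statistic — each
chain halved, so within-chain drift also registers — is below 1.1 for
every parameter; `fit_hssd()` warns otherwise. Identical seed, data and
configuration give bit-identical draws. `sampler_config_fast()`
(3 × 2,000/2,000, no thinning) is the profile used for simulation studies
and tests, where datasets are small and mixing is fast.

## WAIC and model ranking

`waic()` computes the widely applicable information criterion from the
pointwise posterior log densities, reported on the deviance scale
$-2(\mathrm{lppd} - p_{WAIC})$ so that differences match the familiar
deviance magnitudes. The pointwise density is **conditional on the sampled
reference intercepts**: it scores predictions for new species within the
observed studies, matches the standard generated-quantities usage of the
tooling this workflow descends from, and needs no extra integration. The
alternative — marginalising the random effect, which scores predictions
for unseen studies using $\mathrm{sd} = \sqrt{\sigma^2 + \sigma_{Ref}^2}$
— is available as `waic(fit, marginal = TRUE)`; the two answer different
questions and are not interchangeable in a ranking.

`rank_models()` orders the eight candidates by ascending WAIC and reports
ΔWAIC to the minimum. No "competitive ΔWAIC" cut-off is hard-coded: there
is no theoretical criterion for one, so the table reports raw ΔWAIC and
leaves the judgement to the analyst. Exact ties (a measure-zero event with
real draws) go to the model with fewer predictors, then label order, and
the tie-break is recorded on the table.

## HC5 and SSD curves

For a scenario (particle size, medium, optionally polymer class), each
retained draw $s$ yields $\mu_s$ from the sampled coefficients and
$\mathrm{HC5}_s = 10^{\mu_s + z_{0.05}\sigma_s}$, with $z_{0.05}$ computed
from the inverse normal CDF at run time (never hard-coded to 4 digits, so
the round-trip identity `ssd_fraction_affected(HC5) = 0.05` holds to
machine precision). The protected fraction is a parameter (`hcp`), so HC1
or HC10 come at no extra cost.

By default the reference intercepts are **excluded** from $\mu_s$: the
HC5 then describes an idealised study free of reference-specific
unmodeled factors, which is the quantity of regulatory interest. With
`include_random_effects = TRUE` a single perturbation
$r^*_s \sim \mathrm{Normal}(0, \sigma_{Ref,s})$ is added per posterior
draw — one draw per draw, not one per reference, since the scenario
concerns one hypothetical new study — which leaves the median nearly
unchanged but widens the credible interval, quantifying how much
between-study heterogeneity inflates HC5 uncertainty.

Scenario sizes outside the fitted size range are flagged
(`extrapolated`): the linear size term is then pure extrapolation.
Percentiles everywhere (posterior summaries, HC5 intervals, SSD bands)
use linear interpolation between order statistics (R's default type 7),
matching common statistical software.

## The synthetic-data generator

`simulate_hssd_records()` draws data with exactly the generative structure
above: reference intercepts first, then per observation a log-uniform
size, Bernoulli medium and polymer, and a normal log10 LOEC. Defaults
place it in the regime the model targets — 15 references of 2
observations, intercept 3.20 log10 µg/L, size slope −0.21, marine offset
−0.95, PS offset −1.09, $\sigma = 0.72$, $\sigma_{Ref} = 0.92$, sizes
0.04–315 µm, 62% marine and 85% PS records — i.e. realistic effect sizes
and a realistically small, unbalanced dataset. Sizes are log-uniform so
that $x_{size}$ is well spread across its decades, mirroring the
heavy-tailed size distribution of compiled NMP data.

What the generator does *not* emulate: correlation between covariates
(real studies confound polymer with size and medium), non-normal residual
tails, intraspecies replicate structure beyond the aggregation no-op,
censored or range-reported concentrations, and reporting error in sizes.
Passing recovery tests therefore demonstrate that the estimator is
correct and calibrated *under the model's own assumptions* — they cannot
certify robustness to the ways real compilations violate them.

`recovery_experiment()` is the end-to-end harness: simulate, fit the
generating model, record posterior-median errors and 95%-interval
coverage per parameter.

## Numerical choices and degenerate inputs

- Log-sum-exp with a per-observation maximum guards the lppd computation.
- `p_waic` uses the sample variance over draws (denominator $S-1$).
- $\sigma_{Ref} = 0$ is supported as a *fixed* value
  (`sigma_ref_fixed = 0`), collapsing the model to a plain log-normal SSD
  regression; sampling $\sigma_{Ref}$ requires at least two references.
- Zero-row inputs: the preprocessing stages pass them through with a
  warning (an all-fibre input is a legitimate, if empty, result); the
  sampler refuses them.
- The log prior returns $-\infty$ outside the support, and at
  $\sigma_{Ref} = 0$ assigns the point mass to $r \equiv 0$.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
fixture fits use 4–10 references with a few hundred retained draws;
calibration experiments use 20 replicates at $J = 15$ with $n = 30$ and
$n = 195$ under the fast profile; the reference analysis in
`scripts/acceptance.R` uses the full default profile (3,000 retained
draws) on a 30-observation dataset, the scale of dataset this model is
designed for. The moment checks on the generator use $n \approx 10^4$.

## Known limitations

- LOEC-based SSDs are less conservative than NOEC-based ones; the HC5
  values are "likely safe-range" quantities, not PNECs. No assessment
  factors are applied.
- The size effect is a single log-linear term; size-dependent
  bioavailability or a ratio-to-body-size formulation are out of scope.
- The polymer contrast is PS vs non-PS only.
- WAIC is a relative predictive ranking, not a goodness-of-fit measure;
  a well-ranked model can still fit poorly in absolute terms.
- With a handful of non-PS records, $\alpha$ and $\beta_{polymer}$ are
  weakly identified and HC5 values for the non-PS baseline inherit that
  uncertainty.
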