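---
title: "Models and methods behind the symbiont comparative pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the symbiont comparative pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package estimates

`symbiocomp` implements the comparative analysis used to ask whether
heritable bacterial symbionts (such as *Wolbachia*) vary in the antiviral
protection they confer on their insect host, and whether that protection is
genetically correlated with other symbiont phenotypes — above all bacterial
density. The pipeline has four statistical stages:

1. **Survival**: per-vial protection traits from mixed-effect proportional
   hazards models fitted to daily fly mortality counts.
2. **qPCR**: relative symbiont density, viral titer and host gene expression
   from cycle thresholds, with amplification-efficiency (Pfaffl) correction
   and plate normalisation.
3. **Comparative model**: a Bayesian multi-response mixed model over
   strain-level traits whose between-strain covariance is split into a
   phylogenetic component (structured by shared ancestry) and a
   strain-specific component; genetic correlations `r_g` with 95% HPD
   intervals are read off the posterior covariance draws.
4. **Univariate companions**: one-way ANOVA on ln-transformed quantities,
   Dunnett many-to-one and Tukey all-pairs comparisons, and a backward-
   selected polynomial regression for titer time-courses.

A synthetic-data module generates every input — coalescent trees, strain
effects with known covariance, survival tables with vial frailty, qPCR
plates with known efficiencies — so each stage can be validated against
ground truth without any external data.

## The survival model and the protection trait

Each fly contributes one record (strain, treatment, vial, day of death or
censoring). Deaths recorded on day 1 are attributed to the inoculation
injury and removed (`exclude_day1_deaths()`); survivors at the end of
follow-up (default 25 days) are censored. The hazard of fly $i$ in vial $v$
of strain $s$ is

$$\lambda_i(t) = \lambda_0(t)\, e^{\beta_s + b_v},
  \qquad b_v \sim N(0, \sigma^2_v),$$

with the symbiont-free line as the reference ($\beta_{\text{ref}} = 0$).
Daily censuses produce heavy ties, handled by the Efron approximation
(Breslow available via `ties =`). Estimation maximises the penalized
partial likelihood over $(\beta, b)$ by Newton–Raphson with step halving;
the frailty variance is optimised in an outer one-dimensional search on the
Laplace-approximate integrated likelihood

$$\ell(\sigma^2_v) = \widehat{PPL}
 - \tfrac{q}{2}\log\sigma^2_v
 - \tfrac12 \log\det\!\big(H_{bb} + I/\sigma^2_v\big),$$

with tolerance $10^{-8}$ on the log variance. Fixed-effect terms are tested
by likelihood-ratio tests between nested fits; per-strain Wald $z$ tests
against the control are reported without multiplicity correction (they
correspond to per-strain significance stars, not a family-wise claim).

The protection trait of vial $v$ of strain $s$ is
$-(\beta_s + b_v)$ — the negative log hazard ratio versus the symbiont-free
flies; larger is more protective. Whether per-vial hazard ratios should use
predicted vial random effects or vials fitted as fixed effects is not
decidable from the field's published descriptions; both are implemented
(`vial_as = "random"` default, `"fixed"` alternative) and agree closely on
simulated data (rank correlation > 0.85 in the test suite). A variance of
exactly zero returned by the outer optimisation means the penalized fit
collapsed to the ordinary fixed-effects Cox model; no p-value is ever
attached to the frailty variance itself (boundary problem).

## qPCR quantification

For a target gene with per-cycle amplification efficiency $E_t$ measured
against a reference gene with efficiency $E_r$, the relative quantity is
the Pfaffl ratio $E_r^{Ct_r} / E_t^{Ct_t}$, which reduces to the textbook
$2^{\Delta Ct}$ when both efficiencies are 2. Efficiencies are estimated
from ten-fold dilution series as $E = 10^{-1/\text{slope}}$ (slope of Ct on
log10 input; −3.32 cycles per decade is perfect doubling). Technical
replicates are averaged on the Ct scale — the dominant convention; the
difference from quantity-scale averaging is second order in the replicate
spread — and replicate pairs more than 1 cycle apart are flagged. Cts of
genes with $E \neq 2$ are first rescaled to the doubling scale as
$Ct' = Ct \log_2 E$ (so $2^{-Ct'} = E^{-Ct}$); a reference gene validated
at 100% efficiency is left untouched. Host-gene expression values are
z-scored within each 96-well plate (`plate_normalize()`), which removes
any per-plate additive shift or positive rescaling; density and titers are
not plate-normalised. Strains with unstable symbiont transmission can be
excluded from trait assembly by a configuration list. All downstream
analysis uses $\ln$ relative quantities, which are finite by construction
whenever the input Cts are.

## The multi-response (phylogenetic) mixed model

The comparative model for replicate $i$ of trait $t$ in strain $w$ is

$$y_{twi} = \beta_t + u_{s:tw} + u_{p:tw} + e_{twi},$$

with trait intercepts $\beta_t$ (normal prior, mean 0, variance $10^{10}$),
strain effects $u_s \sim N(0, V_s \otimes I)$, optional phylogenetic
effects $u_p \sim N(0, V_p \otimes A)$, and residuals with a separate
variance per trait (traits are measured on different biological replicates,
so residuals are independent across traits; missing strain × trait cells
simply contribute no rows). $A$ holds pairwise shared-ancestry proportions:
the depth of the most recent common ancestor of two strains divided by the
root-to-tip depth of the (ultrametric, tolerance $10^{-6}$ relative tip
spread) tree. Normalising to unit diagonal makes $A$ scale-free; the
magnitude of phylogenetic variance lives entirely in $V_p$. Under Brownian
trait evolution this is exactly the expected covariance structure of
strain effects. Tips with zero divergence give a singular (PSD, not PD)
$A$; the fitter then adds a $10^{-8}$ diagonal jitter and says so.

The genetic correlation between traits $t_1, t_2$ within a component is
$r_g = \sigma_{t_1 t_2} / \sqrt{\sigma^2_{t_1}\sigma^2_{t_2}}$, computed
per posterior draw and summarised by the mean and the 95% highest posterior
density interval (shortest sorted window containing $\lceil 0.95 n\rceil$
draws; width ties resolved toward the lower start).

### The Gibbs sampler

`fit_multiresponse()` runs a blocked Gibbs sampler (RcppArmadillo):

* all location effects $(\beta, u_s, u_p)$ jointly from their Gaussian full
  conditional (mixed-model equations, one Cholesky per iteration);
* $V_s$ from an inverse-Wishart full conditional on the strain-effect outer
  product, $V_p$ likewise with the $A^{-1}$-weighted quadratic form;
* residual variances from scaled inverse-chi-square conditionals
  (prior $\nu = 0.002$, scale 1).

Three prior families are available for the covariance matrices:

* **`"px"` (default, parameter expansion)** — the component is written
  $u = \Lambda \eta$ with a full working loadings matrix $\Lambda$
  (entries $N(0,1)$, "half-Cauchy-like with scale 1") around an inner
  inverse-Wishart matrix $\Psi \sim IW(d+1, I)$, and $V = \Lambda \Psi
  \Lambda'$. Two deliberate choices here: (i) $d+1$ degrees of freedom make
  the implied marginal prior on every correlation uniform on $(-1,1)$ — with
  $d$ degrees the marginal is $(1-r^2)^{-1/2}$, which piles mass at $\pm 1$
  and visibly degrades the frequentist coverage of the $r_g$ HPD when the
  true correlation is 0; (ii) the expansion uses a full matrix rather than
  per-trait scalars because the rows of $\Lambda$ are updated by
  data-driven regressions, which is what lets the cross-trait structure of
  a weakly identified component (for instance $V_p$ on a root-heavy
  coalescent tree) mix in thousands rather than millions of iterations.
* **`"iw"`** — inverse-Wishart, $d+1$ degrees of freedom, scale $0.01 I$.
* **`"flat"`** — improper flat prior; the posterior is proper only with
  more than $2d+1$ strains, which is validated before sampling.

All randomness flows through R's RNG, so a seed makes runs byte-identical.
Non-positive-definite covariance draws are rejected and resampled (counted
and reported); every retained draw passes a Cholesky factorisation, so
every implied $r_g$ draw lies in $[-1, 1]$.

### Schedules

The default desk schedule is 50,000 iterations, 10,000 burn-in, thinning
10. For the package's own replicate studies (19 strains × 10 replicates,
two traits) we use 20,000/5,000/5: the $r_g$ chain there has lag-1
autocorrelation ≈ 0.03, so longer runs only cost time. The
100-strain partition analyses use 12,000/3,000/3. Publication-grade runs on
real data should use a much longer schedule (the literature uses up to
13M/3M with thinning 1,000), passed through `model_spec()`. Convergence is
checked with `convergence_report()`: the pass rule is |lag-1
autocorrelation| < 0.1 for every scalar parameter of the retained chain,
plus an effective-sample-size estimate from the truncated autocorrelation
sum; degenerate (constant) chains fail explicitly.

### Phylogenetic vs strain partition

`component_regression_compare()` asks whether the regression of one trait
on another (say survival on ln density) differs between the phylogenetic
and strain components: per draw, $b_c = \sigma_{c:12}/\sigma^2_{c:1}$ for
each component $c$, and the posterior of $b_p - b_s$ is summarised. Draws
in which either component's predictor variance is numerically zero —
defined as less than 1% (configurable) of that draw's total between-strain
predictor variance — are skipped and counted, because a slope inside a
component that explains essentially nothing is not meaningful.

Two caveats that the package surfaces as warnings rather than hiding:
with ~19 strains the two components are weakly identified in a joint
model, and on coalescent trees (root-heavy, roughly 3–8 effective
phylogenetic degrees of freedom regardless of tip count) the phylogenetic
covariance is poorly estimated unless it is large. The test suite's
partition study therefore uses 100 strains and a strong link (correlation
0.95, regression slope 2.7) carried by exactly one component, with the
"null" component in the strain-link case given appreciable variance and
zero covariance so that its slope is data-informed; weaker configurations
are genuinely undecidable from this design, which mirrors how real studies
report the phylogenetic component with caution.

## What the synthetic data do and do not emulate

The generator reproduces the design skeleton of a transinfection panel
study: ~19 strains plus a symbiont-free control in a common host genetic
background, three infection treatments, four replicate vials per strain and
treatment (two per day over six days, split across three treatments;
control replication doubled), 20 flies per vial followed 25 days, 10 pools
of flies per strain for qPCR with two technical replicates, plate batch
effects, and a day-1 injury-death rate (default 2%; the real rate is not
reported anywhere, so it is an explicit parameter rather than a matched
value). Survival times are exponential given the vial's hazard and
discretised by ceiling to whole days, producing exactly the tie structure
the Efron approximation must face; vial frailty is lognormal on the hazard
(Gaussian on the log-hazard, matching the fitted model); qPCR noise is
additive Gaussian on Ct, i.e. multiplicative lognormal on quantity.

What it does not emulate: non-proportional hazards, within-vial contagion
or shared-food effects beyond a single multiplicative frailty, mechanistic
within-host virus growth (titer time-courses are simulated only as smooth
polynomial trends where needed), primer-specific qPCR artefacts, or
model-misspecified residual distributions. Passing tests therefore
demonstrate correctness of the estimators under the generating model — the
self-consistency a pipeline must have before touching real data — not
robustness to every failure mode of real assays.

## Numerical choices and degenerate inputs

* Cox Newton iterations use step halving on the penalized objective;
  convergence at $10^{-9}$ relative change and gradient $10^{-5}$.
  Non-identifiable coefficients (a strain with no events) are flagged with
  infinite standard errors and p = 1, never dropped silently.
* A fit with no events, a dilution series with non-negative slope, a plate
  with zero variance, a non-ultrametric tree, a negative variance: all are
  errors with messages naming the offending object, not warnings.
* The null Cox model (`~ 1`) has an empty design and is handled explicitly,
  so likelihood-ratio tests of a single factor work.
* HPD windows require ≥ 2 finite draws and warn below 100.
* `simulate_*` functions restore the caller's RNG state; two runs with one
  config are byte-identical, and the pipeline expands its global seed as
  `seed + 1000·stage`.

## Known limitations

* The integrated likelihood for the frailty variance is a Laplace
  approximation; with very few vials its optimum is noisy (the test suite
  only constrains it to the right order of magnitude).
* The Gibbs sampler's strain/phylogeny partition mixes slowly when both
  components are nearly unidentified; the convergence report is the guard,
  and the phylo-only model (`include_strain_effect = FALSE`) is the
  recommended fallback, just as published analyses fall back to it.
* Dunnett adjusted p-values are Monte-Carlo evaluations of multivariate-t
  probabilities (seeded, via multcomp); they carry ~1e-3 jitter.
* The per-vial protection trait treats the strain coefficient as shared
  across a treatment's fit; protection against different viruses must come
  from separate per-treatment fits, which is how the pipeline runs them.
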