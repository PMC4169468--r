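# symbiocomp

Comparative analysis of symbiont-mediated antiviral protection across host
lines: from raw survival and qPCR measurements to genetic correlations
between symbiont traits, partitioned into phylogenetic and strain-specific
components.

## The scientific problem

Heritable bacterial symbionts such as *Wolbachia* can protect their insect
hosts against RNA viruses, and strains differ enormously in how much
protection they confer. Two questions drive the analysis this package
implements:

1. **How protective is each strain?** Measured as the negative log hazard
   ratio of symbiont-carrying flies versus symbiont-free flies, estimated
   per replicate vial from a mixed-effect Cox proportional-hazards model
   (strain as fixed effect, vial as Gaussian frailty, Efron ties for the
   daily death census, day-1 injury deaths excluded, censoring at the end
   of follow-up).

2. **Is protection genetically correlated with other symbiont traits —
   above all bacterial density?** Strain-level traits (per-vial protection,
   ln relative density, ln viral titer, host gene expression from
   efficiency-corrected qPCR) are jointly modelled as

   y_twi = β_t + u_s:tw + u_p:tw + e_twi,

   where the strain effects u_s have trait covariance **V**_s (independent
   across strains), the phylogenetic effects u_p have covariance
   **V**_p ⊗ **A** under Brownian evolution — **A** being the matrix of
   pairwise shared-ancestry proportions computed from the symbiont
   phylogeny — and each trait has its own residual variance. A blocked
   Gibbs sampler (parameter-expanded, inverse-Wishart or flat priors on the
   covariance matrices) yields posterior draws, from which genetic
   correlations r_g = σ_t1,t2 / √(σ²_t1 σ²_t2) are summarised with 95%
   highest-posterior-density intervals, and the regression of survival on
   density can be compared between the phylogenetic and strain components.

A synthetic-data module simulates the entire experiment — coalescent strain
phylogenies, strain effects with known **V**_s / **V**_p, survival assays
with vial frailty and daily censuses, qPCR plates with known amplification
efficiencies and batch effects — so every stage of the pipeline is testable
against ground truth.

## Worked example

Simulate 19 strains with a true strain-level correlation of 0.8 between
protection and ln density, then recover it:

```r
library(symbiocomp)

tree <- simulate_tree(19, seed = 1)
A    <- shared_ancestry_matrix(tree)
eff  <- simulate_strain_effects(
  tree, V_s = matrix(c(1, 0.8, 0.8, 1), 2), V_p = diag(0, 2),
  seed = 2, trait_names = c("protection", "ln_density")
)
set.seed(3)
traits <- do.call(rbind, lapply(c("protection", "ln_density"), \(tn)
  data.frame(strain = rep(rownames(eff$effects), each = 10), trait = tn,
             value  = rep(eff$effects[, tn], each = 10) + rnorm(190))))

spec <- model_spec(c("protection", "ln_density"), prior = "px",
                   iterations = 20000, burn_in = 5000, thin = 5, seed = 4)
post <- fit_multiresponse(traits, spec)
genetic_correlation(post, "protection", "ln_density", "strain")
#> r_g(protection, ln_density | strain) = 0.839, 95% HPD [0.646, 1.000]
convergence_report(post)
#> Convergence: PASS
#>                   parameter lag1_autocorr  ess degenerate
#>          sigma2[protection]  -0.019060100 3000      FALSE
#>  V_s[protection,protection]   0.016262907 3000      FALSE
#>  ...
```

The posterior mean 0.84 recovers the generating correlation 0.8; the HPD
reflects what 19 strains can say about a correlation. The full
simulate → quantify → survival → comparative chain is one call:

```r
run <- run_pipeline(run_config(outdir = "demo_run", seed = 1))
make_report(run)   # markdown report: protection tables with significance
                   # stars, r_g matrix with HPDs, convergence diagnostics
```

Other entry points: `exclude_day1_deaths()` / `fit_cox_mixed()` /
`per_vial_protection()` / `strain_vs_control_tests()` for the survival
stage; `estimate_efficiency_dilution()` / `relative_quantity()` /
`assemble_qpcr_traits()` for qPCR; `anova_oneway()`,
`dunnett_many_to_one()`, `tukey_hsd()`,
`polynomial_backward_regression()` for the univariate analyses;
`component_regression_compare()` for the phylogeny-vs-strain partition.
The methods vignette (`vignettes/comparative-pipeline.Rmd`) documents the
models, priors, schedules and design choices.

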