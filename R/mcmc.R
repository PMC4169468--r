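#' Specify a multi-response (phylogenetic) mixed model
#'
#' Defines which traits enter the model, which between-strain covariance
#' components are fitted (strain-specific `V_s`, phylogenetic `V_p` whose
#' strain structure is the shared-ancestry matrix `A`), the prior family on
#' the covariance matrices, and the MCMC schedule. Trait intercepts always
#' get independent normal priors with mean 0 and variance 1e10 (effectively
#' flat); residual variances get a vague scaled inverse-chi-square prior.
#'
#' Prior families on `V_s` / `V_p`:
#' \describe{
#'   \item{`"px"`}{parameter expansion: redundant per-trait working scales
#'     with a N(0, `alpha_var`) prior around an inverse-Wishart inner
#'     matrix, giving heavy-tailed (half-Cauchy-like, scale 1) marginals on
#'     the standard deviations. The default, and the family best behaved
#'     when variance components are small.}
#'   \item{`"iw"`}{inverse-Wishart with `nu0` = dimension + 1 degrees of
#'     freedom and scale `0.01 * I`.}
#'   \item{`"flat"`}{improper flat prior on the covariance matrix; proper
#'     posterior only when the number of strains exceeds twice the trait
#'     dimension plus one (validated at fit time).}
#' }
#'
#' @param traits Character vector of trait names to include.
#' @param include_strain_effect,include_phylo_effect Which components to fit
#'   (at least one; both gives the phylogenetic-vs-strain partition, with a
#'   weak-identifiability warning at small strain numbers).
#' @param A Shared-ancestry matrix (required iff the phylogenetic effect is
#'   on); labels must cover every strain in the data.
#' @param prior `"px"`, `"iw"` or `"flat"`.
#' @param iterations,burn_in,thin,seed MCMC schedule. The default is a desk
#'   schedule (50,000 iterations, 10,000 burn-in, thinning 10) suitable for
#'   the data sizes this package targets; for publication-grade runs pass a
#'   longer schedule (e.g. 13e6 / 3e6 / 1000).
#' @param nu0,S0_scale Inverse-Wishart hyperparameters (`"iw"` prior);
#'   `nu0 = NULL` means dimension + 1.
#' @param alpha_var Working-parameter prior variance (`"px"` prior).
#' @return List of class `"model_spec"`.
#' @export
model_spec <- function(traits,
                       include_strain_effect = TRUE,
                       include_phylo_effect = FALSE,
                       A = NULL,
                       prior = c("px", "iw", "flat"),
                       iterations = 50000L, burn_in = 10000L, thin = 10L,
                       seed = 1L,
                       nu0 = NULL, S0_scale = 0.01, alpha_var = 1) {
  prior <- match.arg(prior)
  if (!include_strain_effect && !include_phylo_effect) {
    warning("no between-strain component requested; ",
            "fitting intercepts and residual variances only")
  }
  if (include_phylo_effect && is.null(A)) {
    stop("the phylogenetic effect requires a shared-ancestry matrix `A`")
  }
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(
    traits = traits,
    include_strain_effect = include_strain_effect,
    include_phylo_effect = include_phylo_effect,
    A = A, prior = prior,
    mcmc = list(iterations = as.integer(iterations),
                burn_in = as.integer(burn_in), thin = as.integer(thin),
                seed = as.integer(seed)),
    nu0 = nu0, S0_scale = S0_scale, alpha_var = alpha_var
  ), class = "model_spec")
}

#' Fit the Bayesian multi-response mixed model by Gibbs sampling
#'
#' The model is \eqn{y_{twi} = \beta_t + u_{s:tw} + u_{p:tw} + e_{twi}}:
#' a trait intercept, a strain deviation with trait covariance `V_s`
#' (independent across strains), an optional phylogenetic deviation with
#' covariance `V_p` across traits and the shared-ancestry matrix `A` across
#' strains (Brownian evolution), and a residual with a separate variance per
#' trait (traits are measured on different biological replicates, so
#' residuals are independent across traits). The sampler alternates a joint
#' Gaussian draw of all location effects, inverse-Wishart draws of `V_s` and
#' `V_p` (with parameter-expansion working scales under the `"px"` prior),
#' and scaled inverse-chi-square draws of the residual variances. Strains
#' missing a trait simply contribute no rows for it (missing at random).
#'
#' @param table Long trait table: columns `strain`, `trait`, `value`
#'   (finite), optionally `replicate`.
#' @param spec A [model_spec()].
#' @return Object of class `"posterior_draws"`: `beta` (draws x traits),
#'   `V_s` and `V_p` (draws x traits x traits arrays, absent components
#'   `NULL`), `sigma2` (draws x traits), `traits`, `strains`, `spec`,
#'   `npd_rejects` (non-positive-definite covariance draws that were
#'   rejected and resampled).
#' @export
fit_multiresponse <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("strain", "trait", "value")
  if (!all(need %in% names(table))) {
    stop("trait table must have columns strain, trait, value")
  }
  table <- table[table$trait %in% spec$traits, , drop = FALSE]
  missing_traits <- setdiff(spec$traits, unique(table$trait))
  if (length(missing_traits)) {
    stop("trait(s) absent from the table: ",
         paste(missing_traits, collapse = ", "))
  }
  if (any(!is.finite(table$value))) stop("trait values must be finite")
  strains <- sort(unique(as.character(table$strain)))
  if (length(strains) < 2) stop("need >= 2 strains")
  Tn <- length(spec$traits)
  Ainv <- matrix(0, 1, 1)
  if (spec$include_phylo_effect) {
    A <- spec$A
    miss <- setdiff(strains, rownames(A))
    if (length(miss)) {
      stop("shared-ancestry matrix lacks strain(s): ",
           paste(miss, collapse = ", "))
    }
    A <- as.matrix(A[strains, strains])
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch) || min(diag(ch)) < 1e-7) {
      message("shared-ancestry matrix is singular; adding 1e-8 jitter")
      A <- A + diag(1e-8, nrow(A))
    }
    Ainv <- solve(A)
  }
  if (spec$prior == "flat" && length(strains) <= 2 * Tn + 1) {
    stop("flat covariance prior is improper here: need more than ",
         2 * Tn + 1, " strains for ", Tn, " traits")
  }
  if (spec$include_strain_effect && spec$include_phylo_effect &&
      length(strains) < 30) {
    warning("strain and phylogenetic components are weakly identified with ",
            length(strains), " strains; interpret the partition cautiously")
  }
  trait_idx <- match(as.character(table$trait), spec$traits) - 1L
  strain_idx <- match(as.character(table$strain), strains) - 1L
  nu0 <- spec$nu0 %||% (Tn + 1)
  prior_code <- match(spec$prior, c("px", "iw", "flat")) - 1L
  raw <- with_seed(spec$mcmc$seed, gibbs_multiresponse(
    y = as.numeric(table$value), trait = trait_idx, strain = strain_idx,
    n_traits = Tn, n_strains = length(strains),
    use_strain = spec$include_strain_effect,
    use_phylo = spec$include_phylo_effect,
    Ainv = Ainv, prior = prior_code,
    nu0 = nu0, S0 = diag(spec$S0_scale, Tn),
    # working-matrix df = dim + 1 makes the implied marginal prior on each
    # correlation uniform on (-1, 1)
    nu_px = Tn + 1, S0_px = diag(1, Tn), alpha_var = spec$alpha_var,
    nu_e = 0.002, s2_e = 1,
    n_iter = spec$mcmc$iterations, burn_in = spec$mcmc$burn_in,
    thin = spec$mcmc$thin,
    Vs_init = spec$Vs_init %||% matrix(0, 0, 0),
    Vp_init = spec$Vp_init %||% matrix(0, 0, 0)
  ))
  K <- nrow(raw$beta)
  to_array <- function(m) {
    if (nrow(m) == 0) return(NULL)
    a <- array(t(m), dim = c(Tn, Tn, K),
               dimnames = list(spec$traits, spec$traits, NULL))
    aperm(a, c(3, 1, 2))
  }
  beta <- raw$beta; colnames(beta) <- spec$traits
  sigma2 <- raw$sigma2; colnames(sigma2) <- spec$traits
  structure(list(
    beta = beta, V_s = to_array(raw$V_s), V_p = to_array(raw$V_p),
    sigma2 = sigma2, traits = spec$traits, strains = strains, spec = spec,
    npd_rejects = raw$npd_rejects
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "Posterior draws: %d retained samples, %d trait(s), %d strains\n",
    nrow(x$beta), length(x$traits), length(x$strains)
  ))
  cat("components:",
      paste(c(if (!is.null(x$V_s)) "strain", if (!is.null(x$V_p)) "phylo"),
            collapse = " + ") %||% "none", "\n")
  if (x$npd_rejects > 0) {
    cat(x$npd_rejects, "non-PD covariance draws rejected and resampled\n")
  }
  invisible(x)
}

# pull the draws of one covariance component as a K x T x T array
component_draws <- function(draws, component = c("strain", "phylo",
                                                 "combined")) {
  component <- match.arg(component)
  V <- switch(component,
    strain = draws$V_s,
    phylo = draws$V_p,
    combined = {
      if (is.null(draws$V_s) || is.null(draws$V_p)) {
        draws$V_s %||% draws$V_p
      } else draws$V_s + draws$V_p
    }
  )
  if (is.null(V)) {
    stop("component '", component, "' was not fitted in this model")
  }
  V
}

#' Posterior genetic correlation between two traits
#'
#' For every retained draw of the chosen covariance component, the genetic
#' correlation \eqn{r_g = \sigma_{t_1 t_2} / \sqrt{\sigma^2_{t_1}
#' \sigma^2_{t_2}}} is computed; the posterior is summarised by its mean and
#' 95% highest-posterior-density interval.
#'
#' @param draws A `"posterior_draws"` object.
#' @param t1,t2 Trait names.
#' @param component `"strain"`, `"phylo"`, or `"combined"` (elementwise sum
#'   of both components).
#' @param mass HPD mass.
#' @return List of class `"genetic_correlation"`: `traits`, `component`,
#'   `mean`, `hpd` (length-2), `draws` (the per-draw correlations).
#' @export
genetic_correlation <- function(draws, t1, t2, component = "strain",
                                mass = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!all(c(t1, t2) %in% draws$traits)) {
    stop("both traits must be in the fitted model")
  }
  V <- component_draws(draws, component)
  r <- V[, t1, t2] / sqrt(V[, t1, t1] * V[, t2, t2])
  hpd <- hpd_interval(r, mass)
  structure(list(
    traits = c(t1, t2), component = component, mean = mean(r),
    hpd = hpd, mass = mass, draws = r
  ), class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf(
    "r_g(%s, %s | %s) = %.3f, %d%% HPD [%.3f, %.3f]\n",
    x$traits[1], x$traits[2], x$component, x$mean,
    round(100 * x$mass), x$hpd[1], x$hpd[2]
  ))
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted sample containing
#' `ceiling(mass * n)` points; ties in width are broken toward the lower
#' window start. For symmetric unimodal posteriors this coincides with the
#' equal-tailed interval up to Monte-Carlo error.
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1).
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("mass must be a single number in (0, 1)")
  }
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("need at least 2 finite samples")
  if (n < 100) {
    warning("HPD interval from fewer than 100 samples is unstable")
  }
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- which.min(widths) # which.min takes the first: ties go to lower start
  c(x[i], x[i + k - 1])
}

#' Convergence diagnostics for posterior draws
#'
#' Per scalar parameter: lag-1 autocorrelation of the retained (thinned)
#' chain and an effective sample size from the truncated autocorrelation sum
#' (initial positive sequence). The chain passes when every finite lag-1
#' autocorrelation is below 0.1 in absolute value; constant (degenerate)
#' chains are flagged and fail.
#'
#' @param draws A `"posterior_draws"` object or a numeric matrix with one
#'   column per scalar parameter.
#' @return List of class `"convergence_report"`: `table` (data frame with
#'   `parameter`, `lag1_autocorr`, `ess`, `degenerate`), `pass`.
#' @export
convergence_report <- function(draws) {
  m <- if (inherits(draws, "posterior_draws")) {
    cols <- list(beta = draws$beta, sigma2 = draws$sigma2)
    flat <- do.call(cbind, lapply(names(cols), function(nm) {
      x <- cols[[nm]]
      colnames(x) <- paste0(nm, "[", colnames(x), "]")
      x
    }))
    for (comp in c("V_s", "V_p")) {
      V <- draws[[comp]]
      if (is.null(V)) next
      Tn <- dim(V)[2]
      for (i in seq_len(Tn)) for (j in i:Tn) {
        flat <- cbind(flat, setNames(
          data.frame(V[, i, j]),
          sprintf("%s[%s,%s]", comp, draws$traits[i], draws$traits[j])
        ))
      }
    }
    as.matrix(flat)
  } else as.matrix(draws)
  stats_of <- function(x) {
    if (sd(x) == 0 || !is.finite(sd(x))) {
      return(c(lag1 = NA_real_, ess = 0, degen = 1))
    }
    n <- length(x)
    rho <- as.numeric(acf(x, lag.max = min(n - 1, 200),
                          plot = FALSE)$acf)[-1]
    lag1 <- rho[1]
    pos <- which(rho <= 0.05)
    upto <- if (length(pos)) pos[1] - 1 else length(rho)
    ess <- n / (1 + 2 * sum(rho[seq_len(upto)]))
    c(lag1 = lag1, ess = max(min(ess, n), 1), degen = 0)
  }
  st <- t(apply(m, 2, stats_of))
  tab <- data.frame(
    parameter = colnames(m), lag1_autocorr = st[, "lag1"],
    ess = st[, "ess"], degenerate = st[, "degen"] == 1,
    row.names = NULL, stringsAsFactors = FALSE
  )
  pass <- !any(tab$degenerate) &&
    all(abs(tab$lag1_autocorr) < 0.1, na.rm = TRUE)
  structure(list(table = tab, pass = pass), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s\n", if (x$pass) "PASS" else "FAIL"))
  worst <- x$table[order(-abs(x$table$lag1_autocorr)), ]
  print(head(worst, 5), row.names = FALSE)
  invisible(x)
}

#' Compare the density-trait regression between phylogenetic and strain
#' components
#'
#' For each draw, the regression slope of the response trait on the
#' predictor trait implied by each covariance component,
#' \eqn{b_c = \sigma_{c:resp,pred} / \sigma^2_{c:pred}}, is computed for the
#' phylogenetic and the strain component; the posterior of the difference
#' \eqn{b_{phylo} - b_{strain}} is summarised. A 95% HPD excluding zero
#' indicates that shared ancestry and strain-specific variation carry
#' different trait relationships. Draws where either component's predictor
#' variance is numerically zero are skipped (counted).
#'
#' @param draws A `"posterior_draws"` with both components fitted.
#' @param response_trait,predictor_trait Trait names.
#' @param mass HPD mass.
#' @param var_tol A draw is skipped when either component's predictor
#'   variance is numerically zero, defined as less than `var_tol` times the
#'   draw's total (strain + phylogenetic) predictor variance: a regression
#'   slope within a component that explains essentially none of the
#'   between-strain variance is not defined in any meaningful sense, and
#'   the ratio would be pure noise.
#' @return List with `mean`, `hpd`, `n_used`, `n_skipped`, `draws`
#'   (differences), `b_phylo`, `b_strain` (per-draw slopes).
#' @export
component_regression_compare <- function(draws, response_trait,
                                         predictor_trait, mass = 0.95,
                                         var_tol = 0.01) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(draws$V_s) || is.null(draws$V_p)) {
    stop("both strain and phylogenetic components must be fitted")
  }
  vp <- draws$V_p[, predictor_trait, predictor_trait]
  vs <- draws$V_s[, predictor_trait, predictor_trait]
  tot <- vp + vs
  ok <- vp > var_tol * tot & vs > var_tol * tot & tot > 1e-12
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(n_skipped, " draw(s) skipped: predictor variance ~ 0")
  }
  b_p <- draws$V_p[ok, response_trait, predictor_trait] / vp[ok]
  b_s <- draws$V_s[ok, response_trait, predictor_trait] / vs[ok]
  d <- b_p - b_s
  list(mean = mean(d), hpd = hpd_interval(d, mass), n_used = sum(ok),
       n_skipped = n_skipped, draws = d, b_phylo = b_p, b_strain = b_s)
}

#' The six standard trait-combination model specifications
#'
#' Builds the trait sets of the six comparative models the pipeline is
#' organised around: (1) survival under both viral challenges and
#' mock-infection plus symbiont density; (2) the two viral titers plus
#' density; (3, 4) survival and titer for each virus; (5, 6) survival plus
#' the three host-gene expression traits for each virus.
#'
#' @param ... Passed to [model_spec()] (e.g. `A`, `prior`, the schedule).
#' @return Named list of six [model_spec()] objects.
#' @export
standard_model_specs <- function(...) {
  trait_sets <- list(
    model1 = c("survival_DCV", "survival_FHV", "survival_Ringer",
               "ln_density"),
    model2 = c("titer_DCV", "titer_FHV", "ln_density"),
    model3 = c("survival_DCV", "titer_DCV"),
    model4 = c("survival_FHV", "titer_FHV"),
    model5 = c("survival_DCV", "expr_Drosomycin_DCV", "expr_Diptericin_DCV",
               "expr_Dnmt2_DCV"),
    model6 = c("survival_FHV", "expr_Drosomycin_FHV", "expr_Diptericin_FHV",
               "expr_Dnmt2_FHV")
  )
  lapply(trait_sets, function(tr) model_spec(traits = tr, ...))
}
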