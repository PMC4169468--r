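# build a posterior_draws object by hand (for summary-level operations)
fake_draws <- function(Vs_list, traits = c("x", "y")) {
  K <- length(Vs_list)
  Tn <- length(traits)
  V <- array(NA_real_, dim = c(K, Tn, Tn),
             dimnames = list(NULL, traits, traits))
  for (k in seq_len(K)) V[k, , ] <- Vs_list[[k]]
  structure(list(
    beta = matrix(0, K, Tn, dimnames = list(NULL, traits)),
    V_s = V, V_p = NULL,
    sigma2 = matrix(1, K, Tn, dimnames = list(NULL, traits)),
    traits = traits, strains = c("a", "b"), spec = NULL, npd_rejects = 0L
  ), class = "posterior_draws")
}

test_that("HPD interval is the shortest sorted window", {
  # brute force over all contiguous windows
  brute_hpd <- function(x, mass) {
    x <- sort(x); n <- length(x); k <- ceiling(mass * n)
    w <- sapply(1:(n - k + 1), function(i) x[i + k - 1] - x[i])
    i <- which.min(w)
    c(x[i], x[i + k - 1])
  }
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  expect_equal(hpd_interval(1:100, 0.95), brute_hpd(1:100, 0.95))
  set.seed(4)
  for (i in 1:20) {
    x <- rgamma(200, shape = sample(1:5, 1))
    m <- runif(1, 0.5, 0.99)
    expect_equal(hpd_interval(x, m), brute_hpd(x, m))
  }
  expect_equal(hpd_interval(rep(2, 150), 0.95), c(2, 2))
  # symmetric unimodal: HPD ~ equal-tailed
  z <- rnorm(50000)
  expect_equal(hpd_interval(z, 0.95), quantile(z, c(0.025, 0.975)),
               tolerance = 0.05, ignore_attr = TRUE)
  expect_error(hpd_interval(1:200, 1.2), "mass")
  expect_error(hpd_interval(1:200, 0), "mass")
  expect_warning(hpd_interval(1:50, 0.9), "fewer than 100")
})

test_that("genetic correlation summarises covariance draws", {
  d <- fake_draws(rep(list(matrix(c(1, .5, .5, 1), 2)), 120))
  g <- genetic_correlation(d, "x", "y", "strain")
  expect_equal(g$mean, 0.5)
  expect_equal(unname(g$hpd), c(0.5, 0.5))

  ddiag <- fake_draws(rep(list(diag(2)), 120))
  expect_equal(genetic_correlation(ddiag, "x", "y", "strain")$mean, 0)

  # Wishart draws centred on a known correlation: Monte-Carlo oracle
  set.seed(9)
  V0 <- matrix(c(1, .75, .75, 1), 2)
  df <- 400
  ws <- lapply(1:4000, function(i) {
    L <- chol(V0 / df)
    Z <- matrix(rnorm(2 * df), df, 2) %*% L
    crossprod(Z)
  })
  gw <- genetic_correlation(fake_draws(ws), "x", "y", "strain")
  expect_equal(gw$mean, 0.75, tolerance = 0.05)
  expect_error(genetic_correlation(d, "x", "y", "phylo"), "not fitted")
  expect_error(genetic_correlation(d, "x", "zz"), "traits")
})

test_that("conjugate residual-only toy matches the analytic posterior", {
  set.seed(1)
  y <- rnorm(40, 2, 1.5)
  tab <- data.frame(strain = rep(c("a", "b"), 20), trait = "t1", value = y)
  spec <- suppressWarnings(model_spec(
    "t1", include_strain_effect = FALSE,
    iterations = 22000, burn_in = 2000, thin = 1, seed = 7
  ))
  post <- suppressWarnings(fit_multiresponse(tab, spec))
  # flat-ish intercept prior: sigma^2 | y is scaled inverse chi-square
  n <- length(y); S <- sum((y - mean(y))^2); nu0 <- 0.002
  set.seed(8)
  exact <- (nu0 + S) / rchisq(100000, nu0 + n - 1)
  ks <- suppressWarnings(ks.test(post$sigma2[, 1], exact))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("every covariance draw is PD and correlations stay in [-1, 1]", {
  tab <- sim_two_trait_table(0.5, seed = 31)
  tr <- simulate_tree(19, 31)
  spec <- model_spec(c("x", "y"), include_phylo_effect = TRUE,
                     A = shared_ancestry_matrix(tr), prior = "px",
                     iterations = 4000, burn_in = 1000, thin = 2, seed = 5)
  post <- suppressWarnings(fit_multiresponse(tab, spec))
  for (comp in c("V_s", "V_p")) {
    V <- post[[comp]]
    ok <- vapply(seq_len(dim(V)[1]), function(k) {
      inherits(try(chol(V[k, , ]), silent = TRUE), "matrix")
    }, logical(1))
    expect_true(all(ok))
    r <- V[, 1, 2] / sqrt(V[, 1, 1] * V[, 2, 2])
    expect_true(all(r >= -1 & r <= 1))
  }
})

test_that("convergence diagnostics classify iid, AR(1) and constant chains", {
  set.seed(2)
  iid <- matrix(rnorm(4000), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  rep_iid <- convergence_report(iid)
  expect_true(rep_iid$pass)
  expect_lt(max(abs(rep_iid$table$lag1_autocorr)), 0.1)

  ar <- as.numeric(arima.sim(list(ar = 0.5), 6000))
  rep_ar <- convergence_report(matrix(ar, dimnames = list(NULL, "rho")))
  expect_false(rep_ar$pass)
  expect_equal(rep_ar$table$lag1_autocorr, 0.5, tolerance = 0.08)
  expect_lt(rep_ar$table$ess, 6000 / 2.5)

  rep_const <- convergence_report(matrix(1, 500, 1,
                                         dimnames = list(NULL, "c")))
  expect_true(rep_const$table$degenerate)
  expect_false(rep_const$pass)
})

test_that("star-tree phylo-only model is equivalent to the strain-only model", {
  tab <- sim_two_trait_table(0.8, seed = 41)
  star_A <- shared_ancestry_matrix(make_star_tree(19))
  sched <- list(iterations = 12000, burn_in = 3000, thin = 3)
  s1 <- do.call(model_spec, c(list(c("x", "y"), prior = "px", seed = 6),
                              sched))
  s2 <- do.call(model_spec, c(list(c("x", "y"),
                                   include_strain_effect = FALSE,
                                   include_phylo_effect = TRUE, A = star_A,
                                   prior = "px", seed = 6), sched))
  g1 <- genetic_correlation(fit_multiresponse(tab, s1), "x", "y", "strain")
  g2 <- genetic_correlation(fit_multiresponse(tab, s2), "x", "y", "phylo")
  expect_equal(g1$mean, g2$mean, tolerance = 0.1)
  expect_equal(g1$hpd, g2$hpd, tolerance = 0.2)
})

test_that("prior families agree on a well-identified dataset", {
  tab <- sim_two_trait_table(0.6, seed = 51, n_strains = 150, reps = 8,
                             resid_sd = 0.5)
  means <- vapply(c("px", "iw", "flat"), function(pr) {
    spec <- model_spec(c("x", "y"), prior = pr, iterations = 8000,
                       burn_in = 2000, thin = 2, seed = 3)
    genetic_correlation(fit_multiresponse(tab, spec), "x", "y",
                        "strain")$mean
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.05)
})

test_that("missing traits for some strains are handled, not fatal", {
  tab <- sim_two_trait_table(0.5, seed = 61)
  drop <- unique(tab$strain)[1:3]
  tab_miss <- tab[!(tab$trait == "y" & tab$strain %in% drop), ]
  spec <- model_spec(c("x", "y"), iterations = 4000, burn_in = 1000,
                     thin = 2, seed = 4)
  g_full <- genetic_correlation(fit_multiresponse(tab, spec), "x", "y")
  g_miss <- genetic_correlation(fit_multiresponse(tab_miss, spec),
                                "x", "y")
  expect_true(is.finite(g_miss$mean))
  expect_equal(g_full$mean, g_miss$mean, tolerance = 0.35)
})

test_that("model specification is validated", {
  expect_error(model_spec("x", include_phylo_effect = TRUE), "requires")
  expect_error(model_spec("x", iterations = 100, burn_in = 200), "exceed")
  expect_error(model_spec("x", thin = 0), "thin")
  expect_warning(model_spec("x", include_strain_effect = FALSE),
                 "residual variances only")
  tab <- sim_two_trait_table(0, seed = 1, n_strains = 4)
  expect_error(
    fit_multiresponse(tab, model_spec(c("x", "zz"), iterations = 200,
                                      burn_in = 100)),
    "absent"
  )
  expect_error(
    fit_multiresponse(tab, model_spec(c("x", "y"), prior = "flat",
                                      iterations = 200, burn_in = 100)),
    "flat"
  )
  A_small <- shared_ancestry_matrix(make_star_tree(3))
  expect_error(
    fit_multiresponse(tab, model_spec(c("x", "y"),
                                      include_phylo_effect = TRUE,
                                      A = A_small, iterations = 200,
                                      burn_in = 100)),
    "lacks strain"
  )
})

test_that("component regression difference is exact on constant draws", {
  V <- matrix(c(1, .5, .5, 2), 2)
  K <- 150
  mk <- function(Vc) {
    a <- array(NA_real_, c(K, 2, 2),
               dimnames = list(NULL, c("x", "y"), c("x", "y")))
    for (k in 1:K) a[k, , ] <- Vc
    a
  }
  d <- fake_draws(rep(list(V), K))
  d$V_p <- mk(V) # identical components
  cmp <- component_regression_compare(d, "y", "x")
  expect_equal(cmp$mean, 0)
  expect_equal(unname(cmp$hpd), c(0, 0))
  # degenerate predictor variance in one component: draws skipped
  d2 <- d
  d2$V_p[1:10, 1, 1] <- 1e-9
  expect_message(cmp2 <- component_regression_compare(d2, "y", "x"),
                 "skipped")
  expect_equal(cmp2$n_skipped, 10)
})
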