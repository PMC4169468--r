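# Shared fixtures, all generated in code.

# star phylogeny: no shared ancestry, A = I
make_star_tree <- function(n) {
  labs <- sprintf("w%02d", seq_len(n))
  read_newick(paste0("(", paste0(labs, ":1", collapse = ","), ");"))
}

# long trait table from a strains x traits effect matrix + iid noise
make_trait_table <- function(effects, reps = 10, resid_sd = 1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(colnames(effects), function(tn) data.frame(
    strain = rep(rownames(effects), each = reps), trait = tn,
    replicate = rep(seq_len(reps), nrow(effects)),
    value = rep(effects[, tn], each = reps) +
      rnorm(nrow(effects) * reps, 0, resid_sd),
    stringsAsFactors = FALSE
  )))
}

# two-trait dataset with known strain-level correlation r (star tree)
sim_two_trait_table <- function(r, seed, n_strains = 19, reps = 10,
                                resid_sd = 1) {
  tree <- make_star_tree(n_strains)
  eff <- simulate_strain_effects(
    tree, V_s = matrix(c(1, r, r, 1), 2), V_p = diag(0, 2),
    seed = seed, trait_names = c("x", "y")
  )
  make_trait_table(eff$effects, reps, resid_sd, seed + 1)
}

# independent partial-likelihood oracle: Breslow/no-ties product over risk
# sets for a single covariate, straight from the definition
hand_partial_loglik <- function(beta, x, day, event) {
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(day >= day[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# small survival dataset for oracle comparisons
sim_small_surv <- function(seed, n_strains = 3, vials = 2, flies = 15,
                           frailty_sd = 0, log_hr = NULL) {
  cfg <- sim_config(
    n_strains = max(n_strains, 2), vial_frailty_sd = frailty_sd,
    day1_injury_rate = 0, n_vials_per_strain_per_treatment = vials,
    flies_per_vial = flies
  )
  strains <- c("wfree", sprintf("s%d", seq_len(n_strains - 1)))
  if (is.null(log_hr)) {
    set.seed(seed)
    log_hr <- c(0, rnorm(n_strains - 1, 0, 0.5))
  }
  lhr <- matrix(log_hr, ncol = 1, dimnames = list(strains, "DCV"))
  simulate_survival(lhr, cfg, seed = seed)
}
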