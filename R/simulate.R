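#' Simulation configuration for a full comparative experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults mirror
#' the design of the study system the pipeline targets: 19 symbiont strains
#' plus one symbiont-free control line, survival assays of 20 stabbed flies
#' per vial followed daily for 25 days, four replicate vials per strain and
#' treatment (two vials per day over six replicate days, split across three
#' treatments) with the control replication doubled, and qPCR measurements
#' on 10 pools of flies per strain with two technical replicates per well.
#'
#' @param n_strains Number of symbiont strains (excluding the control line).
#' @param tree_seed,data_seed Integer seeds for the tree and for everything
#'   downstream of it.
#' @param trait_names Character vector naming the simulated strain traits.
#' @param V_s Strain (phylogeny-independent) trait covariance matrix,
#'   `length(trait_names)` square, PSD.
#' @param V_p Phylogenetic trait covariance matrix, same dimension, PSD.
#' @param residual_sd Per-trait residual SD on the replicate level (recycled
#'   to the number of traits). Only used where a trait is sampled directly
#'   rather than through the survival or qPCR generators.
#' @param n_vials_per_strain_per_treatment Replicate vials per strain and
#'   treatment.
#' @param control_label Label of the symbiont-free reference line.
#' @param control_replication Multiplier on the number of control vials.
#' @param flies_per_vial Flies per vial.
#' @param follow_up_days Length of follow-up; survivors are censored here.
#' @param baseline_hazard Daily death hazard of the reference line.
#' @param vial_frailty_sd SD of the Gaussian vial effect on the log hazard.
#' @param day1_injury_rate Probability that a fly dies on day 1 from the
#'   stabbing injury itself, independent of infection (exercises the day-1
#'   exclusion rule; the real rate is unknowable from the study design).
#' @param treatments Treatment labels.
#' @param qpcr List of qPCR settings: `n_pools`, `flies_per_pool`,
#'   `efficiency_target`, `efficiency_ref` (amplification efficiencies, in
#'   (1, 2.2]), `ct_noise_sd` (additive Gaussian noise on Ct, i.e.
#'   multiplicative lognormal on quantity), `n_plates`, `plate_shift_sd`
#'   (shared per-plate Ct shift), `tech_reps`, `ref_base_ct`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_strains = 19L,
                       tree_seed = 1L,
                       data_seed = 2L,
                       trait_names = c("survival_DCV", "survival_FHV",
                                       "survival_Ringer", "ln_density"),
                       V_s = NULL,
                       V_p = NULL,
                       residual_sd = 0.5,
                       n_vials_per_strain_per_treatment = 4L,
                       control_label = "wfree",
                       control_replication = 2L,
                       flies_per_vial = 20L,
                       follow_up_days = 25L,
                       baseline_hazard = 0.04,
                       vial_frailty_sd = 0.2,
                       day1_injury_rate = 0.02,
                       treatments = c("DCV", "FHV", "Ringer"),
                       qpcr = list()) {
  nt <- length(trait_names)
  if (is.null(V_s)) V_s <- diag(0.5, nt) + matrix(0.25, nt, nt)
  if (is.null(V_p)) V_p <- matrix(0, nt, nt)
  V_s <- as.matrix(V_s); V_p <- as.matrix(V_p)
  if (!all(dim(V_s) == nt) || !all(dim(V_p) == nt)) {
    stop("V_s and V_p must be square matrices matching length(trait_names)")
  }
  psd_sqrt(V_s); psd_sqrt(V_p) # errors if not PSD
  stopifnot_scalar_count(n_strains, "n_strains", 2L)
  qpcr_defaults <- list(
    n_pools = 10L, flies_per_pool = 10L,
    efficiency_target = 2, efficiency_ref = 2,
    ct_noise_sd = 0.15, n_plates = 4L, plate_shift_sd = 0.3,
    tech_reps = 2L, ref_base_ct = 20
  )
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)
  if (qpcr$efficiency_target <= 1 || qpcr$efficiency_target > 2.2 ||
      qpcr$efficiency_ref <= 1 || qpcr$efficiency_ref > 2.2) {
    stop("amplification efficiencies must lie in (1, 2.2]")
  }
  cfg <- list(
    n_strains = as.integer(n_strains), tree_seed = tree_seed,
    data_seed = data_seed, trait_names = trait_names, V_s = V_s, V_p = V_p,
    residual_sd = rep_len(residual_sd, nt),
    n_vials_per_strain_per_treatment =
      as.integer(n_vials_per_strain_per_treatment),
    control_label = control_label,
    control_replication = as.integer(control_replication),
    flies_per_vial = as.integer(flies_per_vial),
    follow_up_days = as.integer(follow_up_days),
    baseline_hazard = baseline_hazard,
    vial_frailty_sd = vial_frailty_sd,
    day1_injury_rate = day1_injury_rate,
    treatments = treatments, qpcr = qpcr
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a random ultrametric strain phylogeny
#'
#' Standard coalescent topology and waiting times via [ape::rcoal()], with
#' tip labels `w01, w02, ...` and depth rescaled to 1 (the shared-ancestry
#' matrix is scale-free, so only relative node depths matter). Deterministic
#' given the seed.
#'
#' @param n_strains Number of tips, >= 2.
#' @param seed Integer seed.
#' @return An ultrametric `"phylo"` object.
#' @export
simulate_tree <- function(n_strains, seed = 1L) {
  stopifnot_scalar_count(n_strains, "n_strains", 2L)
  tree <- with_seed(seed, ape::rcoal(
    n_strains, tip.label = sprintf("w%02d", seq_len(n_strains))
  ))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate strain trait effects with phylogenetic and strain components
#'
#' Draws, for each strain and trait, a phylogenetic deviation with
#' covariance `V_p` across traits and the shared-ancestry matrix `A` across
#' strains (so `vec(U_p) ~ N(0, V_p %x% A)`), plus an independent strain
#' deviation with trait covariance `V_s` (i.i.d. across strains). The two
#' components are returned separately as ground truth, and their sum is the
#' true strain trait value used by the downstream generators.
#'
#' @param tree `"phylo"` object, ultrametric.
#' @param V_s,V_p Trait covariance matrices, equal dimension, PSD.
#' @param seed Integer seed.
#' @param trait_names Optional trait names; defaults to `t1, t2, ...`.
#' @return List with `effects` (strains x traits), `phylo`, `strain`
#'   (the two components), `V_s`, `V_p`, and `r_g` (list with true strain-
#'   and phylogenetic-level correlation matrices where defined).
#' @export
simulate_strain_effects <- function(tree, V_s, V_p, seed = 1L,
                                    trait_names = NULL) {
  V_s <- as.matrix(V_s); V_p <- as.matrix(V_p)
  if (!all(dim(V_s) == dim(V_p))) {
    stop("V_s and V_p must have the same trait dimension")
  }
  nt <- nrow(V_s)
  if (is.null(trait_names)) trait_names <- paste0("t", seq_len(nt))
  A <- shared_ancestry_matrix(tree)
  S <- nrow(A)
  LA <- psd_sqrt(A)
  Ls <- psd_sqrt(V_s)
  Lp <- psd_sqrt(V_p)
  draws <- with_seed(seed, list(
    zp = matrix(rnorm(S * nt), S, nt),
    zs = matrix(rnorm(S * nt), S, nt)
  ))
  U_p <- LA %*% draws$zp %*% Lp # vec() covariance V_p %x% A
  U_s <- draws$zs %*% Ls
  dimnames(U_p) <- dimnames(U_s) <- list(rownames(A), trait_names)
  cor_of <- function(V) {
    d <- sqrt(diag(V))
    ok <- d > 0
    R <- matrix(NA_real_, nrow(V), ncol(V))
    R[ok, ok] <- V[ok, ok] / tcrossprod(d[ok])
    dimnames(R) <- list(trait_names, trait_names)
    R
  }
  list(
    effects = U_p + U_s, phylo = U_p, strain = U_s,
    V_s = V_s, V_p = V_p,
    r_g = list(strain = cor_of(V_s), phylo = cor_of(V_p))
  )
}

#' Simulate a survival assay under proportional hazards with vial frailty
#'
#' Each fly's continuous death time is exponential with hazard
#' `baseline_hazard * exp(log_hr + b_v)` where `b_v ~ N(0, vial_frailty_sd^2)`
#' is shared by all flies in a vial, then discretised to whole days by the
#' ceiling (deaths are recorded at the daily census, producing the heavy ties
#' a Cox fit must handle). Flies still alive after `follow_up_days` are
#' censored there. Independently, each fly dies on day 1 from the stabbing
#' injury with probability `day1_injury_rate`, exercising the day-1
#' exclusion rule.
#'
#' @param strain_log_hr Matrix of true log hazard ratios vs the reference,
#'   rows named by strain (include the reference with 0), columns named by
#'   treatment; or a named vector for a single treatment.
#' @param config A [sim_config()]; design fields are read from it.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `fly_id`, `strain`, `treatment`,
#'   `vial_id`, `day`, `event` (1 died, 0 censored).
#' @export
simulate_survival <- function(strain_log_hr, config = sim_config(),
                              seed = 1L) {
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (is.null(dim(strain_log_hr))) {
    strain_log_hr <- matrix(
      strain_log_hr,
      dimnames = list(names(strain_log_hr), config$treatments[1])
    )
  }
  strains <- rownames(strain_log_hr)
  treatments <- colnames(strain_log_hr)
  if (is.null(strains) || is.null(treatments)) {
    stop("strain_log_hr needs strain rownames and treatment colnames")
  }
  grid <- expand.grid(
    strain = strains, treatment = treatments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  nv <- config$n_vials_per_strain_per_treatment
  grid$n_vials <- ifelse(
    grid$strain == config$control_label, nv * config$control_replication, nv
  )
  with_seed(seed, {
    vials <- grid[rep(seq_len(nrow(grid)), grid$n_vials), c("strain", "treatment")]
    vials$vial_rep <- unlist(lapply(grid$n_vials, seq_len))
    vials$vial_id <- sprintf(
      "%s_%s_v%02d", vials$strain, vials$treatment, vials$vial_rep
    )
    vials$frailty <- rnorm(nrow(vials), 0, config$vial_frailty_sd)
    nf <- config$flies_per_vial
    flies <- vials[rep(seq_len(nrow(vials)), each = nf), ]
    flies$log_hr <- strain_log_hr[cbind(flies$strain, flies$treatment)]
    rate <- config$baseline_hazard * exp(flies$log_hr + flies$frailty)
    tcont <- rexp(nrow(flies), rate = rate)
    day <- ceiling(tcont)
    event <- rep(1L, nrow(flies))
    injured <- runif(nrow(flies)) < config$day1_injury_rate
    day[injured] <- 1L
    late <- day > config$follow_up_days
    day[late] <- config$follow_up_days
    event[late] <- 0L
    data.frame(
      fly_id = sprintf("f%06d", seq_len(nrow(flies))),
      strain = flies$strain, treatment = flies$treatment,
      vial_id = flies$vial_id, day = as.integer(day), event = event,
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
}

#' Simulate a qPCR experiment (cycle thresholds plus dilution series)
#'
#' Generates one target/reference gene pair per pool. The reference-gene Ct
#' is a baseline plus a shared per-plate shift; the target-gene Ct is placed
#' so that the efficiency-corrected ratio
#' \eqn{E_{ref}^{Ct_{ref}} / E_{target}^{Ct_{target}}} equals the pool's true
#' relative quantity; independent Gaussian noise is then added per well
#' (additive on Ct = multiplicative lognormal on quantity). A ten-fold
#' dilution series with slope \eqn{-1/\log_{10} E} is generated per gene for
#' efficiency estimation.
#'
#' @param true_quantity Data frame with columns `pool_id`, `strain`,
#'   `value` (> 0, the true relative quantity per pool), or a named numeric
#'   vector (names = pool ids, strain recorded as `NA`).
#' @param config A [sim_config()] (the `qpcr` sub-list is used).
#' @param seed Integer seed.
#' @param target_gene,reference_gene Gene labels written into the table.
#' @param experiment Experiment/trait label carried through.
#' @return List with `ct` (long table: `pool_id`, `strain`, `experiment`,
#'   `gene`, `plate_id`, `tech_rep`, `ct`) and `dilution` (columns `gene`,
#'   `log10_input`, `ct`).
#' @export
simulate_qpcr <- function(true_quantity, config = sim_config(), seed = 1L,
                          target_gene = "target", reference_gene = "ref",
                          experiment = target_gene) {
  q <- config$qpcr
  if (is.numeric(true_quantity)) {
    true_quantity <- data.frame(
      pool_id = names(true_quantity) %||% sprintf(
        "p%03d", seq_along(true_quantity)
      ),
      strain = NA_character_, value = as.numeric(true_quantity),
      stringsAsFactors = FALSE
    )
  }
  if (any(!is.finite(true_quantity$value)) || any(true_quantity$value <= 0)) {
    stop("true relative quantities must be positive and finite")
  }
  n <- nrow(true_quantity)
  Et <- q$efficiency_target; Er <- q$efficiency_ref
  with_seed(seed, {
    plate <- sprintf("plate%02d", 1L + (seq_len(n) - 1L) %% q$n_plates)
    shift <- rnorm(q$n_plates, 0, q$plate_shift_sd)
    names(shift) <- sprintf("plate%02d", seq_len(q$n_plates))
    ct_ref_true <- q$ref_base_ct + shift[plate]
    ct_tgt_true <- (ct_ref_true * log(Er) - log(true_quantity$value)) / log(Et)
    reps <- q$tech_reps
    long <- data.frame(
      pool_id = rep(true_quantity$pool_id, each = 2L * reps),
      strain = rep(true_quantity$strain, each = 2L * reps),
      experiment = experiment,
      gene = rep(rep(c(target_gene, reference_gene), each = reps), n),
      plate_id = rep(plate, each = 2L * reps),
      tech_rep = rep(seq_len(reps), 2L * n),
      stringsAsFactors = FALSE
    )
    ct_true <- rep(as.vector(rbind(
      matrix(ct_tgt_true, nrow = 1), matrix(ct_ref_true, nrow = 1)
    )), each = reps)
    long$ct <- ct_true + rnorm(nrow(long), 0, q$ct_noise_sd)
    dil_points <- 0:-4
    dilution <- rbind(
      data.frame(
        gene = target_gene, log10_input = dil_points,
        ct = 12 - dil_points / log10(Et) +
          rnorm(length(dil_points), 0, q$ct_noise_sd)
      ),
      data.frame(
        gene = reference_gene, log10_input = dil_points,
        ct = 12 - dil_points / log10(Er) +
          rnorm(length(dil_points), 0, q$ct_noise_sd)
      )
    )
    list(ct = long, dilution = dilution)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic comparative dataset
#'
#' Runs the whole generator: coalescent tree, strain trait effects (split
#' into phylogenetic and strain components), a survival assay for every
#' treatment whose protection trait is listed in `trait_names` (traits named
#' `survival_<treatment>`; the true log hazard ratio of a strain is minus its
#' protection effect), and a qPCR experiment for every trait named
#' `ln_density`, `titer_*` or `expr_*`. All remaining traits are sampled
#' directly as strain effect + Gaussian replicate noise.
#'
#' @param config A [sim_config()].
#' @return List with `tree`, `truth` (effects and components, true log-HR
#'   matrix, true per-pool quantities), `survival` (data frame), `qpcr`
#'   (list with `ct` and `dilution` tables), `direct_traits` (data frame of
#'   directly sampled traits, possibly empty), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_tree(config$n_strains, config$tree_seed)
  eff <- simulate_strain_effects(
    tree, config$V_s, config$V_p, seed = config$data_seed,
    trait_names = config$trait_names
  )
  strains <- rownames(eff$effects)
  traits <- config$trait_names
  surv_traits <- grep("^survival_", traits, value = TRUE)
  out_surv <- NULL
  log_hr <- NULL
  if (length(surv_traits)) {
    tr_labels <- sub("^survival_", "", surv_traits)
    log_hr <- -eff$effects[, surv_traits, drop = FALSE]
    colnames(log_hr) <- tr_labels
    log_hr <- rbind(log_hr, matrix(
      0, 1, length(tr_labels),
      dimnames = list(config$control_label, tr_labels)
    ))
    out_surv <- simulate_survival(log_hr, config, seed = config$data_seed + 1L)
  }
  qpcr_traits <- grep("^(ln_density|titer_|expr_)", traits, value = TRUE)
  ct_tables <- list(); dil_tables <- list(); true_q <- list()
  gene_map <- qpcr_gene_map(qpcr_traits)
  for (i in seq_along(qpcr_traits)) {
    tn <- qpcr_traits[i]
    # control line included: density is zero there in truth, so simulate
    # strains only; titers/expression include the control at effect 0
    eff_vec <- eff$effects[, tn]
    if (tn != "ln_density") {
      eff_vec <- c(eff_vec, setNames(0, config$control_label))
    }
    pools <- data.frame(
      pool_id = sprintf("%s_%s_p%02d", tn, rep(names(eff_vec),
                        each = config$qpcr$n_pools),
                        rep(seq_len(config$qpcr$n_pools), length(eff_vec))),
      strain = rep(names(eff_vec), each = config$qpcr$n_pools),
      value = exp(rep(eff_vec, each = config$qpcr$n_pools)),
      stringsAsFactors = FALSE
    )
    sim <- simulate_qpcr(
      pools, config, seed = config$data_seed + 10L + i,
      target_gene = gene_map[[tn]]$target,
      reference_gene = gene_map[[tn]]$reference, experiment = tn
    )
    ct_tables[[tn]] <- sim$ct
    dil_tables[[tn]] <- sim$dilution
    true_q[[tn]] <- pools
  }
  direct <- setdiff(traits, c(surv_traits, qpcr_traits))
  direct_df <- data.frame()
  if (length(direct)) {
    direct_df <- with_seed(config$data_seed + 99L, {
      do.call(rbind, lapply(direct, function(tn) {
        nrep <- 10L
        data.frame(
          strain = rep(strains, each = nrep), trait = tn,
          replicate = rep(seq_len(nrep), length(strains)),
          value = rep(eff$effects[, tn], each = nrep) +
            rnorm(length(strains) * nrep, 0,
                  config$residual_sd[match(tn, traits)]),
          stringsAsFactors = FALSE
        )
      }))
    })
  }
  list(
    tree = tree,
    truth = list(
      effects = eff$effects, phylo = eff$phylo, strain = eff$strain,
      V_s = eff$V_s, V_p = eff$V_p, r_g = eff$r_g, log_hr = log_hr,
      true_quantities = true_q
    ),
    survival = out_surv,
    qpcr = list(
      ct = if (length(ct_tables)) do.call(rbind, c(ct_tables,
                                                   make.row.names = FALSE)),
      dilution = if (length(dil_tables)) unique(do.call(rbind, c(
        dil_tables, make.row.names = FALSE
      )))
    ),
    direct_traits = direct_df,
    config = config
  )
}

# Default target/reference gene labels per qPCR trait, mirroring the marker
# scheme of the study system: symbiont density via a bacterial gene against
# host actin, titers against a host elongation-factor gene, host expression
# against actin.
qpcr_gene_map <- function(traits) {
  out <- lapply(traits, function(tn) {
    if (tn == "ln_density") {
      list(target = "atpD", reference = "Actin5C")
    } else if (grepl("^titer_", tn)) {
      list(target = sub("^titer_", "", tn), reference = "EF1a100E")
    } else {
      list(target = sub("^expr_", "", tn), reference = "Actin5C")
    }
  })
  names(out) <- traits
  out
}
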