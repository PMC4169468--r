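#' Configuration for a full pipeline run
#'
#' Bundles the simulation design, model choices and output location of one
#' reproducible end-to-end run. One global seed is expanded into per-stage
#' seeds by a fixed counter scheme (`stage_seed = seed + 1000 * stage
#' index`, stages numbered tree = 1, data = 2, comparative = 3), so stages
#' can be rerun independently yet reproducibly.
#'
#' @param outdir Output directory (created if missing). `NULL` runs
#'   in-memory only.
#' @param seed Global integer seed.
#' @param simulation A [sim_config()]; its `tree_seed`/`data_seed` are
#'   overridden by the global seed scheme.
#' @param models Named list of [model_spec()]-argument lists (each must at
#'   least name `traits`); specs inherit the shared-ancestry matrix of the
#'   simulated tree and the run's comparative schedule. The default runs
#'   the survival + density model on the simulated traits.
#' @param prior Covariance prior family for the comparative models.
#' @param iterations,burn_in,thin Comparative MCMC schedule.
#' @param exclude_strains Strains dropped from qPCR trait assembly (e.g.
#'   unstable transmitters).
#' @param vial_as Per-vial trait construction: vial `"random"` effect
#'   (predicted) or vial `"fixed"` effect.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(outdir = NULL, seed = 1L,
                       simulation = sim_config(),
                       models = list(model1 = list(traits = c(
                         "survival_DCV", "survival_FHV", "survival_Ringer",
                         "ln_density"
                       ))),
                       prior = "px",
                       iterations = 20000L, burn_in = 5000L, thin = 5L,
                       exclude_strains = character(),
                       vial_as = "random") {
  simulation$tree_seed <- seed + 1000L
  simulation$data_seed <- seed + 2000L
  structure(list(
    outdir = outdir, seed = as.integer(seed), simulation = simulation,
    models = models, prior = prior,
    iterations = as.integer(iterations), burn_in = as.integer(burn_in),
    thin = as.integer(thin), exclude_strains = exclude_strains,
    vial_as = vial_as
  ), class = "run_config")
}

write_tsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  file
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    config[setdiff(names(config), "outdir")], tmp,
    auto_unbox = TRUE, force = TRUE, digits = NA
  )
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-to-posterior pipeline
#'
#' Executes, in dependency order: data simulation (tree, strain effects,
#' survival assay, qPCR plates); qPCR quantification (efficiencies estimated
#' from the simulated dilution series, Pfaffl correction, plate
#' normalisation of expression traits); per-treatment mixed-effect Cox fits
#' with day-1 exclusion, producing per-vial protection traits and per-strain
#' Wald tests; and the requested comparative models with genetic
#' correlations and convergence diagnostics. When `config$outdir` is set,
#' every stage output is written as TSV/JSON/newick and listed in a run
#' manifest carrying the seed and a hash of the configuration. Any stage
#' failure leaves a `FAILED` marker file next to the partial outputs.
#'
#' @param config A [run_config()].
#' @return List with `manifest`, `data` (the simulated dataset), `traits`
#'   (assembled long trait table), `cox_fits`, `strain_tests`, `posteriors`
#'   (one `"posterior_draws"` per model), `correlations` (per model, all
#'   trait pairs), `convergence` (per model).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  fail_marker <- if (!is.null(outdir)) file.path(outdir, "FAILED")
  run <- tryCatch(
    run_pipeline_stages(config),
    error = function(e) {
      if (!is.null(fail_marker)) {
        writeLines(conditionMessage(e), fail_marker)
      }
      stop(e)
    }
  )
  if (!is.null(fail_marker) && file.exists(fail_marker)) unlink(fail_marker)
  run
}

run_pipeline_stages <- function(config) {
  outdir <- config$outdir
  manifest <- list(
    seed = config$seed, config_hash = config_hash(config),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), outputs = list()
  )
  note <- function(stage, file) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], file)
  }

  # -- stage 1+2: simulation ------------------------------------------------
  ds <- simulate_dataset(config$simulation)
  if (!is.null(outdir)) {
    note("simulate", write_newick(ds$tree, file.path(outdir, "tree.nwk")))
    if (!is.null(ds$survival)) {
      note("simulate", write_tsv(ds$survival,
                                 file.path(outdir, "survival.tsv")))
    }
    if (!is.null(ds$qpcr$ct)) {
      note("simulate", write_tsv(ds$qpcr$ct, file.path(outdir, "qpcr.tsv")))
    }
    truth_file <- file.path(outdir, "ground_truth.json")
    jsonlite::write_json(
      list(effects = as.data.frame(ds$truth$effects),
           V_s = ds$truth$V_s, V_p = ds$truth$V_p),
      truth_file, digits = NA
    )
    note("simulate", truth_file)
  }

  # -- stage: qPCR quantification ------------------------------------------
  trait_tabs <- list()
  if (!is.null(ds$qpcr$ct)) {
    eff <- numeric()
    for (g in unique(ds$qpcr$dilution$gene)) {
      dl <- ds$qpcr$dilution[ds$qpcr$dilution$gene == g, ]
      eff[g] <- estimate_efficiency_dilution(dl$log10_input, dl$ct, g)$E
    }
    qt <- assemble_qpcr_traits(
      ds$qpcr$ct, efficiencies = eff,
      exclude_strains = config$exclude_strains
    )
    qt$replicate <- qt$replicate
    trait_tabs$qpcr <- qt[, c("strain", "trait", "replicate", "value")]
    if (!is.null(outdir)) {
      note("qpcr", write_tsv(qt, file.path(outdir, "qpcr_traits.tsv")))
    }
  }

  # -- stage: survival ------------------------------------------------------
  cox_fits <- list(); strain_tests <- list()
  if (!is.null(ds$survival)) {
    ctrl <- config$simulation$control_label
    for (tr in unique(ds$survival$treatment)) {
      rec <- ds$survival[ds$survival$treatment == tr, ]
      rec <- exclude_day1_deaths(rec)
      fit <- fit_cox_mixed(rec, fixed = ~ strain, reference_strain = ctrl,
                           vial_as = config$vial_as)
      cox_fits[[tr]] <- fit
      strain_tests[[tr]] <- strain_vs_control_tests(fit)
      prot <- per_vial_protection(fit, ctrl)
      prot <- prot[prot$strain != ctrl, ]
      trait_tabs[[paste0("surv_", tr)]] <- data.frame(
        strain = prot$strain, trait = paste0("survival_", tr),
        replicate = prot$vial_id, value = prot$value,
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(outdir)) {
      fits_json <- file.path(outdir, "cox_fits.json")
      jsonlite::write_json(lapply(cox_fits, function(f) list(
        coefficients = as.list(f$coefficients), se = as.list(f$se),
        frailty_variance = f$frailty_variance,
        loglik = f$loglik, n = f$n, n_events = f$n_events
      )), fits_json, auto_unbox = TRUE, digits = NA)
      note("survival", fits_json)
    }
  }
  if (nrow(ds$direct_traits %||% data.frame())) {
    trait_tabs$direct <- ds$direct_traits[, c("strain", "trait",
                                              "replicate", "value")]
  }
  traits <- do.call(rbind, c(trait_tabs, make.row.names = FALSE))
  if (!is.null(outdir)) {
    note("survival", write_tsv(traits, file.path(outdir, "traits.tsv")))
  }

  # -- stage: comparative ---------------------------------------------------
  A <- shared_ancestry_matrix(ds$tree)
  posteriors <- list(); correlations <- list(); convergence <- list()
  for (nm in names(config$models)) {
    args <- config$models[[nm]]
    args$A <- args$A %||% A
    args$prior <- args$prior %||% config$prior
    args$iterations <- args$iterations %||% config$iterations
    args$burn_in <- args$burn_in %||% config$burn_in
    args$thin <- args$thin %||% config$thin
    args$seed <- args$seed %||% (config$seed + 3000L)
    spec <- do.call(model_spec, args)
    present <- spec$traits %in% unique(traits$trait)
    if (!all(present)) {
      warning("model '", nm, "' skipped: missing trait(s) ",
              paste(spec$traits[!present], collapse = ", "))
      next
    }
    post <- fit_multiresponse(traits, spec)
    posteriors[[nm]] <- post
    convergence[[nm]] <- convergence_report(post)
    prs <- utils::combn(spec$traits, 2, simplify = FALSE)
    comp <- if (spec$include_strain_effect) "strain" else "phylo"
    correlations[[nm]] <- do.call(rbind, lapply(prs, function(pr) {
      g <- genetic_correlation(post, pr[1], pr[2], component = comp)
      data.frame(model = nm, trait1 = pr[1], trait2 = pr[2],
                 component = comp, mean = g$mean,
                 hpd_lower = g$hpd[1], hpd_upper = g$hpd[2],
                 stringsAsFactors = FALSE)
    }))
  }
  correlations_df <- do.call(rbind, c(correlations, make.row.names = FALSE))
  if (!is.null(outdir) && !is.null(correlations_df)) {
    note("comparative", write_tsv(
      correlations_df, file.path(outdir, "genetic_correlations.tsv")
    ))
    post_file <- file.path(outdir, "posterior_summary.json")
    jsonlite::write_json(list(
      correlations = correlations_df,
      convergence = lapply(convergence, function(cv) list(
        pass = cv$pass, worst_lag1 = max(abs(cv$table$lag1_autocorr),
                                         na.rm = TRUE)
      ))
    ), post_file, auto_unbox = TRUE, digits = NA)
    note("comparative", post_file)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(
    manifest = manifest, data = ds, traits = traits, cox_fits = cox_fits,
    strain_tests = strain_tests, posteriors = posteriors,
    correlations = correlations_df, convergence = convergence,
    config = config
  )
}

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Write a markdown summary report for a pipeline run
#'
#' Tables of per-strain protection (mean per-vial trait, Wald significance
#' stars vs the symbiont-free control), the genetic-correlation estimates
#' with HPD intervals, a strain-level density-vs-protection summary, and
#' convergence diagnostics. A visible warning banner is added when any
#' comparative chain fails its convergence check.
#'
#' @param run Result of [run_pipeline()].
#' @param file Output path; defaults to `report.md` in the run's outdir (or
#'   a tempfile for in-memory runs).
#' @return The path, invisibly.
#' @export
make_report <- function(run, file = NULL) {
  file <- file %||% file.path(
    run$config$outdir %||% tempdir(), "report.md"
  )
  lines <- c("# Symbiont comparative pipeline report", "",
             sprintf("Seed %d, config hash `%s`.", run$manifest$seed,
                     run$manifest$config_hash), "")
  conv_fail <- any(!vapply(run$convergence, `[[`, logical(1), "pass"))
  if (length(run$convergence) && conv_fail) {
    lines <- c(lines,
               "> **WARNING: one or more MCMC chains failed the",
               "> autocorrelation convergence check; estimates below may be",
               "> unreliable.**", "")
  }
  for (tr in names(run$strain_tests)) {
    st <- run$strain_tests[[tr]]
    tt <- run$traits[run$traits$trait == paste0("survival_", tr), ]
    mn <- tapply(tt$value, tt$strain, mean)
    st$strain <- sub("^strain", "", st$coefficient)
    lines <- c(lines, sprintf("## Protection, %s treatment", tr), "",
               "| strain | mean -ln(HR) | p (Wald) | |",
               "|---|---|---|---|",
               sprintf("| %s | %.3f | %.3g | %s |",
                       st$strain, mn[st$strain], st$p, sig_stars(st$p)),
               "")
  }
  if (!is.null(run$correlations)) {
    co <- run$correlations
    lines <- c(lines, "## Genetic correlations", "",
               "| model | traits | component | r_g | 95% HPD |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s ~ %s | %s | %.3f | [%.3f, %.3f] |",
                       co$model, co$trait1, co$trait2, co$component,
                       co$mean, co$hpd_lower, co$hpd_upper),
               "")
  }
  dens <- run$traits[run$traits$trait == "ln_density", ]
  prot <- run$traits[run$traits$trait == "survival_DCV", ]
  if (nrow(dens) && nrow(prot)) {
    md <- tapply(dens$value, dens$strain, mean)
    mp <- tapply(prot$value, prot$strain, mean)
    common <- intersect(names(md), names(mp))
    lines <- c(lines, "## Density vs DCV protection (strain means)", "",
               "| strain | mean ln density | mean protection |",
               "|---|---|---|",
               sprintf("| %s | %.3f | %.3f |", common, md[common],
                       mp[common]),
               "",
               sprintf("Pearson correlation of strain means: %.3f",
                       if (length(common) > 2) {
                         stats::cor(md[common], mp[common])
                       } else NA_real_),
               "")
  }
  for (nm in names(run$convergence)) {
    cv <- run$convergence[[nm]]
    lines <- c(lines, sprintf(
      "Convergence (%s): %s; worst |lag-1 autocorrelation| %.3f", nm,
      if (cv$pass) "pass" else "FAIL",
      max(abs(cv$table$lag1_autocorr), na.rm = TRUE)
    ))
  }
  writeLines(lines, file)
  invisible(file)
}
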