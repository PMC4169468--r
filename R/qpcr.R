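#' Average technical replicates on the Ct scale
#'
#' Collapses a long Ct table to one Ct per (pool, gene) by the arithmetic
#' mean across technical replicates. Averaging is done on the Ct scale (the
#' dominant qPCR convention; the alternative, averaging back-transformed
#' quantities, differs only at second order in the replicate spread).
#' Replicate pairs whose Ct spread exceeds `discordance_threshold` cycles
#' are kept but flagged, since a large spread usually indicates a pipetting
#' or amplification problem in one well.
#'
#' @param measurements Data frame with columns `pool_id`, `gene`, `tech_rep`,
#'   `ct`, plus any metadata columns (`strain`, `plate_id`, `experiment`,
#'   ...) which are carried through (taken from the first replicate).
#' @param discordance_threshold Ct spread (max - min) above which a
#'   (pool, gene) is flagged, in cycles.
#' @return Data frame with one row per (pool, gene): the metadata columns,
#'   `ct` (mean), `n_reps`, and logical `discordant`.
#' @export
average_technical_replicates <- function(measurements,
                                         discordance_threshold = 1) {
  need <- c("pool_id", "gene", "ct")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns pool_id, gene, ct")
  }
  if (any(!is.finite(measurements$ct)) || any(measurements$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  key <- interaction(measurements$pool_id, measurements$gene, drop = TRUE)
  idx <- split(seq_len(nrow(measurements)), key)
  meta_cols <- setdiff(names(measurements), c("tech_rep", "ct"))
  rows <- lapply(idx, function(i) {
    out <- measurements[i[1], meta_cols, drop = FALSE]
    out$ct <- mean(measurements$ct[i])
    out$n_reps <- length(i)
    out$discordant <- diff(range(measurements$ct[i])) > discordance_threshold
    out
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (any(out$discordant)) {
    message(sum(out$discordant),
            " (pool, gene) Ct pairs exceed the discordance threshold")
  }
  out
}

#' Efficiency-corrected relative quantity (Pfaffl method)
#'
#' Ratio of target to reference template implied by the two cycle
#' thresholds, correcting for unequal amplification efficiencies:
#' \deqn{ratio = E_{ref}^{Ct_{ref}} / E_{target}^{Ct_{target}}.}
#' With both efficiencies equal to 2 (perfect doubling) this reduces to the
#' textbook \eqn{2^{Ct_{ref} - Ct_{target}}}.
#'
#' @param ct_target,ct_ref Cycle thresholds (finite).
#' @param E_target,E_ref Amplification efficiencies per cycle, in (1, 2.2].
#' @return The dimensionless relative quantity (vectorised).
#' @examples
#' relative_quantity(18, 21) # 2^3 = 8
#' @export
relative_quantity <- function(ct_target, ct_ref, E_target = 2, E_ref = 2) {
  check_efficiency(E_target)
  check_efficiency(E_ref)
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref))) {
    stop("cycle thresholds must be finite")
  }
  exp(ct_ref * log(E_ref) - ct_target * log(E_target))
}

check_efficiency <- function(E) {
  if (any(!is.finite(E)) || any(E <= 1) || any(E > 2.2)) {
    stop("amplification efficiency must lie in (1, 2.2]")
  }
  invisible(E)
}

#' Estimate amplification efficiency from a dilution series
#'
#' Least-squares slope of Ct against log10(input); the per-cycle efficiency
#' is \eqn{E = 10^{-1/slope}}. Perfect doubling (E = 2) corresponds to a
#' slope of \eqn{-1/\log_{10} 2 \approx -3.3219} cycles per decade.
#'
#' @param log10_input Base-10 log of template input (at least 3 points
#'   spanning at least 2 orders of magnitude).
#' @param ct Observed cycle thresholds.
#' @param gene Optional gene label stored on the estimate.
#' @return List of class `"efficiency_estimate"` with `gene`, `E`, `slope`,
#'   `r_squared`, `source = "dilution series"`.
#' @export
estimate_efficiency_dilution <- function(log10_input, ct, gene = NA) {
  if (length(log10_input) != length(ct)) stop("input lengths differ")
  if (length(ct) < 3) stop("need >= 3 dilution points")
  if (diff(range(log10_input)) < 2) {
    stop("dilution series must span >= 2 orders of magnitude")
  }
  fit <- lm(ct ~ log10_input)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("dilution series is not monotone decreasing in Ct (slope >= 0)")
  }
  E <- 10^(-1 / slope)
  check_efficiency(E)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(gene = gene, E = E, slope = slope,
         r_squared = r2, source = "dilution series"),
    class = "efficiency_estimate"
  )
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf(
    "qPCR efficiency estimate (%s): E = %.4f (slope %.4f, R^2 %.4f)\n",
    if (is.na(x$gene)) "unnamed gene" else x$gene, x$E, x$slope, x$r_squared
  ))
  invisible(x)
}

#' Rescale a Ct to the perfect-doubling (E = 2) scale
#'
#' A gene amplifying with efficiency E reaches threshold after `ct` cycles
#' starting from a quantity proportional to \eqn{E^{-ct}}; the corrected Ct
#' is the number of perfect doublings implying the same quantity:
#' \deqn{Ct' = Ct \cdot \log_2 E,} so that \eqn{2^{-Ct'} = E^{-Ct}}. E = 2
#' is the identity.
#'
#' @param ct Cycle threshold(s).
#' @param E Amplification efficiency in (1, 2.2].
#' @return Corrected Ct on the doubling scale.
#' @export
efficiency_correct_ct <- function(ct, E) {
  check_efficiency(E)
  ct * log2(E)
}

#' Normalise values across plates (per-plate z-scores)
#'
#' Removes plate batch effects by centring and scaling within each plate:
#' \eqn{z_j = (x_j - \bar{x}_i) / s_i} for sample j on plate i. After
#' normalisation every plate has mean 0 and SD 1, so the output is invariant
#' to any per-plate additive shift or positive rescaling.
#'
#' @param values Numeric vector.
#' @param plate_ids Plate label per value (>= 2 values per plate).
#' @return Normalised vector, same order.
#' @export
plate_normalize <- function(values, plate_ids) {
  if (length(values) != length(plate_ids)) stop("input lengths differ")
  out <- numeric(length(values))
  for (pl in unique(plate_ids)) {
    i <- which(plate_ids == pl)
    if (length(i) < 2) {
      stop(sprintf("plate '%s' has fewer than 2 values", pl))
    }
    s <- sd(values[i])
    if (!is.finite(s) || s == 0) {
      stop(sprintf("plate '%s' has zero variance", pl))
    }
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

#' Assemble trait values from a raw Ct table
#'
#' The full quantification path of the pipeline: technical replicates are
#' averaged on the Ct scale; the target-gene Ct is efficiency-corrected to
#' the doubling scale when its efficiency differs from 2 (the reference is
#' left uncorrected when its efficiency is 2, the usual case for a validated
#' reference gene); the Pfaffl ratio is formed per pool and ln-transformed;
#' and, for traits flagged in `plate_normalize_traits` (host gene
#' expression), the ln values are plate-normalised per gene. Pools missing
#' their reference gene are dropped with a warning. Strains listed in
#' `exclude_strains` (e.g. lines with unstable symbiont transmission) are
#' removed before trait assembly.
#'
#' @param ct_table Long Ct table with columns `pool_id`, `strain`,
#'   `experiment` (trait label), `gene`, `plate_id`, `tech_rep`, `ct`.
#' @param gene_map Named list mapping each trait label to
#'   `list(target =, reference =)` gene names; defaults to
#'   the mapping used by the synthetic generator (see [simulate_dataset()]).
#' @param efficiencies Named numeric vector of per-gene amplification
#'   efficiencies; genes not listed are taken as E = 2.
#' @param plate_normalize_traits Character vector of trait labels to
#'   plate-normalise (on the ln scale); default: every `expr_*` trait.
#' @param exclude_strains Strains dropped before assembly.
#' @return Data frame with columns `strain`, `trait`, `replicate`
#'   (pool id), `value` (ln relative quantity, plate-normalised where
#'   requested), `plate_id`.
#' @export
assemble_qpcr_traits <- function(ct_table,
                                 gene_map = NULL,
                                 efficiencies = NULL,
                                 plate_normalize_traits = NULL,
                                 exclude_strains = character()) {
  need <- c("pool_id", "strain", "experiment", "gene", "plate_id",
            "tech_rep", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns ", paste(need, collapse = ", "))
  }
  ct_table <- ct_table[!(ct_table$strain %in% exclude_strains), ]
  traits <- unique(ct_table$experiment)
  if (is.null(gene_map)) gene_map <- qpcr_gene_map(traits)
  if (is.null(plate_normalize_traits)) {
    plate_normalize_traits <- grep("^expr_", traits, value = TRUE)
  }
  eff_of <- function(gene) {
    if (!is.null(efficiencies) && gene %in% names(efficiencies)) {
      unname(efficiencies[gene])
    } else 2
  }
  out <- list()
  for (tn in traits) {
    sub <- ct_table[ct_table$experiment == tn, ]
    genes <- gene_map[[tn]]
    if (is.null(genes)) stop("no gene mapping for trait '", tn, "'")
    avg <- average_technical_replicates(sub)
    tgt <- avg[avg$gene == genes$target, ]
    ref <- avg[avg$gene == genes$reference, ]
    m <- match(tgt$pool_id, ref$pool_id)
    if (anyNA(m)) {
      warning(sum(is.na(m)), " pool(s) of trait '", tn,
              "' lack the reference gene and were dropped")
      tgt <- tgt[!is.na(m), ]
      m <- m[!is.na(m)]
    }
    Et <- eff_of(genes$target); Er <- eff_of(genes$reference)
    ct_t <- tgt$ct
    ct_r <- ref$ct[m]
    # correction to the doubling scale only where the efficiency calls for it
    if (Et != 2) ct_t <- efficiency_correct_ct(ct_t, Et)
    if (Er != 2) ct_r <- efficiency_correct_ct(ct_r, Er)
    value <- log(relative_quantity(ct_t, ct_r, 2, 2))
    df <- data.frame(
      strain = tgt$strain, trait = tn, replicate = tgt$pool_id,
      value = value, plate_id = tgt$plate_id, stringsAsFactors = FALSE
    )
    if (tn %in% plate_normalize_traits) {
      df$value <- plate_normalize(df$value, df$plate_id)
    }
    out[[tn]] <- df
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (any(!is.finite(res$value))) {
    stop("non-finite ln relative quantity produced; check input Cts")
  }
  res
}
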