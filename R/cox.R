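#' Remove day-1 deaths attributed to the inoculation injury
#'
#' Deaths recorded on the day after infection are attributed to the stabbing
#' injury rather than to the infection and are discarded before fitting.
#' Censored day-1 records (possible only in degenerate designs) are kept.
#'
#' @param records Survival data frame with columns `day` and `event`.
#' @return The filtered data frame; the number of removals is reported via
#'   `message()`.
#' @export
exclude_day1_deaths <- function(records) {
  drop <- records$event == 1 & records$day == 1
  if (any(drop)) {
    message(sum(drop), " day-1 death(s) excluded as injury mortality")
  }
  records[!drop, , drop = FALSE]
}

# ---- Efron/Breslow partial likelihood machinery -------------------------

# Observed-information parameterisation: returns loglik, gradient and the
# *negative* Hessian (positive semi-definite information matrix) of the
# partial likelihood at linear predictor eta = X %*% theta.
# X: sparse (Matrix) or dense design, day: integer day, event: 0/1.
efron_derivs <- function(X, day, event, theta, ties = "efron",
                         want_hessian = TRUE) {
  eta <- as.numeric(X %*% theta)
  w <- exp(eta)
  p <- ncol(X)
  days_desc <- sort(unique(day), decreasing = TRUE)
  loglik <- 0
  grad <- numeric(p)
  info <- if (want_hessian) matrix(0, p, p) else NULL
  A0 <- 0; A1 <- numeric(p)
  A2 <- if (want_hessian) matrix(0, p, p) else NULL
  for (d in days_desc) {
    i <- which(day == d)
    Xi <- X[i, , drop = FALSE]
    wi <- w[i]
    A0 <- A0 + sum(wi)
    A1 <- A1 + as.numeric(Matrix::crossprod(Xi, wi))
    if (want_hessian) {
      A2 <- A2 + as.matrix(Matrix::crossprod(Xi, Xi * wi))
    }
    dd <- i[event[i] == 1]
    m <- length(dd)
    if (m == 0) next
    Xd <- X[dd, , drop = FALSE]
    wd <- w[dd]
    B0 <- sum(wd)
    B1 <- as.numeric(Matrix::crossprod(Xd, wd))
    B2 <- if (want_hessian) as.matrix(Matrix::crossprod(Xd, Xd * wd))
    loglik <- loglik + sum(eta[dd])
    grad <- grad + as.numeric(Matrix::colSums(Xd))
    fr <- if (ties == "efron") (seq_len(m) - 1) / m else rep(0, m)
    for (f in fr) {
      phi <- A0 - f * B0
      loglik <- loglik - log(phi)
      u <- (A1 - f * B1) / phi
      grad <- grad - u
      if (want_hessian) {
        info <- info + (A2 - f * B2) / phi - tcrossprod(u)
      }
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

# Newton-Raphson for the (penalized) partial likelihood. pen is a vector of
# ridge penalties per column (0 for fixed effects, 1/sigma2 for frailties).
cox_newton <- function(X, day, event, pen, theta = NULL, ties = "efron",
                       tol = 1e-9, max_iter = 50) {
  p <- ncol(X)
  if (p == 0L) { # null model: nothing to maximise
    d <- efron_derivs(X, day, event, numeric(0), ties, want_hessian = FALSE)
    return(list(theta = numeric(0), loglik = d$loglik, ppl = d$loglik,
                grad = numeric(0), info = matrix(0, 0, 0), iterations = 0L))
  }
  if (is.null(theta)) theta <- numeric(p)
  ppl_of <- function(d, th) d$loglik - sum(pen * th^2) / 2
  d <- efron_derivs(X, day, event, theta, ties)
  ppl <- ppl_of(d, theta)
  for (it in seq_len(max_iter)) {
    g <- d$grad - pen * theta
    H <- d$info + diag(pen, p)
    step <- tryCatch(
      solve(H + diag(1e-10, p), g),
      error = function(e) solve(H + diag(1e-6 + 1e-6 * max(diag(H)), p), g)
    )
    # step-halving on the penalized objective
    ok <- FALSE
    for (h in 0:30) {
      theta_new <- theta + step / 2^h
      d_new <- efron_derivs(X, day, event, theta_new, ties)
      ppl_new <- ppl_of(d_new, theta_new)
      if (is.finite(ppl_new) && ppl_new >= ppl - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    converged <- abs(ppl_new - ppl) < tol && max(abs(g)) < 1e-5
    theta <- theta_new; d <- d_new; ppl <- ppl_new
    if (converged) break
  }
  list(theta = theta, loglik = d$loglik, ppl = ppl, grad = d$grad,
       info = d$info, iterations = it)
}

# ---- model construction -------------------------------------------------

build_cox_design <- function(records, fixed, reference_strain = NULL) {
  vars <- all.vars(fixed)
  for (v in vars) {
    if (!v %in% names(records)) stop("column '", v, "' not in records")
    if (!is.factor(records[[v]]) && is.character(records[[v]])) {
      records[[v]] <- factor(records[[v]])
    }
  }
  if (!is.null(reference_strain) && "strain" %in% vars) {
    if (!reference_strain %in% levels(records$strain)) {
      stop("reference strain '", reference_strain, "' not present")
    }
    records$strain <- stats::relevel(records$strain, ref = reference_strain)
  }
  single <- vars[vapply(vars, function(v) {
    is.factor(records[[v]]) && nlevels(records[[v]]) < 2
  }, logical(1))]
  if (length(vars) == 0L || length(single) == length(vars)) {
    # null model: the Cox partial likelihood has no intercept
    return(list(X = Matrix::Matrix(0, nrow(records), 0, sparse = TRUE),
                records = records))
  }
  mm <- model.matrix(fixed, records)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  list(X = Matrix::Matrix(mm, sparse = TRUE), records = records)
}

# sparse one-column-per-level indicator (robust to single-level factors)
indicator_matrix <- function(f) {
  f <- factor(f)
  Z <- Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f))
  )
  colnames(Z) <- levels(f)
  Z
}

#' Fit a mixed-effect proportional-hazards model with vial frailty
#'
#' Hand-rolled Cox model for daily-census survival data: fixed effects
#' (typically the strain factor, with the symbiont-free line as reference)
#' plus a Gaussian random effect per replicate vial on the log hazard.
#' Heavy daily ties are handled by the Efron approximation by default.
#'
#' Estimation maximises the penalized partial likelihood
#' \eqn{PL(\beta, b) - b'b / 2\sigma^2} over coefficients by Newton-Raphson,
#' with the frailty variance \eqn{\sigma^2} optimised in an outer loop on a
#' Laplace-approximate integrated likelihood
#' \eqn{\hat{PPL} - \tfrac{q}{2}\log\sigma^2 -
#'   \tfrac12 \log\det(H_{bb} + I/\sigma^2)}.
#'
#' @param records Data frame with columns `day`, `event`, the fixed-effect
#'   variables, and `vial_id`. Apply [exclude_day1_deaths()] first.
#' @param fixed One-sided formula of fixed effects, e.g. `~ strain` or
#'   `~ strain * treatment`.
#' @param reference_strain Level to use as the reference (coefficient 0).
#' @param vial_as `"random"` (Gaussian frailty, the default) or `"fixed"`
#'   (one unpenalised log-HR per non-reference vial; `fixed` is ignored and
#'   the reference strain's vials form the baseline).
#' @param frailty_variance `NULL` to estimate; a number to hold fixed
#'   (0 gives an ordinary fixed-effects Cox fit).
#' @param ties `"efron"` or `"breslow"`.
#' @param tol Outer-optimisation tolerance on log variance.
#' @param max_outer Maximum outer iterations (function evaluations).
#' @return Object of class `"cox_fit"`: `coefficients`, `se`, `vcov`,
#'   `frailty_variance`, `vial_effects`, `loglik` (list with `partial`,
#'   `penalized`, `integrated`), `n`, `n_events`, `flags` (non-identifiable
#'   coefficients), plus bookkeeping used by [per_vial_protection()].
#' @export
fit_cox_mixed <- function(records, fixed = ~ strain,
                          reference_strain = NULL,
                          vial_as = c("random", "fixed"),
                          frailty_variance = NULL,
                          ties = c("efron", "breslow"),
                          tol = 1e-8, max_outer = 200) {
  vial_as <- match.arg(vial_as)
  ties <- match.arg(ties)
  if (!all(c("day", "event") %in% names(records))) {
    stop("records must have `day` and `event` columns")
  }
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(records$event) < 1) stop("no events in the data; cannot fit")
  records <- droplevels(records)

  if (vial_as == "fixed") {
    return(fit_cox_vial_fixed(records, reference_strain, ties))
  }

  des <- build_cox_design(records, fixed, reference_strain)
  X <- des$X
  records <- des$records
  p_fixed <- ncol(X)
  has_vial <- "vial_id" %in% names(records)
  if (!has_vial) stop("records must have a `vial_id` column")
  Z <- indicator_matrix(records$vial_id)
  q <- ncol(Z)
  W <- cbind(X, Z)
  day <- records$day; event <- records$event

  fit_at <- function(sigma2, theta0 = NULL) {
    pen <- c(rep(0, p_fixed), rep(if (sigma2 > 0) 1 / sigma2 else Inf, q))
    if (sigma2 <= 0) {
      # frailty variance 0: vial effects pinned at 0, plain Cox on X
      nf <- cox_newton(X, day, event, rep(0, p_fixed), theta0[seq_len(p_fixed)],
                       ties)
      return(list(theta = c(nf$theta, numeric(q)), loglik = nf$loglik,
                  ppl = nf$ppl, info = nf$info, sigma2 = 0))
    }
    nf <- cox_newton(W, day, event, pen, theta0, ties)
    nf$sigma2 <- sigma2
    nf
  }

  ilik <- function(log_s2, theta0 = NULL) {
    s2 <- exp(log_s2)
    nf <- fit_at(s2, theta0)
    Hbb <- nf$info[p_fixed + seq_len(q), p_fixed + seq_len(q), drop = FALSE] +
      diag(1 / s2, q)
    ld <- determinant(Hbb, logarithm = TRUE)$modulus
    as.numeric(nf$ppl - q / 2 * log(s2) - ld / 2)
  }

  if (is.null(frailty_variance)) {
    opt <- optimize(ilik, interval = log(c(1e-6, 25)), maximum = TRUE,
                    tol = tol * 10)
    sigma2 <- exp(opt$maximum)
    # collapse to the boundary when the optimum sits at effectively zero
    if (sigma2 < 2e-6 || ilik(log(1e-8)) >= opt$objective - 1e-8) sigma2 <- 0
    integrated <- if (sigma2 > 0) opt$objective else {
      f0 <- fit_at(0); f0$loglik
    }
  } else {
    if (frailty_variance < 0) stop("frailty_variance must be >= 0")
    sigma2 <- frailty_variance
    integrated <- if (sigma2 > 0) ilik(log(sigma2)) else NULL
  }

  nf <- fit_at(sigma2)
  theta <- nf$theta
  beta <- theta[seq_len(p_fixed)]
  names(beta) <- colnames(X)
  b <- theta[p_fixed + seq_len(q)]
  names(b) <- colnames(Z)
  if (sigma2 == 0) {
    # info from the plain fixed-effects fit is p_fixed x p_fixed
    V_full <- matrix(0, p_fixed + q, p_fixed + q)
    if (p_fixed > 0) {
      V_full[seq_len(p_fixed), seq_len(p_fixed)] <-
        solve(nf$info + diag(1e-12, p_fixed))
    }
  } else {
    Hp <- nf$info + diag(c(rep(0, p_fixed), rep(1 / sigma2, q)),
                         p_fixed + q)
    V_full <- solve(Hp)
  }
  se <- sqrt(pmax(diag(V_full)[seq_len(p_fixed)], 0))
  names(se) <- names(beta)
  flags <- abs(beta) > 15 | se > 100
  se[flags] <- Inf
  if (any(flags)) {
    message("non-identifiable coefficient(s): ",
            paste(names(beta)[flags], collapse = ", "))
  }
  vial_strain <- records[!duplicated(records$vial_id),
                         intersect(c("vial_id", "strain", "treatment"),
                                   names(records)), drop = FALSE]
  structure(list(
    coefficients = beta, se = se,
    vcov = V_full[seq_len(p_fixed), seq_len(p_fixed), drop = FALSE],
    frailty_variance = sigma2, vial_effects = b,
    loglik = list(partial = nf$loglik, penalized = nf$ppl,
                  integrated = if (sigma2 > 0) integrated else nf$loglik),
    n = nrow(records), n_events = sum(records$event),
    fixed = fixed, ties = ties, vial_as = "random",
    reference_strain = reference_strain %||% {
      if ("strain" %in% names(records)) levels(records$strain)[1] else NULL
    },
    vial_strain = vial_strain, flags = flags
  ), class = "cox_fit")
}

# Vial-as-fixed-effect variant: one unpenalised coefficient per vial of a
# non-reference strain; vials of the reference strain form the baseline.
fit_cox_vial_fixed <- function(records, reference_strain, ties) {
  if (is.null(reference_strain)) stop("vial_as = 'fixed' needs a reference strain")
  if (!"strain" %in% names(records)) stop("records must have a strain column")
  is_ref <- records$strain == reference_strain
  keep <- levels(factor(records$vial_id[!is_ref]))
  mm <- indicator_matrix(records$vial_id)
  X <- mm[, keep, drop = FALSE]
  nf <- cox_newton(X, records$day, records$event, rep(0, ncol(X)),
                   ties = ties)
  beta <- nf$theta
  names(beta) <- keep
  V <- solve(nf$info + diag(1e-12, ncol(X)))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- keep
  flags <- abs(beta) > 15 | se > 100
  se[flags] <- Inf
  vial_strain <- records[!duplicated(records$vial_id),
                         intersect(c("vial_id", "strain", "treatment"),
                                   names(records)), drop = FALSE]
  structure(list(
    coefficients = beta, se = se, vcov = V,
    frailty_variance = NA_real_, vial_effects = NULL,
    loglik = list(partial = nf$loglik, penalized = nf$ppl,
                  integrated = nf$loglik),
    n = nrow(records), n_events = sum(records$event),
    fixed = ~vial, ties = ties, vial_as = "fixed",
    reference_strain = reference_strain,
    vial_strain = vial_strain, flags = flags
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Mixed-effect Cox fit (%s ties): %d records, %d events\n",
    x$ties, x$n, x$n_events
  ))
  if (!is.na(x$frailty_variance)) {
    cat(sprintf("vial frailty variance: %.4f\n", x$frailty_variance))
  }
  cat(sprintf("%d fixed-effect coefficient(s); reference: %s\n",
              length(x$coefficients), x$reference_strain %||% "<none>"))
  invisible(x)
}

#' Likelihood ratio test between two nested Cox fits
#'
#' Twice the log-likelihood difference against the chi-square with degrees
#' of freedom equal to the difference in fixed-effect count. When both fits
#' carry an estimated frailty the Laplace-integrated likelihoods are
#' compared; otherwise the partial likelihoods.
#'
#' @param full,reduced `"cox_fit"` objects on the same records, reduced
#'   nested in full.
#' @return List with `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (!inherits(full, "cox_fit") || !inherits(reduced, "cox_fit")) {
    stop("both arguments must be cox_fit objects")
  }
  if (full$n != reduced$n || full$n_events != reduced$n_events) {
    stop("fits are not on the same records")
  }
  df <- length(full$coefficients) - length(reduced$coefficients)
  if (df < 0) stop("`reduced` has more coefficients than `full`; not nested")
  use <- if (!is.na(full$frailty_variance) && full$frailty_variance > 0 &&
             !is.na(reduced$frailty_variance) && reduced$frailty_variance > 0) {
    "integrated"
  } else "partial"
  chi2 <- 2 * (full$loglik[[use]] - reduced$loglik[[use]])
  if (chi2 < 0 && chi2 > -1e-6) chi2 <- 0
  if (chi2 < 0) stop("full model has lower likelihood; models not nested?")
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Per-vial protection traits from a Cox fit
#'
#' The protection trait of a vial is the negative log hazard ratio of its
#' flies versus the symbiont-free reference: \eqn{-(\beta_s + b_v)} with the
#' strain fixed effect \eqn{\beta_s} (0 for the reference strain) and the
#' predicted vial effect \eqn{b_v}. Larger values mean better survival. For
#' a vial-as-fixed fit the per-vial coefficient is used directly.
#'
#' @param fit A `"cox_fit"` from a model with `strain` fixed effects (or a
#'   vial-as-fixed fit).
#' @param reference_strain Reference strain label; defaults to the one
#'   recorded in the fit.
#' @return Data frame with `vial_id`, `strain`, `treatment` (if recorded),
#'   `value`.
#' @export
per_vial_protection <- function(fit, reference_strain = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  reference_strain <- reference_strain %||% fit$reference_strain
  vs <- fit$vial_strain
  if (fit$vial_as == "fixed") {
    value <- numeric(nrow(vs))
    nonref <- vs$strain != reference_strain
    miss <- setdiff(vs$vial_id[nonref], names(fit$coefficients))
    if (length(miss)) stop("vial(s) absent from fit: ",
                           paste(miss, collapse = ", "))
    value[nonref] <- -fit$coefficients[vs$vial_id[nonref]]
  } else {
    if (is.null(fit$vial_effects)) stop("fit has no vial effects")
    miss <- setdiff(vs$vial_id, names(fit$vial_effects))
    if (length(miss)) stop("vial(s) absent from fit: ",
                           paste(miss, collapse = ", "))
    beta_of <- function(s) {
      if (s == reference_strain) return(0)
      nm <- paste0("strain", s)
      if (!nm %in% names(fit$coefficients)) {
        stop("strain '", s, "' has no coefficient in the fit")
      }
      unname(fit$coefficients[nm])
    }
    beta_s <- vapply(vs$strain, beta_of, numeric(1))
    value <- -(beta_s + fit$vial_effects[vs$vial_id])
  }
  out <- data.frame(vial_id = vs$vial_id, strain = vs$strain,
                    value = unname(value), stringsAsFactors = FALSE)
  if ("treatment" %in% names(vs)) out$treatment <- vs$treatment
  rownames(out) <- NULL
  out
}

#' Per-strain Wald tests against the reference line
#'
#' \eqn{z = \beta_s / SE(\beta_s)}, two-sided p, no multiplicity correction
#' (these are the per-strain significance stars of a protection figure, not
#' a family-wise procedure). Coefficients flagged non-identifiable (infinite
#' SE) get p = 1 and `flagged = TRUE`.
#'
#' @param fit A `"cox_fit"` with strain fixed effects.
#' @return Data frame with `coefficient`, `estimate`, `se`, `z`, `p`,
#'   `flagged`.
#' @export
strain_vs_control_tests <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  beta <- fit$coefficients
  se <- fit$se
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  flagged <- !is.finite(se)
  p[flagged] <- 1
  z[flagged] <- NA_real_
  data.frame(
    coefficient = names(beta), estimate = unname(beta), se = unname(se),
    z = unname(z), p = unname(p), flagged = unname(flagged),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
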