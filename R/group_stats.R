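#' One-way ANOVA on (ln-transformed) group samples
#'
#' Standard fixed-effects one-way decomposition, intended for ln relative
#' quantities (density, titer) which upstream quantification guarantees to
#' be finite. Assumes homoscedasticity.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 1)) stop("every group needs >= 1 value")
  if (any(!is.finite(values))) stop("values must be finite")
  if (all(tapply(values, groups, function(v) diff(range(v)) == 0))) {
    stop("zero within-group variance: F statistic undefined")
  }
  a <- anova(lm(values ~ groups))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p = a$`Pr(>F)`[1])
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Per-group t statistics against the control with the pooled within-group
#' variance, adjusted family-wise over the k comparisons via the
#' multivariate-t distribution of the maximum statistic (single-step
#' Dunnett), evaluated by seeded Monte-Carlo integration (there is no closed
#' form). Backed by \pkg{multcomp}. Two-sided.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param control Label of the control group.
#' @param seed Integer seed for the Monte-Carlo evaluation of the
#'   multivariate-t probabilities.
#' @return Data frame with `group`, `estimate` (difference vs control),
#'   `se`, `t`, `p_adjusted`, `p_unadjusted`.
#' @export
dunnett_many_to_one <- function(values, groups, control, seed = 1L) {
  groups <- factor(groups)
  if (!control %in% levels(groups)) {
    stop("control group '", control, "' not found")
  }
  groups <- stats::relevel(groups, ref = control)
  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  smry <- with_seed(seed, summary(glt))
  est <- unname(coef(glt))
  se <- unname(sqrt(diag(vcov(glt))))
  tval <- est / se
  df <- fit$df.residual
  data.frame(
    group = setdiff(levels(groups), control),
    estimate = est, se = se, t = tval,
    p_adjusted = as.numeric(smry$test$pvalues),
    p_unadjusted = 2 * pt(-abs(tval), df),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tukey honest significant difference test with compact letter display
#'
#' All-pairs comparisons based on the studentized range, plus the usual
#' compact letter display (groups sharing no letter differ at `alpha`).
#' Backed by \pkg{multcomp}.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups).
#' @param alpha Significance level for the letter display.
#' @param seed Integer seed for the multivariate-t evaluation.
#' @return List with `pairs` (data frame: `pair`, `estimate`, `p_adjusted`)
#'   and `letters` (named character vector, one entry per group).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  smry <- with_seed(seed, summary(glt))
  cld <- with_seed(seed, multcomp::cld(smry, level = alpha))
  pairs <- data.frame(
    pair = names(coef(glt)),
    estimate = unname(coef(glt)),
    p_adjusted = as.numeric(smry$test$pvalues),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(pairs = pairs, letters = cld$mcletters$Letters)
}

#' Polynomial time-course regression with backward selection
#'
#' Models a (log) titer time-course as a polynomial in day with
#' strain-by-day interactions, starting from the full model
#' `y ~ strain * (day + day^2 + ... + day^max_degree)` and iteratively
#' removing the least significant currently-removable term with p >= alpha
#' (highest order first). Marginality is respected throughout: a main
#' effect or lower-order term is never dropped while a term containing it
#' remains ([drop1()] only offers removable terms).
#'
#' @param day Numeric day of measurement.
#' @param response Numeric response (e.g. log2 mean titer).
#' @param strain Strain label per observation (a single level is allowed;
#'   interactions then never enter).
#' @param max_degree Highest polynomial degree of day.
#' @param alpha Per-term significance threshold for removal.
#' @return List with `formula` (selected), `fit` (the `lm`),
#'   `anova` (F tests of the retained terms), `removed` (character vector,
#'   in removal order).
#' @export
polynomial_backward_regression <- function(day, response, strain,
                                           max_degree = 3, alpha = 0.05) {
  if (sd(response) == 0) stop("zero-variance response")
  strain <- factor(strain)
  dat <- data.frame(y = response, day = day, strain = strain)
  day_terms <- vapply(seq_len(max_degree), function(d) {
    if (d == 1) "day" else sprintf("I(day^%d)", d)
  }, character(1))
  rhs <- paste(day_terms, collapse = " + ")
  form <- if (nlevels(strain) > 1) {
    as.formula(paste("y ~ strain * (", rhs, ")"))
  } else {
    as.formula(paste("y ~", rhs))
  }
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design: collinear polynomial/interaction terms")
  }
  removed <- character()
  repeat {
    d1 <- drop1(fit, test = "F")
    d1 <- d1[rownames(d1) != "<none>", , drop = FALSE]
    cand <- rownames(d1)[!is.na(d1$`Pr(>F)`) & d1$`Pr(>F)` >= alpha]
    if (!length(cand)) break
    # prefer the highest-order candidate; among equals the least significant
    ord <- vapply(cand, function(tm) {
      deg <- if (grepl("I\\(day\\^(\\d)\\)", tm)) {
        as.integer(sub(".*I\\(day\\^(\\d)\\).*", "\\1", tm))
      } else if (grepl("day", tm)) 1L else 0L
      deg + grepl(":", tm) * 0.5
    }, numeric(1))
    worst <- cand[order(-ord, -d1[cand, "Pr(>F)"])][1]
    fit <- update(fit, as.formula(paste(". ~ . -", worst)))
    removed <- c(removed, worst)
  }
  list(formula = formula(fit), fit = fit, anova = drop1(fit, test = "F"),
       removed = removed)
}
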