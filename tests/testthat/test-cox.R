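test_that("day-1 deaths are excluded, censored records kept", {
  rec <- data.frame(day = c(1, 1, 2, 5), event = c(1, 0, 1, 0))
  expect_message(out <- exclude_day1_deaths(rec), "1 day-1 death")
  expect_equal(nrow(out), 3)
  expect_true(all(!(out$day == 1 & out$event == 1)))
  # identity when nothing to remove
  rec2 <- data.frame(day = c(2, 3), event = c(1, 1))
  expect_identical(exclude_day1_deaths(rec2), rec2)
  # all deaths on day 1: downstream fit refuses (no events left)
  rec3 <- data.frame(strain = factor(c("a", "a", "b", "b")),
                     vial_id = c("v1", "v1", "v2", "v2"),
                     day = c(1, 1, 1, 3), event = c(1, 1, 1, 0))
  kept <- suppressMessages(exclude_day1_deaths(rec3))
  expect_error(fit_cox_mixed(kept, ~ strain), "no events")
})

test_that("partial likelihood matches a hand-coded product oracle on a toy", {
  # 6 observations, distinct days (no ties): PL is the textbook product
  toy <- data.frame(
    x = c(0, 0, 0, 1, 1, 1),
    day = c(2, 5, 9, 1, 4, 8),
    event = c(1, 1, 0, 1, 1, 1),
    vial_id = "v1"
  )
  toy$strain <- factor(ifelse(toy$x == 1, "B", "A"))
  fit <- fit_cox_mixed(toy, ~ strain, frailty_variance = 0)
  b <- unname(fit$coefficients)
  expect_equal(fit$loglik$partial,
               hand_partial_loglik(b, toy$x, toy$day, toy$event))
  # grid-search maximiser of the oracle likelihood agrees to 1e-4
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, hand_partial_loglik, numeric(1),
               x = toy$x, day = toy$day, event = toy$event)
  expect_equal(b, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("fixed-effect fits equal the independent Cox implementation", {
  skip_if_not_installed("survival")
  for (seed in c(11, 23, 35)) {
    rec <- sim_small_surv(seed, n_strains = 4, vials = 2, flies = 20)
    fit <- fit_cox_mixed(rec, ~ strain, reference_strain = "wfree",
                         frailty_variance = 0)
    rec$strain <- relevel(factor(rec$strain), "wfree")
    cfit <- survival::coxph(survival::Surv(day, event) ~ strain,
                            data = rec, ties = "efron")
    expect_equal(unname(fit$coefficients), unname(coef(cfit)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cfit)))),
                 tolerance = 1e-6)
    expect_equal(fit$loglik$partial, cfit$loglik[2], tolerance = 1e-8)
  }
  # Breslow ties too
  rec <- sim_small_surv(47, n_strains = 3)
  fit_b <- fit_cox_mixed(rec, ~ strain, reference_strain = "wfree",
                         frailty_variance = 0, ties = "breslow")
  rec$strain <- relevel(factor(rec$strain), "wfree")
  cfit_b <- survival::coxph(survival::Surv(day, event) ~ strain,
                            data = rec, ties = "breslow")
  expect_equal(unname(fit_b$coefficients), unname(coef(cfit_b)),
               tolerance = 1e-6)
})

test_that("partial likelihood is invariant to monotone day relabelling", {
  rec <- sim_small_surv(7, n_strains = 3)
  fit1 <- fit_cox_mixed(rec, ~ strain, frailty_variance = 0)
  rec2 <- rec
  rec2$day <- rec$day^2 + 3 * rec$day # strictly increasing map
  fit2 <- fit_cox_mixed(rec2, ~ strain, frailty_variance = 0)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-9)
  expect_equal(fit1$loglik$partial, fit2$loglik$partial, tolerance = 1e-9)
})

test_that("frailty variance is recovered and vial effects predicted", {
  rec <- sim_small_surv(91, n_strains = 5, vials = 8, flies = 25,
                        frailty_sd = 0.5)
  fit <- fit_cox_mixed(rec, ~ strain, reference_strain = "wfree")
  expect_gt(fit$frailty_variance, 0.02)
  expect_lt(fit$frailty_variance, 1.5)
  expect_equal(length(fit$vial_effects), length(unique(rec$vial_id)))
  # near-zero truth: estimate collapses toward the boundary
  rec0 <- sim_small_surv(92, n_strains = 4, vials = 4, flies = 25,
                         frailty_sd = 0)
  fit0 <- fit_cox_mixed(rec0, ~ strain, reference_strain = "wfree")
  expect_lt(fit0$frailty_variance, 0.05)
})

test_that("likelihood ratio tests compare nested fits", {
  rec <- sim_small_surv(13, n_strains = 4, vials = 3, flies = 20,
                        log_hr = c(0, 1.2, -0.8, 0.6))
  full <- fit_cox_mixed(rec, ~ strain, frailty_variance = 0)
  reduced <- fit_cox_mixed(rec, ~ 1, frailty_variance = 0)
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 3)
  expect_gte(lrt$chi2, 0)
  expect_lt(lrt$p, 0.01) # strong true effects
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(likelihood_ratio_test(reduced, full), "more coefficients")
})

test_that("a strain-by-treatment interaction is detected by the LRT", {
  # protection present under virus challenge but absent under mock
  # inoculation is an interaction; the additive model must lose the LRT
  cfg <- sim_config(n_strains = 4, vial_frailty_sd = 0,
                    day1_injury_rate = 0,
                    n_vials_per_strain_per_treatment = 4,
                    flies_per_vial = 25, treatments = c("DCV", "Ringer"))
  lhr <- cbind(DCV = c(0, -1.2, -0.6, 0.9), Ringer = c(0, 0, 0, 0))
  rownames(lhr) <- c("wfree", "s1", "s2", "s3")
  rec <- simulate_survival(lhr, cfg, seed = 83)
  full <- fit_cox_mixed(rec, ~ strain * treatment,
                        reference_strain = "wfree", frailty_variance = 0)
  reduced <- fit_cox_mixed(rec, ~ strain + treatment,
                           reference_strain = "wfree",
                           frailty_variance = 0)
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 3)
  expect_lt(lrt$p, 0.05)
})

test_that("per-vial protection uses -(beta + vial effect) with reference 0", {
  rec <- sim_small_surv(29, n_strains = 3, vials = 3, flies = 20,
                        frailty_sd = 0.3, log_hr = c(0, -0.7, 0.4))
  fit <- fit_cox_mixed(rec, ~ strain, reference_strain = "wfree")
  prot <- per_vial_protection(fit)
  expect_setequal(prot$vial_id, unique(rec$vial_id))
  for (v in prot$vial_id[prot$strain == "s1"][1]) {
    expect_equal(prot$value[prot$vial_id == v],
                 unname(-(fit$coefficients["strains1"] +
                            fit$vial_effects[v])))
  }
  ref_vials <- prot[prot$strain == "wfree", ]
  expect_equal(ref_vials$value, unname(-fit$vial_effects[ref_vials$vial_id]))
  # protective strain (negative log-HR) gets positive trait values
  expect_gt(mean(prot$value[prot$strain == "s1"]), 0)
})

test_that("increasing a strain's hazard strictly decreases its protection", {
  means <- vapply(c(-0.8, 0, 0.8), function(lh) {
    rec <- sim_small_surv(57, n_strains = 2, vials = 6, flies = 25,
                          frailty_sd = 0.2, log_hr = c(0, lh))
    fit <- fit_cox_mixed(rec, ~ strain, reference_strain = "wfree")
    prot <- per_vial_protection(fit)
    mean(prot$value[prot$strain == "s1"])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("vial-as-fixed construction agrees with the random-effect one", {
  rec <- sim_small_surv(63, n_strains = 4, vials = 4, flies = 25,
                        frailty_sd = 0.3)
  f_ran <- fit_cox_mixed(rec, ~ strain, reference_strain = "wfree")
  f_fix <- fit_cox_mixed(rec, reference_strain = "wfree", vial_as = "fixed")
  p_ran <- per_vial_protection(f_ran)
  p_fix <- per_vial_protection(f_fix)
  m <- match(p_ran$vial_id, p_fix$vial_id)
  keep <- p_ran$strain != "wfree"
  expect_gt(cor(p_ran$value[keep], p_fix$value[m][keep]), 0.85)
})

test_that("Wald tests flag non-identifiable strains instead of failing", {
  rec <- sim_small_surv(71, n_strains = 3, vials = 2, flies = 15)
  # one strain whose flies all survive: no events, coefficient diverges
  idx <- rec$strain == "s2"
  rec$event[idx] <- 0
  rec$day[idx] <- 25
  fit <- suppressMessages(
    fit_cox_mixed(rec, ~ strain, reference_strain = "wfree",
                  frailty_variance = 0)
  )
  tests <- strain_vs_control_tests(fit)
  flagged <- tests[tests$coefficient == "strains2", ]
  expect_true(flagged$flagged)
  expect_equal(flagged$p, 1)
  ok <- tests[tests$coefficient == "strains1", ]
  expect_false(ok$flagged)
  expect_true(ok$p >= 0 && ok$p <= 1)
})
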