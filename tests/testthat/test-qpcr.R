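test_that("technical replicates average on the Ct scale with QC flags", {
  m <- data.frame(pool_id = "p1", strain = "s", experiment = "e",
                  gene = "g", plate_id = "pl", tech_rep = 1:2,
                  ct = c(20.0, 20.4))
  avg <- average_technical_replicates(m)
  expect_equal(avg$ct, 20.2)
  expect_false(avg$discordant)

  one <- average_technical_replicates(m[1, ])
  expect_equal(one$ct, 20.0)
  expect_equal(one$n_reps, 1L)

  m$ct <- c(20, 25)
  expect_message(avg2 <- average_technical_replicates(m), "discordance")
  expect_equal(avg2$ct, 22.5)
  expect_true(avg2$discordant)

  expect_error(average_technical_replicates(data.frame(pool_id = 1)),
               "columns")
})

test_that("Pfaffl relative quantity reduces to 2^-dCt and handles efficiencies", {
  expect_equal(relative_quantity(20, 20), 1)
  expect_equal(relative_quantity(18, 21), 8)
  expect_equal(relative_quantity(20, 20, 1.9, 2.0), 2^20 / 1.9^20)
  # algebraic identity on random Cts
  set.seed(1)
  ct_t <- runif(100, 10, 35); ct_r <- runif(100, 10, 35)
  expect_equal(relative_quantity(ct_t, ct_r, 2, 2), 2^(ct_r - ct_t))
  expect_error(relative_quantity(20, 20, 1, 2), "efficiency")
  expect_error(relative_quantity(Inf, 20), "finite")
})

test_that("dilution-series efficiency estimation inverts the slope", {
  lg <- 0:-4
  expect_equal(estimate_efficiency_dilution(lg, 12 - lg * 3.3219281)$E, 2,
               tolerance = 1e-6)
  e36 <- estimate_efficiency_dilution(lg, 12 - lg * 3.6)
  expect_equal(e36$E, 10^(1 / 3.6), tolerance = 1e-10)
  expect_error(estimate_efficiency_dilution(0:-1, c(12, 15)), ">= 3")
  expect_error(estimate_efficiency_dilution(c(0, -0.5, -1), c(12, 13, 14)),
               "orders of magnitude")
  expect_error(estimate_efficiency_dilution(lg, 12 + lg * 3.3), "monotone")
})

test_that("efficiency correction maps Ct to the doubling scale", {
  expect_equal(efficiency_correct_ct(20, 2), 20)
  expect_equal(efficiency_correct_ct(20, 1.9), 20 * log2(1.9))
  expect_equal(efficiency_correct_ct(0, 1.8), 0)
  # definitional identity: 2^-ct' = E^-ct
  set.seed(2)
  ct <- runif(50, 5, 40); E <- runif(50, 1.7, 2.1)
  expect_equal(2^(-efficiency_correct_ct(ct, E)), E^(-ct))
  expect_error(efficiency_correct_ct(20, 2.5), "efficiency")
})

test_that("plate normalisation is a within-plate z-score", {
  expect_equal(plate_normalize(c(1, 2, 3), rep("p", 3)), c(-1, 0, 1))
  x <- as.numeric(scale(c(-1.2, 0.3, 0.9))) # already mean 0 sd 1
  expect_equal(plate_normalize(x, rep("p", 3)), x, tolerance = 1e-12)

  set.seed(3)
  v <- rnorm(12)
  pl <- rep(c("a", "b"), each = 6)
  base <- plate_normalize(v, pl)
  shifted <- v + ifelse(pl == "a", 5, -2)
  scaled <- v * ifelse(pl == "a", 3, 0.25)
  expect_equal(plate_normalize(shifted, pl), base)
  expect_equal(plate_normalize(scaled, pl), base)
  expect_equal(as.numeric(tapply(base, pl, mean)), c(0, 0))
  expect_equal(as.numeric(tapply(base, pl, sd)), c(1, 1))
  expect_error(plate_normalize(c(1, 2, 3), c("a", "b", "b")),
               "fewer than 2")
  expect_error(plate_normalize(c(1, 1, 2, 3), c("a", "a", "b", "b")),
               "'a'")
})

test_that("noiseless simulate-to-quantify round trip is exact", {
  cfg <- sim_config(
    n_strains = 4,
    trait_names = c("ln_density", "titer_DCV", "expr_Drosomycin_DCV"),
    V_s = diag(0.4, 3), V_p = diag(0, 3),
    qpcr = list(ct_noise_sd = 0, efficiency_target = 1.85, n_pools = 4)
  )
  ds <- simulate_dataset(cfg)
  eff <- c(atpD = 1.85, DCV = 1.85, Drosomycin_DCV = 1.85,
           Actin5C = 2, EF1a100E = 2)
  traits <- assemble_qpcr_traits(ds$qpcr$ct, efficiencies = eff,
                                 plate_normalize_traits = character())
  for (tn in c("ln_density", "titer_DCV", "expr_Drosomycin_DCV")) {
    truth <- ds$truth$true_quantities[[tn]]
    est <- traits[traits$trait == tn, ]
    m <- match(truth$pool_id, est$replicate)
    expect_equal(est$value[m], log(truth$value), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # and the estimated efficiencies come straight off the dilution series
  for (g in c("atpD", "DCV", "Drosomycin_DCV")) {
    dl <- ds$qpcr$dilution[ds$qpcr$dilution$gene == g, ]
    expect_equal(estimate_efficiency_dilution(dl$log10_input, dl$ct)$E,
                 1.85, tolerance = 1e-6)
  }
})

test_that("trait assembly drops excluded strains and orphan pools", {
  cfg <- sim_config(n_strains = 5, trait_names = c("ln_density"),
                    V_s = matrix(0.4), V_p = matrix(0),
                    qpcr = list(n_pools = 3))
  ds <- simulate_dataset(cfg)
  tab <- assemble_qpcr_traits(ds$qpcr$ct, exclude_strains = c("w01", "w02"))
  expect_false(any(tab$strain %in% c("w01", "w02")))
  expect_true(all(is.finite(tab$value)))

  # remove the reference gene for one pool: that pool is dropped, warned
  ct <- ds$qpcr$ct
  drop_pool <- ct$pool_id[1]
  ct <- ct[!(ct$pool_id == drop_pool & ct$gene == "Actin5C"), ]
  expect_warning(tab2 <- assemble_qpcr_traits(ct), "reference gene")
  expect_false(drop_pool %in% tab2$replicate)
})

test_that("expression traits are plate-normalised during assembly", {
  cfg <- sim_config(n_strains = 6, trait_names = "expr_Drosomycin_DCV",
                    V_s = matrix(0.4), V_p = matrix(0),
                    qpcr = list(n_pools = 6, n_plates = 3))
  ds <- simulate_dataset(cfg)
  tab <- assemble_qpcr_traits(ds$qpcr$ct)
  means <- tapply(tab$value, tab$plate_id, mean)
  expect_equal(as.numeric(means), rep(0, 3), tolerance = 1e-10)
})
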