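test_that("log-linear inactivation fit inverts noiseless decay", {
  d <- simulate_decay(0.05, seq(0, 60, by = 5))
  fit <- fit_inactivation(d$time, d$residual_activity)
  expect_equal(fit$kd, 0.05, tolerance = 1e-9)
  expect_equal(fit$t_half, log(2) / 0.05, tolerance = 1e-9)
  expect_equal(fit$t_half, 13.863, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # the half-life identity holds exactly for every fit
  expect_equal(fit$t_half * fit$kd, log(2), tolerance = 1e-15)
})

test_that("inactivation fit handles bad points and non-decaying series", {
  t <- seq(0, 50, by = 10)
  y <- exp(-0.1 * t); y[4] <- 0
  expect_warning(fit <- fit_inactivation(t, y), "excluded")
  expect_equal(fit$n_used, 5)
  expect_warning(flat <- fit_inactivation(t, rep(1, 6) * exp(0.01 * t)),
                 "not decaying")
  expect_false(flat$decaying)
  expect_equal(flat$t_half, Inf)
  expect_error(fit_inactivation(c(0, 0, 1), c(1, 1, 1)), "strictly increasing")
})

test_that("a 2.3-minute half-life implies kd of 0.3014 per minute", {
  # invert the half-life identity, then confirm by refitting a series
  kd <- log(2) / 2.3
  expect_equal(round(kd, 4), 0.3014)
  d <- simulate_decay(kd, seq(0, 10, by = 1))
  expect_equal(fit_inactivation(d$time, d$residual_activity)$t_half, 2.3,
               tolerance = 1e-9)
})

test_that("melting fit recovers the transition midpoint", {
  mc <- simulate_melt(48.17, steepness = 2)
  fit <- fit_melting(mc$temperature, mc$signal)
  expect_equal(fit$tm, 48.17, tolerance = 0.05)
  expect_gt(fit$steepness, 0)
  expect_gt(fit$r_squared, 0.999)
  # symmetric curve with flat baselines: Tm is the halfway temperature
  flat <- simulate_melt(55, steepness = 3,
                        baselines = list(native = c(-20, 0), denatured = c(-4, 0)))
  fit2 <- fit_melting(flat$temperature, flat$signal)
  halfway <- (-20 + -4) / 2
  t_half_sig <- flat$temperature[which.min(abs(flat$signal - halfway))]
  expect_equal(fit2$tm, 55, tolerance = 0.05)
  expect_equal(t_half_sig, 55, tolerance = 1)
})

test_that("a strictly linear curve has no detectable transition", {
  temp <- seq(20, 90, by = 2)
  expect_error(fit_melting(temp, -20 + 0.05 * temp), "no detectable")
  expect_error(fit_melting(1:5, 1:5), "at least 8")
})

test_that("Michaelis-Menten fit inverts noiseless rate data", {
  s <- c(5, 10, 20, 40, 80, 160, 320)
  r <- simulate_rates(56, 12, s)
  fit <- fit_michaelis_menten(r$substrate, r$rate)
  expect_equal(fit$km, 56, tolerance = 1e-6)
  expect_equal(fit$vmax, 12, tolerance = 1e-6)
  # v at S = Km equals Vmax/2
  expect_equal(12 * 56 / (56 + 56), 12 / 2)
  # kcat = Vmax / [E]; doubling [E] halves kcat
  cfg1 <- assay_config(enzyme_molar_conc = 1e-7)
  cfg2 <- assay_config(enzyme_molar_conc = 2e-7)
  f1 <- fit_michaelis_menten(r$substrate, r$rate, cfg1)
  f2 <- fit_michaelis_menten(r$substrate, r$rate, cfg2)
  expect_equal(f1$kcat, 2 * f2$kcat)
  # non-saturating data are flagged
  low_s <- c(1, 2, 3, 4, 5)
  low <- simulate_rates(500, 10, low_s)
  expect_warning(ns <- fit_michaelis_menten(low$substrate, low$rate),
                 "non-saturating")
  expect_false(ns$saturating)
})

test_that("catalytic efficiency converts units correctly", {
  expect_equal(catalytic_efficiency(1, 1), 1000)
  expect_equal(round(catalytic_efficiency(30.3, 56), 1), 541.1)
  expect_equal(round(catalytic_efficiency(117.6, 56), 1), 2100.0)
  expect_error(catalytic_efficiency(1, 0), "positive")
})

test_that("absorbance slopes convert to rates and specific activity", {
  cfg <- assay_config(epsilon = 25000, path_length = 1, enzyme_mass = 2)
  out <- activity_from_absorbance(0.25, cfg)
  expect_equal(out$rate_uM_per_min, 10)
  expect_equal(out$specific_activity, 5)
  expect_equal(activity_from_absorbance(0, cfg)$rate_uM_per_min, 0)
  # specific activity doubles when enzyme mass halves
  half <- assay_config(epsilon = 25000, path_length = 1, enzyme_mass = 1)
  expect_equal(activity_from_absorbance(0.25, half)$specific_activity, 10)
})

test_that("optimal temperature picks the activity peak deterministically", {
  prof <- data.frame(t = c(30, 35, 40, 45, 50), a = c(1, 3, 5, 4, 2))
  expect_equal(optimal_temperature(prof$t, prof$a)$t_opt, 40)
  # monotone profile: boundary flagged
  mono <- optimal_temperature(c(30, 40, 50), c(1, 2, 3))
  expect_equal(mono$t_opt, 50)
  expect_true(mono$boundary)
  # ties resolve to the lowest temperature and are flagged
  tie <- optimal_temperature(c(30, 40, 50), c(1, 5, 5))
  expect_equal(tie$t_opt, 40)
  expect_true(tie$tie)
})

test_that("comparison reports reproduce published-style conventions", {
  wt <- enzyme_characterization("WT", specific_activity = 10.4,
                                optimal_temperature = 35, t_half = 2.3,
                                tm = 48.17, km = 56, kcat = 30.3)
  mut <- enzyme_characterization("N130D/G260Q", specific_activity = 21.0,
                                 optimal_temperature = 40, t_half = 15.2,
                                 tm = 50.62, km = 13, kcat = 35.4)
  rep <- compare_characterizations(wt, mut)
  expect_equal(rep$fold_t_half, 6.6)
  expect_equal(rep$delta_tm, 2.45)
  expect_equal(rep$delta_t_opt, 5)
  expect_equal(rep$pct_change_km, 77)
  expect_equal(rep$fold_specific_activity, 2.0)
  # antisymmetry of delta fields under argument swap
  swapped <- compare_characterizations(mut, wt)
  expect_equal(swapped$delta_tm, -rep$delta_tm)
  expect_equal(swapped$delta_t_opt, -rep$delta_t_opt)
  # missing fields are omitted, not defaulted
  partial <- enzyme_characterization("X", t_half = 4.6)
  rep2 <- compare_characterizations(wt, partial)
  expect_equal(rep2$fold_t_half, 2.0)
  expect_true(is.na(rep2$delta_tm))
  # zero-valued wild-type fields are an error, not an Inf
  zero <- enzyme_characterization("Z", t_half = 0)
  expect_error(compare_characterizations(zero, mut), "zero")
})

test_that("series CSV readers validate their headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(simulate_decay(0.1, 0:5), path, row.names = FALSE)
  d <- read_decay_csv(path)
  expect_named(d, c("time", "residual_activity"))
  utils::write.csv(data.frame(a = 1), path, row.names = FALSE)
  expect_error(read_decay_csv(path), "missing required")
  expect_error(read_melt_csv(path), "temperature")
  expect_error(read_rates_csv(path), "substrate")
})
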