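test_that("default profiles honor the published aggregate constraints", {
  prof <- default_ses_profiles()
  w <- prof$cohort_share
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # cohort-weighted severity prevalences reproduce the printed overall values
  expect_equal(sum(w * prof$prev_mild), 0.128, tolerance = 1e-9)
  expect_equal(sum(w * prof$prev_moderate), 0.302, tolerance = 1e-9)
  expect_equal(sum(w * prof$prev_severe), 0.030, tolerance = 1e-9)
  # poorest-decile and wealthiest-quintile moderate+severe anchors
  expect_equal(prof$prev_moderate[1] + prof$prev_severe[1], 0.392,
               tolerance = 1e-9)
  w910 <- w[9:10] / sum(w[9:10])
  expect_equal(sum(w910 * (prof$prev_moderate[9:10] + prof$prev_severe[9:10])),
               0.253, tolerance = 1e-9)
  # moderate and severe fall with wealth, mild rises slightly
  expect_true(all(diff(prof$prev_moderate) < 0))
  expect_true(all(diff(prof$prev_severe) < 0))
  expect_true(all(diff(prof$prev_mild) > 0))
  # poorest / wealthiest quintile mortality ratio
  expect_equal(prof$annual_mortality[1] / prof$annual_mortality[10], 2.8)
  # buyer-class shares are a partition
  expect_equal(prof$share_current + prof$share_potential + prof$share_non,
               rep(1, 10), tolerance = 1e-9)
})

test_that("shipped profile config file matches the in-code construction", {
  shipped <- read_ses_profiles(system.file("extdata", "ses_profiles.tsv",
                                           package = "fpicce"))
  built <- default_ses_profiles()
  for (cc in names(built)) {
    expect_equal(shipped[[cc]], built[[cc]], tolerance = 1e-8, label = cc)
  }
})

test_that("anemia-to-IDA attribution scales severities uniformly", {
  prev <- c(0.2133, 0.5033, 0.05)
  expect_equal(anemia_to_ida(prev, 1.0), prev)
  expect_equal(anemia_to_ida(prev, 0), c(0, 0, 0))
  expect_equal(round(anemia_to_ida(prev, 0.6), 3), c(0.128, 0.302, 0.030))
  expect_error(anemia_to_ida(prev, 1.5), class = "fpicce_domain_error")
})

test_that("hemoglobin calibration recovers an exact-fit Gaussian", {
  tg <- gaussian_targets(105, 12)
  fit <- calibrate_hb_distribution(tg)
  expect_lt(abs(fit[["hb_mean"]] - 105), 0.1)
  expect_lt(abs(fit[["hb_sd"]] - 12), 0.1)
  implied <- implied_prevalence(fit[["hb_mean"]], fit[["hb_sd"]])
  expect_lt(max(abs(implied[c("mild", "moderate", "severe")] -
                      tg[c("mild", "moderate", "severe")])), 0.01)

  expect_error(calibrate_hb_distribution(c(mild = 0, moderate = 0, severe = 1)),
               class = "fpicce_calibration_error")
})

test_that("calibrated category masses always sum to one", {
  cal <- calibrated_defaults()
  for (i in seq_len(nrow(cal$profiles))) {
    imp <- implied_prevalence(cal$profiles$hb_mean[i], cal$profiles$hb_sd[i])
    expect_equal(sum(imp), 1, tolerance = 1e-12)
  }
  expect_true(all(cal$profiles$hb_sd > 0))
})

test_that("burden arithmetic matches the hand oracle on a single decile", {
  prof <- toy_profiles(prev_mild = 0.5, share1 = 0.1)
  params <- default_burden_params(cohort_size = 10000,
                                  dw_current = c(mild = 0.01, moderate = 0, severe = 0))
  b <- compute_burden(prof, params)
  # 10000 * 0.1 children x 0.5 prevalence x 0.01 weight x 1.5 years
  expect_equal(b$by_decile$yld_current[1], 7.5, tolerance = 1e-12)
  expect_equal(sum(b$by_decile$yld_current[-1]), 0)
  # mild anemia carries no excess mortality under the default RRs
  expect_equal(b$totals$yll, 0)

  zero <- compute_burden(toy_profiles(), default_burden_params())
  expect_equal(zero$totals$dalys_total, 0)
  expect_equal(zero$totals$losses_total, 0)
})

test_that("burden totals equal the sum of components and deciles", {
  cal <- calibrated_defaults()
  b <- compute_burden(cal$profiles, cal$params)
  expect_equal(b$totals$dalys_total,
               b$totals$yld_current + b$totals$yld_future + b$totals$yll,
               tolerance = 1e-9)
  expect_equal(b$totals$losses_total, sum(b$by_decile$losses), tolerance = 1e-9)
  expect_equal(b$totals$dalys_total, sum(b$by_decile$dalys), tolerance = 1e-9)
})

test_that("burden is monotone in prevalence and decreases with wealth", {
  cal <- calibrated_defaults()
  base <- compute_burden(cal$profiles, cal$params)
  bumped_prof <- cal$profiles
  bumped_prof$prev_moderate <- pmin(1, bumped_prof$prev_moderate + 0.01)
  bumped <- compute_burden(bumped_prof, cal$params)
  expect_true(bumped$totals$dalys_total > base$totals$dalys_total)
  expect_true(bumped$totals$losses_total > base$totals$losses_total)
  # social costs decline from poorest to wealthiest decile
  expect_true(all(diff(base$by_decile$dalys) < 0))
  expect_true(all(diff(base$by_decile$losses) < 0))
})

test_that("cost calibration rescales components exactly", {
  prof <- default_ses_profiles()
  params <- default_burden_params()
  base <- compute_burden(prof, params)$totals
  doubled <- list(loss_future = 2 * base$loss_future,
                  loss_mortality = 2 * base$loss_mortality,
                  yld_current = 2 * base$yld_current / 1000,
                  yld_future = 2 * base$yld_future / 1000,
                  yll = 2 * base$yll / 1000)
  cal <- calibrate_costs(prof, params, targets = doubled)
  expect_equal(unname(attr(cal, "multipliers")), rep(2, 5), tolerance = 1e-12)

  bad <- default_burden_params(mortality_rr = c(mild = 1, moderate = 1, severe = 1))
  expect_error(calibrate_costs(prof, bad), class = "fpicce_calibration_error")
})

test_that("calibrated totals reproduce the published cohort burden", {
  cal <- calibrated_defaults()
  b <- compute_burden(cal$profiles, cal$params)$totals
  expect_equal(b$loss_future, 3172, tolerance = 1e-6)
  expect_equal(b$loss_mortality, 50, tolerance = 1e-6)
  expect_equal(b$yld_current / 1000, 92, tolerance = 1e-6)
  expect_equal(b$yld_future / 1000, 588, tolerance = 1e-6)
  expect_equal(b$yll / 1000, 46, tolerance = 1e-6)
  expect_equal(b$losses_total, 3222, tolerance = 1e-6)
  expect_equal(b$dalys_total / 1000, 726, tolerance = 1e-6)
})
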