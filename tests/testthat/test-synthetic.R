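test_that("study profiles reproduce the experimental design", {
  profiles <- make_study_profiles()
  # treatment A: pulses at [0,1) and [3,4), 10 d total
  expect_equal(profiles$A$start_times, c(0, 1, 3, 4))
  expect_equal(profiles$A$concentrations, c(28, 0, 28, 0))
  expect_equal(profiles$A$end_time, 10)
  expect_equal(concentration_at(profiles$A, c(0.5, 2, 3.5, 9)),
               c(28, 0, 28, 0))
  # treatment B: second pulse after the 6-d gap, i.e. at [7,8)
  expect_equal(profiles$B$start_times, c(0, 1, 7, 8))
  expect_equal(concentration_at(profiles$B, 7.5), 28)
  # treatment C holds the TWA concentration for the whole 10 d
  expect_equal(time_weighted_average(profiles$C, 0, 10), 4.6)
  # acute series spans the seven-concentration design over 4 d
  acute <- grep("^acute_", names(profiles), value = TRUE)
  expect_length(acute, 7)
  expect_equal(profiles$acute_1$concentrations, 8.2)
  expect_equal(profiles$acute_7$concentrations, 37.4)
  expect_equal(profiles$acute_1$end_time, 4)
  # TK exposures: 1 d uptake then 5 d / 1 d depuration
  expect_equal(profiles$TK1$end_time, 6)
  expect_equal(profiles$TK2$end_time, 2)
})

test_that("TK data generation is exact at cv = 0 and reproducible under seed", {
  tk1 <- make_study_profiles()$TK1
  exact <- generate_tk_data(tk1, tk_study, cv = 0)
  expect_equal(exact$internal_concentrations,
               simulate_internal(tk1, tk_study, exact$times))
  a <- generate_tk_data(tk1, tk_study, cv = 0.15, seed = 33)
  b <- generate_tk_data(tk1, tk_study, cv = 0.15, seed = 33)
  expect_identical(a$internal_concentrations, b$internal_concentrations)
  # empirical CV of the multiplicative noise is close to nominal
  big <- generate_tk_data(constant_profile(5, 10), tk_study, cv = 0.15,
                          times = rep(5, 1000), seed = 34)
  x <- big$internal_concentrations
  expect_lt(abs(sd(x) / mean(x) - 0.15) / 0.15, 0.15)
})

test_that("conditional-binomial survivor counts have the right first moment", {
  vr <- model_variant("SD", "reduced")
  prm <- sd_params(1.7, 0.126, 16.4, hb_study)
  p <- pulse_profile(28, 1, 10)
  # certain survival: everyone alive at every time under every seed
  sure <- generate_survival_data(vr, sd_params(1.7, 0.126, 1e6, 0), p, 10,
                                 seed = 1)
  expect_equal(sure$survivor_counts, rep(10L, 11))
  # counts non-increasing for every seed; mean final count matches n * S_n
  S_end <- predict_survival(vr, prm, p, c(0, 10))[2]
  finals <- vapply(1:800, function(s) {
    d <- generate_survival_data(vr, prm, p, 10, seed = s)
    expect_true(all(diff(d$survivor_counts) <= 0))
    d$survivor_counts[11]
  }, 0L)
  se <- sqrt(10 * S_end * (1 - S_end) / 800)
  expect_lt(abs(mean(finals) - 10 * S_end), 3 * se)
})

test_that("pulsed treatments kill more than the constant-TWA treatment", {
  vr <- model_variant("SD", "reduced")
  prm <- sd_params(1.7, 0.126, 16.4, hb_study)
  worse <- vapply(1:9, function(s) {
    st <- generate_study(vr, prm, seed = s)
    final <- vapply(st$pulsed, function(d)
      d$survivor_counts[length(d$survivor_counts)], 0L)
    final["A"] < final["C"] && final["B"] < final["C"]
  }, TRUE)
  expect_gt(mean(worse), 0.5)
})

test_that("the generated study round-trips through calibration", {
  # ties the generator to the estimator: moderate-n recovery with loose tol
  vr <- model_variant("IT", "reduced")
  gen <- it_params(0.8, 18.7, 7.4, hb_study)
  st <- generate_study(vr, gen, seed = 5, n_per_treatment = 300)
  hb <- fit_background_hazard(st$controls)$h_b
  fit <- calibrate(vr, c(st$pulsed, st$acute), h_b = hb, n_starts = 2,
                   seed = 5)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates - c(0.8, 18.7, 7.4)) /
                  c(0.8, 18.7, 7.4)), 0.15)
})
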