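test_that("dose metrics reach the expected limits and peak after pulses", {
  # reduced: steady state equals the external concentration
  vr <- model_variant("SD", "reduced")
  expect_equal(dose_metric(vr, sd_params(1.7, 1, 1),
                           constant_profile(4.6, 60), 60), 4.6,
               tolerance = 1e-10)
  # full with fast damage kinetics tracks the internal equilibrium k_in*c/k_out
  tk <- tk_study
  vf <- model_variant("SD", "full", tk)
  expect_equal(dose_metric(vf, sd_params(500, 1, 1),
                           constant_profile(2, 30), 30),
               130.9 * 2 / 6.9, tolerance = 1e-4)
  # full, 1-d pulse, k_d = 0.6: damage peaks shortly AFTER the pulse ends,
  # at the same interior maximum an Euler fine grid locates
  kd <- 0.6
  tg <- seq(0, 3, by = 1e-4)
  m <- dose_metric(vf, sd_params(kd, 1, 1), pulse_profile(28, 1, 10), tg)
  t_peak <- tg[which.max(m)]
  dt <- 1e-5
  te <- seq(0, 3, by = dt)
  ce <- ifelse(te < 1, 28, 0)
  ci <- c(0, stats::filter(130.9 * dt * ce[-length(te)], 1 - 6.9 * dt,
                           method = "recursive"))
  de <- c(0, stats::filter(kd * dt * ci[-length(te)], 1 - kd * dt,
                           method = "recursive"))
  expect_gt(t_peak, 1)
  expect_equal(t_peak, te[which.max(de)], tolerance = 2e-3)
  expect_error(model_variant("SD", "full"), "require")
})

test_that("stochastic-death survival matches closed forms and the fine-grid oracle", {
  vr <- model_variant("SD", "reduced")
  p <- pulse_profile(28, 1, 10)
  tt <- 0:10
  # metric below threshold with no background hazard: no mortality at all
  S <- survival_sd(vr, sd_params(1.7, 0.126, 100, 0), p, tt)$survival
  expect_equal(S, rep(1, length(tt)))
  # zero killing rate reduces to background survival
  S <- survival_sd(vr, sd_params(1.7, 0, 5, 0.03), p, tt)$survival
  expect_equal(S, exp(-0.03 * tt), tolerance = 1e-12)
  # reduced-SD at the pulsed-study generating values, constant 30 nmol/mL:
  # agreement with the Euler oracle at 4 d
  S4 <- predict_survival(vr, sd_params(1.7, 0.126, 16.4, 0),
                         constant_profile(30, 4), c(0, 4))
  S4_oracle <- euler_survival("SD", FALSE, constant_profile(30, 4), c(0, 4),
                              k_d = 1.7, k_k = 0.126, z = 16.4)
  expect_equal(S4[2], S4_oracle[2], tolerance = 1e-4)
  expect_lt(S4[2], 0.05)  # strong effect well above threshold
})

test_that("individual-tolerance survival depends only on the running maximum", {
  vr <- model_variant("IT", "reduced")
  prm <- it_params(0.8, 18.7, 7.4, 0)
  # constant exposure: long-run survival tends to 1 - F(c)
  S_inf <- predict_survival(vr, prm, constant_profile(25, 80), 80)
  expect_equal(S_inf, 1 - loglogistic_cdf(25, 18.7, 7.4), tolerance = 1e-4)
  # appending sub-maximal exposure after the peak leaves F unchanged
  base <- exposure_profile(c(0, 1), c(28, 0), 6)
  extended <- exposure_profile(c(0, 1, 6), c(28, 0, 10), 12)
  F6 <- survival_it(vr, prm, base, c(0, 6))$threshold_cdf[2]
  F12 <- survival_it(vr, prm, extended, c(0, 6, 12))$threshold_cdf[3]
  expect_equal(F12, F6, tolerance = 1e-12)
  # identical pulses with a long recovery gap: no additional IT mortality
  # during the second pulse once damage has fully recovered
  vf <- model_variant("IT", "full", tk_study)
  prf <- it_params(0.6, 341.1, 2.4, 0)
  two <- exposure_profile(c(0, 1, 60, 61), c(28, 0, 28, 0), 120)
  tr <- survival_it(vf, prf, two, c(0, 59, 120))
  expect_equal(tr$survival[3], tr$survival[2], tolerance = 1e-6)
})

test_that("background survival follows the exponential closed form", {
  expect_equal(background_survival(0, c(0, 5, 50)), c(1, 1, 1))
  expect_equal(background_survival(-log(0.9) / 10, 10), 0.9)
  expect_equal(background_survival(0.01054, 4), exp(-0.01054 * 4))
  expect_equal(round(background_survival(0.01054, 4), 4), 0.9587)
  expect_error(background_survival(0.1, -1), "non-negative")
  expect_error(background_survival(-0.1, 1), "non-negative")
})

test_that("survival curves are valid and grid-independent for all variants", {
  set.seed(42)
  for (i in 1:16) {
    mech <- c("SD", "IT")[(i %% 2) + 1]
    full <- i %% 4 >= 2
    sc <- random_scenario(mech, full)
    fn <- if (mech == "SD") survival_sd else survival_it
    dense <- seq(0, max(sc$times), by = 0.5)
    tr <- fn(sc$variant, sc$params, sc$profile, dense)
    expect_true(all(tr$survival >= 0 & tr$survival <= 1))
    expect_true(all(diff(tr$survival) <= 1e-12))
    expect_equal(tr$survival[1], 1)
    if (mech == "SD") expect_true(all(diff(tr$cumulative_hazard) >= -1e-12))
    else expect_true(all(diff(tr$threshold_cdf) >= -1e-12))
    # doubling the observation density leaves shared times unchanged
    sparse <- fn(sc$variant, sc$params, sc$profile, sc$times)
    expect_lt(max(abs(sparse$survival -
                      tr$survival[match(sc$times, dense)])), 1e-6)
  }
})

test_that("reduced dose metric with k_d = k_out is the internal concentration rescaled by BAF", {
  # the lumped interpretation: C*int with the dominant rate set to k_out
  # equals C_int / BAF exactly
  p <- exposure_profile(c(0, 1, 3, 4), c(28, 0, 28, 0), 10)
  tt <- seq(0, 10, by = 0.25)
  m_reduced <- dose_metric(model_variant("SD", "reduced"),
                           sd_params(6.9, 1, 1), p, tt)
  cint <- simulate_internal(p, tk_study, tt)
  expect_equal(m_reduced, cint / baf(tk_study), tolerance = 1e-10)
})

test_that("equal-rate degeneracy k_d = k_out uses a stable limit form", {
  vf <- model_variant("SD", "full", tk_study)
  p <- pulse_profile(28, 1, 10)
  tt <- 0:10
  exact_eq <- predict_survival(vf, sd_params(6.9, 0.005, 10, 0), p, tt)
  near_eq <- predict_survival(vf, sd_params(6.9 + 1e-7, 0.005, 10, 0), p, tt)
  expect_equal(exact_eq, near_eq, tolerance = 1e-5)
  oracle <- euler_survival("SD", TRUE, p, tt, k_d = 6.9, k_in = 130.9,
                           k_out = 6.9, k_k = 0.005, z = 10)
  expect_lt(max(abs(exact_eq - oracle)), 1e-4)
})
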