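test_that("interval-censored log-likelihood matches hand-computed closed forms", {
  ll <- tktdsurv:::.ll_dataset
  # all alive at the last observation: censoring term y_n * log(S_n)
  expect_equal(ll(c(1, 0.5), c(10L, 10L)), 10 * log(0.5))
  # all die in the observed interval
  expect_equal(ll(c(1, 0.5), c(10L, 0L)), 10 * log(0.5))
  # flat stretch with no deaths: 0 * log(0) = 0
  expect_equal(ll(c(1, 0.6, 0.6), c(10L, 6L, 6L)), 4 * log(0.4) + 6 * log(0.6))
  expect_equal(round(ll(c(1, 0.6, 0.6), c(10L, 6L, 6L)), 4), -6.7301)
  # deaths in an interval of zero probability: -Inf, not an error
  expect_identical(ll(c(1, 1, 0.5), c(10L, 8L, 8L)), -Inf)
})

test_that("likelihood reduces to a binomial and is invariant to deathless splits", {
  ll <- tktdsurv:::.ll_dataset
  # single interval: multinomial term equals the binomial log-likelihood up
  # to the constant binomial coefficient
  y0 <- 10L; y1 <- 7L; S1 <- 0.64
  expect_equal(ll(c(1, S1), c(y0, y1)),
               dbinom(y1, y0, S1, log = TRUE) - lchoose(y0, y1))
  # splitting an interval at a time with no deaths and unchanged survival
  expect_equal(ll(c(1, 1, 0.4), c(10L, 10L, 3L)),
               ll(c(1, 0.4), c(10L, 3L)))
})

test_that("model log-likelihood sums over treatments", {
  vr <- model_variant("SD", "reduced")
  prm <- sd_params(1.7, 0.126, 16.4, hb_study)
  d1 <- generate_survival_data(vr, prm, pulse_profile(28, 1, 10), 70, seed = 1,
                               treatment_id = "a")
  d2 <- generate_survival_data(vr, prm, constant_profile(4.6, 10), 70, seed = 2,
                               treatment_id = "b")
  expect_equal(log_likelihood_survival(vr, prm, list(d1, d2)),
               log_likelihood_survival(vr, prm, d1) +
                 log_likelihood_survival(vr, prm, d2))
})

test_that("background hazard estimation matches the one-interval closed form", {
  clean <- constant_profile(0, 10)
  # 9 of 10 alive at day 10, single interval: MLE is log(10/9)/10
  d <- survival_dataset("ctrl", clean, c(0, 10), c(10L, 9L))
  est <- fit_background_hazard(d)
  expect_equal(est$h_b, log(10 / 9) / 10, tolerance = 1e-6)
  expect_false(est$boundary)
  # pooling two identical controls leaves the estimate unchanged
  est2 <- fit_background_hazard(list(d, d))
  expect_equal(est2$h_b, est$h_b, tolerance = 1e-6)
  # no deaths: boundary estimate zero, flagged
  d0 <- survival_dataset("ctrl0", clean, 0:10, rep(10L, 11))
  est0 <- fit_background_hazard(d0)
  expect_identical(est0$h_b, 0)
  expect_true(est0$boundary)
})

test_that("mean percentage error follows its definition", {
  expect_equal(mean_percentage_error(c(0.9, 0.5, 0.1), c(0.9, 0.5, 0.1)), 0)
  expect_equal(mean_percentage_error(1.0, 0.5), 100)
  expect_equal(mean_percentage_error(c(0.9, 0.4), c(1.0, 0.5)), 15.0)
  expect_error(mean_percentage_error(c(1, 1), c(1, 0)), "positive")
  expect_error(mean_percentage_error(1, c(1, 1)), "lengths")
})

test_that("two-step calibration recovers generating parameters from expected counts", {
  # deterministic expected survivor counts at large n; both reduced variants
  vr <- model_variant("SD", "reduced")
  gen_sd <- sd_params(1.7, 0.126, 16.4, hb_study)
  profiles <- list(A = exposure_profile(c(0, 1, 3, 4), c(28, 0, 28, 0), 10),
                   C = constant_profile(4.6, 10),
                   acute_hi = constant_profile(30, 4))
  mk_expected <- function(variant, prm) lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    tt <- 0:p$end_time
    S <- predict_survival(variant, prm, p, tt)
    survival_dataset(id, p, tt, round(1000 * cummin(S)))
  })
  fit_sd <- calibrate(vr, mk_expected(vr, gen_sd), h_b = hb_study,
                      n_starts = 2, seed = 5)
  expect_true(fit_sd$converged)
  expect_lt(max(abs(fit_sd$estimates - c(1.7, 0.126, 16.4)) /
                  c(1.7, 0.126, 16.4)), 0.05)
  vi <- model_variant("IT", "reduced")
  gen_it <- it_params(0.8, 18.7, 7.4, hb_study)
  fit_it <- calibrate(vi, mk_expected(vi, gen_it), h_b = hb_study,
                      n_starts = 2, seed = 6)
  expect_lt(max(abs(fit_it$estimates - c(0.8, 18.7, 7.4)) /
                  c(0.8, 18.7, 7.4)), 0.05)
})

test_that("profile bounds solve the quadratic benchmark and flag flat profiles", {
  # quadratic profile log-likelihood -(theta - 2)^2: bounds at 2 +/- sqrt(1.9207)
  b <- profile_bounds(function(th) -(th - 2)^2, mle = 2, max_ll = 0)
  expect_equal(unname(b), c(2 - sqrt(1.9207), 2 + sqrt(1.9207)),
               tolerance = 1e-4)
  # a profile that never drops is reported as not determined
  b2 <- profile_bounds(function(th) 0 * th, mle = 1, max_ll = 0,
                       max_steps = 20)
  expect_true(all(is.na(b2)))
})

test_that("zero treatment mortality leaves the threshold upper bound undetermined", {
  # no deaths at all: any threshold above the dose metric fits perfectly,
  # so the z profile is flat upward and the bound is not determined
  vr <- model_variant("SD", "reduced")
  none <- generate_survival_data(vr, sd_params(1.7, 0.126, 1e6, 0),
                                 pulse_profile(28, 1, 10), 70, seed = 3)
  expect_equal(unique(none$survivor_counts), 70L)
  fit <- calibrate(vr, list(none), h_b = 0, n_starts = 1, seed = 3)
  ci <- profile_ci(fit, "z", step_factor = 1.6)
  expect_true(is.na(ci[["upper"]]))
})

test_that("model comparison table totals per-group likelihoods", {
  vr <- model_variant("SD", "reduced")
  gen <- sd_params(1.7, 0.126, 16.4, hb_study)
  d <- generate_survival_data(vr, gen, pulse_profile(28, 1, 10), 70, seed = 8)
  fit <- calibrate(vr, list(d), h_b = hb_study, n_starts = 2, seed = 8,
                   calibration_set = "pulsed")
  cmp <- compare_models(list(fit), list(pulsed = list(d)))
  # evaluated on its own (only) calibration data: total equals the fit value
  expect_equal(cmp$total_log_likelihood, fit$log_likelihood, tolerance = 1e-9)
  expect_equal(cmp$log_likelihood_pulsed, fit$log_likelihood, tolerance = 1e-9)
  # a model predicting the observations exactly dominates any other
  frac <- d$survivor_counts / d$n_initial
  expect_gte(tktdsurv:::.ll_dataset(frac, d$survivor_counts),
             fit$log_likelihood)
})

test_that("survival CSV writer output is accepted by the reader unchanged", {
  vr <- model_variant("SD", "reduced")
  gen <- sd_params(1.7, 0.126, 16.4, hb_study)
  profs <- list(A = pulse_profile(28, 1, 10), C = constant_profile(4.6, 10))
  ds <- lapply(names(profs), function(id)
    generate_survival_data(vr, gen, profs[[id]], 70, seed = 4,
                           treatment_id = id))
  f <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(ds, f)
  back <- read_survival_csv(f, profs)
  for (d in ds) {
    expect_equal(back[[d$treatment_id]]$survivor_counts, d$survivor_counts)
    expect_equal(back[[d$treatment_id]]$observation_times,
                 d$observation_times)
  }
})
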