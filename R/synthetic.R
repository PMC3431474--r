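#' Study design for the synthetic-data generator
#'
#' Describes the pulsed, constant, acute and toxicokinetic exposure
#' scenarios of a pulsed-toxicity study on *Gammarus pulex*: two-pulse
#' treatments (1-d pulses at 28 nmol/mL, separated by a 2-d or 6-d recovery
#' period, 10 d total), a constant treatment at the corresponding
#' time-weighted average concentration (4.6 nmol/mL), a 7-concentration 4-d
#' acute series (8.2-37.4 nmol/mL), and two TK exposures (1 d at 8.7
#' nmol/mL followed by 5 d or 1 d of depuration), with ten organisms per
#' beaker and daily observations.
#'
#' @param pulse_concentration pulsed-treatment concentration (nmol/mL).
#' @param pulse_duration pulse length (days).
#' @param gap_a,gap_b recovery period between pulses in treatments A and B
#'   (days).
#' @param pulsed_duration total length of the pulsed experiment (days).
#' @param constant_concentration treatment C concentration (nmol/mL).
#' @param acute_concentrations acute-series concentrations (nmol/mL).
#' @param acute_duration acute test length (days).
#' @param tk_concentration TK exposure concentration (nmol/mL).
#' @param tk1_depuration,tk2_depuration depuration lengths of experiments
#'   TK1 and TK2 (days).
#' @param n_per_beaker organisms per beaker.
#' @param replicates_pulsed,replicates_acute beakers per pulsed treatment /
#'   per acute concentration.
#' @return An object of class `study_design`.
#' @export
study_design <- function(pulse_concentration = 28,
                         pulse_duration = 1,
                         gap_a = 2,
                         gap_b = 6,
                         pulsed_duration = 10,
                         constant_concentration = 4.6,
                         acute_concentrations = c(8.2, 13.1, 17.9, 22.8,
                                                  27.6, 32.5, 37.4),
                         acute_duration = 4,
                         tk_concentration = 8.7,
                         tk1_depuration = 5,
                         tk2_depuration = 1,
                         n_per_beaker = 10,
                         replicates_pulsed = 7,
                         replicates_acute = 2) {
  stopifnot(pulse_concentration >= 0, constant_concentration >= 0,
            all(acute_concentrations >= 0), tk_concentration >= 0,
            pulse_duration > 0, n_per_beaker >= 1)
  structure(list(pulse_concentration = pulse_concentration,
                 pulse_duration = pulse_duration,
                 gap_a = gap_a, gap_b = gap_b,
                 pulsed_duration = pulsed_duration,
                 constant_concentration = constant_concentration,
                 acute_concentrations = acute_concentrations,
                 acute_duration = acute_duration,
                 tk_concentration = tk_concentration,
                 tk1_depuration = tk1_depuration,
                 tk2_depuration = tk2_depuration,
                 n_per_beaker = n_per_beaker,
                 replicates_pulsed = replicates_pulsed,
                 replicates_acute = replicates_acute),
            class = "study_design")
}

#' Exposure profiles of the study design
#'
#' Deterministic step profiles for the pulsed treatments A (pulses at
#' `[0,1)` and `[3,4)` by default) and B (second pulse after the longer
#' gap), the constant-TWA treatment C, the acute concentration series and
#' the two TK experiments.
#'
#' @param design a [study_design()].
#' @return Named list of [exposure_profile()] objects: `A`, `B`, `C`,
#'   `acute_1` ... `acute_k`, `TK1`, `TK2`.
#' @export
make_study_profiles <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  pd <- design$pulse_duration
  two_pulse <- function(gap) {
    t2 <- pd + gap
    exposure_profile(c(0, pd, t2, t2 + pd),
                     c(design$pulse_concentration, 0,
                       design$pulse_concentration, 0),
                     design$pulsed_duration)
  }
  profiles <- list(
    A = two_pulse(design$gap_a),
    B = two_pulse(design$gap_b),
    C = constant_profile(design$constant_concentration,
                         design$pulsed_duration))
  for (i in seq_along(design$acute_concentrations))
    profiles[[paste0("acute_", i)]] <-
      constant_profile(design$acute_concentrations[i], design$acute_duration)
  profiles$TK1 <- pulse_profile(design$tk_concentration, pd,
                                pd + design$tk1_depuration)
  profiles$TK2 <- pulse_profile(design$tk_concentration, pd,
                                pd + design$tk2_depuration)
  profiles
}

#' Generate noisy toxicokinetic observations
#'
#' Simulates internal concentrations along a profile and multiplies them by
#' lognormal noise with a given coefficient of variation.
#'
#' @param profile an [exposure_profile()].
#' @param params a [tk_params()].
#' @param cv coefficient of variation of the multiplicative noise, >= 0.
#' @param times sampling times (days); default daily plus mid-pulse points.
#' @param seed integer seed (optional).
#' @return A [tk_observations()] object.
#' @export
generate_tk_data <- function(profile, params, cv = 0.15, times = NULL,
                             seed = NULL) {
  stopifnot(cv >= 0)
  if (is.null(times)) {
    # emulate the study's TK sampling: within-pulse points at ~5, 10, 24 h,
    # early-depuration points, then daily until the end of the experiment
    cand <- c(0.21, 0.42, 1, 1.21, 1.42, seq(2, profile$end_time, by = 1),
              profile$end_time)
    times <- sort(unique(cand[cand <= profile$end_time & cand > 0]))
  }
  mu <- simulate_internal(profile, params, times)
  noise <- if (cv == 0) rep(1, length(times)) else {
    sdlog <- sqrt(log(1 + cv^2))
    .with_seed(seed, stats::rlnorm(length(times), -sdlog^2 / 2, sdlog))
  }
  tk_observations(times, mu * noise, profile)
}

#' Generate a stochastic survival dataset
#'
#' Samples survivor counts sequentially by conditional binomial thinning:
#' `y_i ~ Binomial(y_{i-1}, S_i / S_{i-1})`, the population-level
#' distribution implied by independent individuals under either death
#' mechanism. Counts are non-increasing by construction.
#'
#' @param variant a [model_variant()].
#' @param params an [sd_params()] or [it_params()] matching the variant.
#' @param profile an [exposure_profile()].
#' @param n_initial initial number of organisms.
#' @param observation_times observation schedule (days), starting at 0.
#' @param seed integer seed (optional).
#' @param treatment_id label for the resulting dataset.
#' @return A [survival_dataset()].
#' @export
generate_survival_data <- function(variant, params, profile, n_initial = 10,
                                   observation_times = NULL, seed = NULL,
                                   treatment_id = "synthetic") {
  stopifnot(n_initial >= 1)
  if (is.null(observation_times))
    observation_times <- seq(0, profile$end_time, by = 1)
  S <- predict_survival(variant, params, profile, observation_times)
  S <- pmax(S, .PROB_FLOOR)
  y <- integer(length(S))
  y[1L] <- n_initial
  .with_seed(seed, {
    for (i in seq_along(S)[-1L]) {
      p <- min(S[i] / S[i - 1L], 1)
      y[i] <- stats::rbinom(1L, y[i - 1L], p)
    }
  })
  survival_dataset(treatment_id, profile, observation_times, y)
}

#' Generate a full synthetic study
#'
#' Simulates the whole experimental campaign under one generating model:
#' survivor counts for the pulsed treatments A, B and the constant-TWA
#' treatment C (with background mortality), the acute concentration series
#' (no background mortality over the short test, matching the near-full
#' control survival of acute tests), control beakers (background hazard
#' only), and the two TK datasets.
#'
#' @param variant the generating [model_variant()].
#' @param params the generating [sd_params()] or [it_params()] (its `h_b`
#'   is used for the pulsed treatments and controls).
#' @param tk the generating [tk_params()] for the TK datasets.
#' @param design a [study_design()].
#' @param seed integer seed; sub-seeds are derived per dataset.
#' @param n_per_treatment organisms per treatment dataset (defaults to
#'   `n_per_beaker * replicates` of the design; replicate beakers are
#'   pooled, matching how the likelihood treats a treatment).
#' @param tk_cv coefficient of variation of TK measurement noise.
#' @return A list with elements `pulsed` (datasets A, B, C), `acute`
#'   (one dataset per concentration), `controls`, `tk` (TK1, TK2
#'   observations) and `profiles`.
#' @export
generate_study <- function(variant, params, tk = tk_params(130.9, 6.9),
                           design = study_design(), seed = 1,
                           n_per_treatment = NULL, tk_cv = 0.15) {
  profiles <- make_study_profiles(design)
  n_pulsed <- n_per_treatment %||%
    (design$n_per_beaker * design$replicates_pulsed)
  n_acute <- n_per_treatment %||%
    (design$n_per_beaker * design$replicates_acute)
  sub <- function(k) (seed * 97L + k) %% .Machine$integer.max
  pulsed <- lapply(seq_along(c("A", "B", "C")), function(i) {
    id <- c("A", "B", "C")[i]
    generate_survival_data(variant, params, profiles[[id]], n_pulsed,
                           seed = sub(i), treatment_id = id)
  })
  names(pulsed) <- c("A", "B", "C")
  acute_ids <- grep("^acute_", names(profiles), value = TRUE)
  acute_params <- .set_hb(params, 0)  # 4-d test: negligible background
  acute <- lapply(seq_along(acute_ids), function(i) {
    generate_survival_data(variant, acute_params, profiles[[acute_ids[i]]],
                           n_acute, seed = sub(10L + i),
                           treatment_id = acute_ids[i])
  })
  names(acute) <- acute_ids
  ctrl_profile <- constant_profile(0, design$pulsed_duration)
  controls <- lapply(1:2, function(i)
    generate_survival_data(variant, params, ctrl_profile, n_pulsed,
                           seed = sub(20L + i),
                           treatment_id = paste0("control_", i)))
  tk_data <- list(
    TK1 = generate_tk_data(profiles$TK1, tk, cv = tk_cv, seed = sub(31L)),
    TK2 = generate_tk_data(profiles$TK2, tk, cv = tk_cv, seed = sub(32L)))
  list(pulsed = pulsed, acute = acute, controls = controls, tk = tk_data,
       profiles = profiles)
}

# copy of params with a different background hazard
.set_hb <- function(params, h_b) {
  if (inherits(params, "sd_params"))
    sd_params(params$k_d, params$k_k, params$z, h_b)
  else
    it_params(params$k_d, params$alpha, params$beta, h_b)
}
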