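#' Calibrate the full variant-by-calibration-data grid
#'
#' Runs the complete model-comparison experiment: fits the background
#' hazard from controls, fixes the TK parameters, and calibrates every
#' requested combination of death mechanism (SD, IT), TK inclusion (full,
#' reduced) and calibration set (pulsed, acute, both). Returns the fits and
#' the goodness-of-fit comparison table (per-group log-likelihood, total
#' likelihood, MPE).
#'
#' @param pulsed list of pulsed-treatment [survival_dataset()] objects.
#' @param acute list of acute-series [survival_dataset()] objects.
#' @param controls list of control [survival_dataset()] objects.
#' @param tk a [tk_params()] object (pre-calibrated, e.g. by [fit_tk()]).
#' @param mechanisms,tk_inclusions,calibration_sets grid axes.
#' @param n_starts optimizer starts per calibration.
#' @param seed integer seed (restarts are derived from it).
#' @return A list with `fits` (named list of [calibrate()] results, names
#'   like `"SD_reduced_both"`), `comparison` (data frame), `h_b`.
#' @export
run_model_grid <- function(pulsed, acute, controls, tk,
                           mechanisms = c("SD", "IT"),
                           tk_inclusions = c("full", "reduced"),
                           calibration_sets = c("pulsed", "acute", "both"),
                           n_starts = 5, seed = 1) {
  stopifnot(inherits(tk, "tk_params"))
  hb_fit <- fit_background_hazard(controls)
  h_b <- hb_fit$h_b
  groups <- list(pulsed = pulsed, acute = acute)
  fits <- list()
  k <- 0L
  for (mech in mechanisms) for (tki in tk_inclusions) {
    variant <- model_variant(mech, tki,
                             tk_params = if (tki == "full") tk else NULL)
    # run "both" last within a variant so its optimizer can also start from
    # the single-set solutions (its total likelihood must dominate theirs)
    for (cs in calibration_sets[order(calibration_sets == "both")]) {
      k <- k + 1L
      data_cs <- switch(cs, pulsed = pulsed, acute = acute,
                        both = c(pulsed, acute),
                        stop("unknown calibration set ", cs))
      extra <- if (cs == "both") {
        sibs <- fits[paste(mech, tki, setdiff(calibration_sets, "both"),
                           sep = "_")]
        lapply(sibs[!vapply(sibs, is.null, TRUE)],
               function(f) f$estimates)
      }
      fits[[paste(mech, tki, cs, sep = "_")]] <-
        calibrate(variant, data_cs, h_b = h_b, n_starts = n_starts,
                  seed = seed * 1000L + k, calibration_set = cs,
                  extra_starts = extra)
    }
  }
  list(fits = fits, comparison = compare_models(fits, groups), h_b = h_b)
}

.require_fields <- function(x, fields, where) {
  missing <- setdiff(fields, names(x))
  if (length(missing))
    stop("configuration error in '", where, "': missing field(s) ",
         paste(missing, collapse = ", "))
}

.variant_from_config <- function(cfg, tk) {
  model_variant(cfg$death_mechanism, cfg$tk_included,
                tk_params = if (cfg$tk_included == "full") tk else NULL)
}

.params_from_config <- function(cfg) {
  p <- cfg$params
  if (cfg$death_mechanism == "SD") {
    .require_fields(p, c("k_d", "k_k", "z"), "generate$params")
    sd_params(p$k_d, p$k_k, p$z, p$h_b %||% 0)
  } else {
    .require_fields(p, c("k_d", "alpha", "beta"), "generate$params")
    it_params(p$k_d, p$alpha, p$beta, p$h_b %||% 0)
  }
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the whole analysis from a single configuration: generate a
#' synthetic study (or read CSV data), fit background hazard and TK,
#' calibrate the variant grid, compare models, compute recovery times and
#' the daily LC50 profile, and optionally write a machine-readable JSON
#' report recording every estimate, likelihood, setting and seed.
#'
#' @param config a named list or the path of a YAML file. Required fields:
#'   `seed`; either `generate` (with `death_mechanism`, `tk_included`,
#'   `params`, `tk`) or `data` (with `survival_csv`, `exposure_dir`,
#'   `pulsed_treatments`, `acute_treatments`, `control_treatments`).
#'   Optional: `n_starts`, `mechanisms`, `tk_inclusions`,
#'   `calibration_sets`, `out` (report path).
#' @return The report as a list (invisibly written to `config$out` as JSON
#'   when given): elements `seed`, `h_b`, `tk_fit`, `fits`, `comparison`,
#'   `recovery_times`, `lc50_by_day`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .require_fields(config, "seed", "config")
  seed <- as.integer(config$seed)

  if (!is.null(config$generate)) {
    g <- config$generate
    .require_fields(g, c("death_mechanism", "tk_included", "params", "tk"),
                    "generate")
    tk_gen <- tk_params(g$tk$k_in, g$tk$k_out)
    variant_gen <- .variant_from_config(g, tk_gen)
    params_gen <- .params_from_config(g)
    study <- generate_study(variant_gen, params_gen, tk = tk_gen, seed = seed)
    pulsed <- study$pulsed; acute <- study$acute; controls <- study$controls
    tk_fit <- fit_tk(study$tk)
  } else if (!is.null(config$data)) {
    d <- config$data
    .require_fields(d, c("survival_csv", "exposure_dir", "pulsed_treatments",
                         "acute_treatments", "control_treatments"), "data")
    all_tr <- c(d$pulsed_treatments, d$acute_treatments, d$control_treatments)
    profiles <- stats::setNames(lapply(all_tr, function(tr)
      read_exposure_csv(file.path(d$exposure_dir, paste0(tr, ".csv")))),
      all_tr)
    datasets <- read_survival_csv(d$survival_csv, profiles)
    pulsed <- datasets[d$pulsed_treatments]
    acute <- datasets[d$acute_treatments]
    controls <- datasets[d$control_treatments]
    if (!is.null(d$tk_csv)) {
      .require_fields(d, "tk_exposure_csv", "data")
      tk_profile <- read_exposure_csv(d$tk_exposure_csv)
      tk_fit <- fit_tk(read_tk_csv(d$tk_csv, tk_profile))
    } else {
      .require_fields(d, "tk_params", "data")
      tk_fit <- list(params = tk_params(d$tk_params$k_in, d$tk_params$k_out),
                     estimates = unlist(d$tk_params), converged = TRUE)
    }
  } else {
    stop("configuration error: need either 'generate' or 'data'")
  }

  grid <- run_model_grid(
    pulsed, acute, controls, tk_fit$params,
    mechanisms = config$mechanisms %||% c("SD", "IT"),
    tk_inclusions = config$tk_inclusions %||% c("full", "reduced"),
    calibration_sets = config$calibration_sets %||%
      c("pulsed", "acute", "both"),
    n_starts = config$n_starts %||% 5, seed = seed)

  recovery <- recovery_table(grid$fits)
  lc50 <- lc_profile_over_days(acute)

  report <- list(
    seed = seed,
    settings = list(n_starts = config$n_starts %||% 5,
                    optimizer = "Nelder-Mead on log-parameters",
                    step1 = "Levenberg-Marquardt least squares"),
    h_b = grid$h_b,
    tk_fit = list(estimates = as.list(tk_fit$estimates),
                  converged = tk_fit$converged),
    fits = lapply(grid$fits, function(f) list(
      death_mechanism = f$variant$death_mechanism,
      tk_included = f$variant$tk_included,
      calibration_set = f$calibration_set,
      estimates = as.list(f$estimates),
      log_likelihood = f$log_likelihood,
      converged = f$converged,
      n_evaluations = f$n_evaluations,
      seed = f$seed)),
    comparison = grid$comparison,
    recovery_times = recovery,
    lc50_by_day = lc50)
  if (!is.null(config$out)) {
    dir.create(dirname(config$out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  report
}
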