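#' Survivor-count dataset for one treatment
#'
#' Per-treatment survival time series: the number of live organisms at each
#' observation time, together with the exposure profile of the treatment.
#'
#' @param treatment_id character label.
#' @param profile the treatment's [exposure_profile()].
#' @param observation_times numeric vector (days), strictly increasing,
#'   first element 0, within the profile domain.
#' @param survivor_counts non-negative integers, non-increasing; the first
#'   element is the initial number of organisms.
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(treatment_id, profile, observation_times,
                             survivor_counts) {
  stopifnot(inherits(profile, "exposure_profile"))
  t <- as.numeric(observation_times)
  y <- as.integer(round(survivor_counts))
  if (length(t) != length(y)) stop("times and counts differ in length")
  if (length(t) < 2L) stop("need at least two observation times")
  if (t[1L] != 0) stop("observation times must start at 0")
  if (any(diff(t) <= 0)) stop("observation times must be strictly increasing")
  if (t[length(t)] > profile$end_time)
    stop("observation times outside the profile domain")
  if (any(y < 0) || any(diff(y) > 0))
    stop("survivor counts must be non-negative and non-increasing")
  structure(list(treatment_id = as.character(treatment_id), profile = profile,
                 observation_times = t, survivor_counts = y,
                 n_initial = y[1L]),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset '%s': %d organisms, %d observations over %g d\n",
              x$treatment_id, x$n_initial, length(x$observation_times),
              max(x$observation_times)))
  invisible(x)
}

#' Read survival datasets from CSV
#'
#' Expects columns `treatment`, `time_d`, `survivors`; one dataset per
#' distinct treatment label. Exposure profiles are supplied as a named list
#' keyed by treatment label.
#'
#' @param path CSV file path.
#' @param profiles named list of [exposure_profile()] objects.
#' @return A list of [survival_dataset()] objects.
#' @export
read_survival_csv <- function(path, profiles) {
  d <- utils::read.csv(path)
  if (!all(c("treatment", "time_d", "survivors") %in% names(d)))
    stop("survival CSV needs columns treatment, time_d, survivors")
  lapply(split(d, d$treatment), function(g) {
    g <- g[order(g$time_d), ]
    id <- as.character(g$treatment[1L])
    if (is.null(profiles[[id]]))
      stop("no exposure profile supplied for treatment ", id)
    survival_dataset(id, profiles[[id]], g$time_d, g$survivors)
  })
}

#' Write survival datasets to CSV
#'
#' @param datasets a [survival_dataset()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(datasets, path) {
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  d <- do.call(rbind, lapply(datasets, function(x)
    data.frame(treatment = x$treatment_id, time_d = x$observation_times,
               survivors = x$survivor_counts)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  eval.parent(substitute(expr))
}

.PROB_FLOOR <- 1e-12

# multinomial interval log-likelihood for one dataset given S at obs times
.ll_dataset <- function(S, y) {
  Sx <- c(S, 0)            # S_{n+1} = 0: survivors past t_n die in (t_n, Inf)
  yx <- c(y, 0L)
  deaths <- -diff(yx)
  p <- -diff(Sx)
  if (any(p <= 0 & deaths > 0)) return(-Inf)
  terms <- ifelse(deaths == 0, 0, deaths * log(pmax(p, .PROB_FLOOR)))
  sum(terms)
}

#' Multinomial survival log-likelihood
#'
#' Interval-censored death-count log-likelihood
#' `sum_i (y_{i-1} - y_i) * log(S_{i-1} - S_i)`, with the censoring
#' convention `S_{n+1} = 0`, `y_{n+1} = 0` (animals alive at the last
#' observation die in `(t_n, Inf)`, contributing `y_n * log(S_n)`).
#' Per-treatment log-likelihoods are summed. `0 * log(0)` is 0; positive
#' death counts in an interval of exactly zero probability give `-Inf`;
#' otherwise interval probabilities are floored at 1e-12 before the log.
#'
#' @param variant a [model_variant()].
#' @param params an [sd_params()] or [it_params()] matching the variant.
#' @param datasets a [survival_dataset()] or list of them.
#' @return The summed log-likelihood (possibly `-Inf`).
#' @export
log_likelihood_survival <- function(variant, params, datasets) {
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  sum(vapply(datasets, function(d) {
    S <- predict_survival(variant, params, d$profile, d$observation_times)
    .ll_dataset(S, d$survivor_counts)
  }, 0))
}

#' Fit the background hazard rate from control data
#'
#' Maximum-likelihood estimate of the constant background hazard h_b under
#' exponential background survival, using the interval-censored count
#' likelihood pooled across all control datasets.
#'
#' @param controls a [survival_dataset()] or list of them (typically
#'   non-solvent and solvent controls combined).
#' @param upper search upper bound for h_b (d^-1).
#' @return A list with `h_b`, `log_likelihood` and `boundary` (`TRUE` when
#'   no deaths occurred and the estimate sits at the h_b = 0 boundary).
#' @export
fit_background_hazard <- function(controls, upper = 10) {
  if (inherits(controls, "survival_dataset")) controls <- list(controls)
  stopifnot(length(controls) >= 1L,
            all(vapply(controls, inherits, TRUE, "survival_dataset")))
  ll <- function(h) sum(vapply(controls, function(d)
    .ll_dataset(exp(-h * d$observation_times), d$survivor_counts), 0))
  deaths <- sum(vapply(controls, function(d)
    d$n_initial - min(d$survivor_counts), 0L))
  if (deaths == 0L)
    return(list(h_b = 0, log_likelihood = ll(0), boundary = TRUE))
  # coarse log-spaced bracket first: the floored likelihood is flat far from
  # the optimum, which can strand a plain golden-section search
  grid <- exp(seq(log(1e-6), log(upper), length.out = 60))
  vals <- vapply(grid, ll, 0)
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-12)
  list(h_b = opt$maximum, log_likelihood = opt$objective, boundary = FALSE)
}

#' Mean percentage error of survival predictions
#'
#' MPE = 100/n * sum(|S_obs - S_model| / S_model), comparing observed and
#' modelled survivor fractions.
#'
#' @param s_obs observed survivor fractions.
#' @param s_model modelled survivor fractions, all > 0.
#' @return MPE in percent.
#' @export
mean_percentage_error <- function(s_obs, s_model) {
  if (length(s_obs) != length(s_model)) stop("lengths differ")
  if (any(!is.finite(s_model)) || any(s_model <= 0))
    stop("all model survival values must be positive")
  100 * mean(abs(s_obs - s_model) / s_model)
}

# ---- free-parameter plumbing ----------------------------------------------

.free_names <- function(mechanism) {
  if (mechanism == "SD") c("k_d", "k_k", "z") else c("k_d", "alpha", "beta")
}

.make_params <- function(mechanism, theta, h_b) {
  if (mechanism == "SD")
    sd_params(theta[[1L]], theta[[2L]], theta[[3L]], h_b)
  else
    it_params(theta[[1L]], theta[[2L]], theta[[3L]], h_b)
}

# objective evaluations happen on the log scale to keep parameters positive
.neg_ll <- function(logtheta, variant, datasets, h_b) {
  theta <- exp(logtheta)
  if (any(!is.finite(theta))) return(1e10)
  ll <- log_likelihood_survival(
    variant, .make_params(variant$death_mechanism, theta, h_b), datasets)
  if (!is.finite(ll)) 1e10 else -ll
}

# default starting values from the scale of the data
.default_init <- function(variant, datasets, h_b) {
  k_d0 <- 1
  mx <- vapply(datasets, function(d)
    max(dose_metric(variant, list(k_d = k_d0), d$profile,
                    d$observation_times)), 0)
  m <- max(stats::median(mx), 1e-3)
  Tmax <- max(vapply(datasets, function(d) max(d$observation_times), 0))
  if (variant$death_mechanism == "SD")
    c(k_d = k_d0, k_k = 1 / (m * Tmax), z = 0.5 * m)
  else
    c(k_d = k_d0, alpha = m, beta = 2)
}

#' Calibrate a TKTD survival model variant
#'
#' Two-step maximum-likelihood calibration on interval-censored survivor
#' counts. Step 1 fits the model survival curves to observed survivor
#' fractions by least squares (Levenberg-Marquardt); the step-1 estimates
#' seed step 2, which maximizes the multinomial log-likelihood
#' (Nelder-Mead on log-parameters). Optionally several jittered restarts
#' are run and the best likelihood kept; the background hazard and, for
#' full variants, the TK parameters are fixed beforehand. Free parameters:
#' (k_d, k_k, z) for SD, (k_d, alpha, beta) for IT.
#'
#' @param variant a [model_variant()].
#' @param datasets a list of [survival_dataset()] objects (the calibration
#'   data; controls should not be included — fit h_b first with
#'   [fit_background_hazard()]).
#' @param h_b pre-fitted background hazard rate (d^-1).
#' @param init optional named numeric vector of starting values for the
#'   free parameters.
#' @param n_starts number of optimizer starts (first from step 1, the rest
#'   jittered), default 5.
#' @param seed integer seed for the jittered restarts (optional).
#' @param calibration_set optional label (`"pulsed"`, `"acute"`, `"both"`,
#'   ...) recorded in the result.
#' @param extra_starts optional list of named parameter vectors used as
#'   additional step-2 starting points (e.g. estimates from related fits).
#' @return An object of class `tktd_fit`: list with `estimates` (named),
#'   `log_likelihood`, `profile_ci_95` (filled by [profile_cis()]),
#'   `converged`, `n_evaluations`, `variant`, `h_b`, `seed`, `datasets`.
#' @export
calibrate <- function(variant, datasets, h_b, init = NULL, n_starts = 5,
                      seed = NULL, calibration_set = NULL,
                      extra_starts = NULL) {
  stopifnot(inherits(variant, "model_variant"))
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  mech <- variant$death_mechanism
  pn <- .free_names(mech)
  if (is.null(init)) init <- .default_init(variant, datasets, h_b)
  init <- init[pn]
  if (any(!is.finite(init)) || any(init <= 0))
    stop("initial values must be positive for ", paste(pn, collapse = ", "))

  # step 1: least squares against observed survivor fractions
  obs_frac <- lapply(datasets, function(d) d$survivor_counts / d$n_initial)
  resid_fn <- function(logtheta) {
    theta <- exp(logtheta)
    unlist(lapply(seq_along(datasets), function(i) {
      d <- datasets[[i]]
      predict_survival(variant, .make_params(mech, theta, h_b),
                       d$profile, d$observation_times) - obs_frac[[i]]
    }))
  }
  ls_fit <- try(minpack.lm::nls.lm(
    par = log(init), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  start1 <- if (inherits(ls_fit, "try-error")) log(init) else ls_fit$par

  # step 2: maximum likelihood, multi-start
  starts <- list(start1)
  for (es in extra_starts) starts <- c(starts, list(log(es[pn])))
  if (n_starts > 1L) {
    jit <- .with_seed(seed, lapply(seq_len(n_starts - 1L), function(i)
      start1 + stats::rnorm(length(pn), sd = 0.5)))
    starts <- c(starts, jit)
  }
  best <- NULL
  n_eval <- 0L
  for (st in starts) {
    opt <- stats::optim(st, .neg_ll, variant = variant, datasets = datasets,
                        h_b = h_b, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-10))
    n_eval <- n_eval + opt$counts[1L]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  est <- exp(best$par)
  names(est) <- pn
  structure(list(
    estimates = est,
    log_likelihood = -best$value,
    profile_ci_95 = NULL,
    converged = best$convergence == 0 && best$value < 1e9,
    n_evaluations = n_eval,
    n_starts = n_starts,
    variant = variant,
    h_b = h_b,
    seed = seed,
    calibration_set = calibration_set,
    datasets = datasets), class = "tktd_fit")
}

#' @export
print.tktd_fit <- function(x, ...) {
  cat(sprintf("TKTD fit: %s-%s%s\n", x$variant$tk_included,
              x$variant$death_mechanism,
              if (!is.null(x$calibration_set))
                paste0(" (", x$calibration_set, " data)") else ""))
  for (nm in names(x$estimates)) {
    ci <- ""
    if (!is.null(x$profile_ci_95)) {
      b <- x$profile_ci_95[nm, ]
      ci <- sprintf("  (%s-%s)",
                    ifelse(is.na(b[1L]), "n.d.", sprintf("%.4g", b[1L])),
                    ifelse(is.na(b[2L]), "n.d.", sprintf("%.4g", b[2L])))
    }
    cat(sprintf("  %-6s = %10.5g%s\n", nm, x$estimates[[nm]], ci))
  }
  cat(sprintf("  log-likelihood = %.4f; h_b = %.4g; converged: %s\n",
              x$log_likelihood, x$h_b, x$converged))
  invisible(x)
}

#' Profile-likelihood bounds of a one-parameter log-likelihood profile
#'
#' Walks a positive parameter outward from its maximum-likelihood value on
#' a log-spaced grid and locates, by bisection between grid points, where
#' the profile log-likelihood drops `drop` (default 1.9207, half the 95%
#' chi-square(1) quantile) below the maximum. A bound that is not reached
#' within `max_steps` grid steps is reported as `NA` ("not determined",
#' e.g. a threshold above every dose metric has no upper effect on the
#' likelihood).
#'
#' @param profile_ll function of the parameter value returning the profile
#'   log-likelihood (other parameters already re-optimized).
#' @param mle maximum-likelihood value of the parameter (> 0).
#' @param max_ll log-likelihood at the joint maximum.
#' @param drop log-likelihood drop defining the confidence bound.
#' @param step_factor multiplicative grid step (> 1).
#' @param max_steps maximum grid steps per direction.
#' @return Numeric `c(lower, upper)`; `NA` marks a not-determined bound.
#' @export
profile_bounds <- function(profile_ll, mle, max_ll, drop = 1.9207,
                           step_factor = 1.2, max_steps = 60) {
  stopifnot(is.finite(mle), mle > 0, is.finite(max_ll))
  target <- max_ll - drop
  walk <- function(direction) {
    prev <- mle
    prev_ll <- max_ll
    for (i in seq_len(max_steps)) {
      cur <- if (direction > 0) prev * step_factor else prev / step_factor
      cur_ll <- profile_ll(cur)
      if (!is.finite(cur_ll) || cur_ll < target) {
        g <- function(v) {
          v_ll <- profile_ll(v)
          if (!is.finite(v_ll)) v_ll <- target - drop  # below target
          v_ll - target
        }
        lo <- min(prev, cur); hi <- max(prev, cur)
        return(stats::uniroot(g, c(lo, hi), tol = mle * 1e-6)$root)
      }
      prev <- cur
      prev_ll <- cur_ll
    }
    NA_real_
  }
  c(lower = walk(-1), upper = walk(+1))
}

#' Profile-likelihood 95% confidence interval for one parameter
#'
#' Re-optimizes all other free parameters at each grid value of the target
#' parameter (warm-started from the previous solution) and applies
#' [profile_bounds()].
#'
#' @param fit a [calibrate()] result.
#' @param parameter_name one of the fit's free parameter names.
#' @param drop log-likelihood drop defining the bound (default 1.9207).
#' @param step_factor multiplicative profile grid step.
#' @return Numeric `c(lower, upper)`; `NA` marks a not-determined bound.
#' @export
profile_ci <- function(fit, parameter_name, drop = 1.9207,
                       step_factor = 1.2) {
  stopifnot(inherits(fit, "tktd_fit"))
  pn <- names(fit$estimates)
  if (!parameter_name %in% pn) stop("unknown parameter ", parameter_name)
  j <- match(parameter_name, pn)
  others0 <- log(fit$estimates[-j])
  warm <- new.env()
  warm$par <- others0
  warm$last <- fit$estimates[[j]]
  profile_ll <- function(value) {
    # warm-start from the neighbouring profile point; reset to the MLE
    # solution when the walk jumps (e.g. switching direction)
    if (abs(log(value) - log(warm$last)) > 1.5 * log(step_factor))
      warm$par <- others0
    obj <- function(lo) {
      theta <- numeric(length(pn))
      theta[j] <- value
      theta[-j] <- exp(lo)
      ll <- log_likelihood_survival(
        fit$variant,
        .make_params(fit$variant$death_mechanism, theta, fit$h_b),
        fit$datasets)
      if (!is.finite(ll)) 1e10 else -ll
    }
    opt <- stats::optim(warm$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9))
    warm$par <- opt$par
    warm$last <- value
    -opt$value
  }
  profile_bounds(profile_ll, fit$estimates[[j]], fit$log_likelihood,
                 drop = drop, step_factor = step_factor)
}

#' Profile-likelihood intervals for all free parameters
#'
#' @param fit a [calibrate()] result.
#' @param ... passed to [profile_ci()].
#' @return The fit with `profile_ci_95` filled in (matrix with one row per
#'   parameter, columns `lower`, `upper`; `NA` = not determined).
#' @export
profile_cis <- function(fit, ...) {
  stopifnot(inherits(fit, "tktd_fit"))
  pn <- names(fit$estimates)
  ci <- t(vapply(pn, function(nm) profile_ci(fit, nm, ...), numeric(2L)))
  dimnames(ci) <- list(pn, c("lower", "upper"))
  fit$profile_ci_95 <- ci
  fit
}

#' Compare fitted models across data groups
#'
#' Builds the goodness-of-fit table for a set of calibrated models: for
#' each fit, the log-likelihood on each data group (the group it was fitted
#' to and the held-out group), the total likelihood (their sum), and the
#' mean percentage error per group. For a model calibrated on "both", the
#' fit likelihood already spans both groups and the total equals it.
#'
#' @param fits list of [calibrate()] results (each carrying its variant and
#'   calibration-set label).
#' @param data_groups named list of dataset lists, e.g.
#'   `list(pulsed = ..., acute = ...)`.
#' @return A data frame with one row per fit: variant descriptors,
#'   calibration set, per-group log-likelihoods and MPEs, and
#'   `total_log_likelihood`.
#' @export
compare_models <- function(fits, data_groups) {
  stopifnot(length(fits) >= 1L, is.list(data_groups),
            !is.null(names(data_groups)))
  rows <- lapply(fits, function(fit) {
    stopifnot(inherits(fit, "tktd_fit"))
    params <- .make_params(fit$variant$death_mechanism, fit$estimates, fit$h_b)
    out <- data.frame(death_mechanism = fit$variant$death_mechanism,
                      tk_included = fit$variant$tk_included,
                      calibration_set = fit$calibration_set %||% "unknown")
    total <- 0
    for (g in names(data_groups)) {
      ll <- log_likelihood_survival(fit$variant, params, data_groups[[g]])
      s_obs <- unlist(lapply(data_groups[[g]], function(d)
        d$survivor_counts / d$n_initial))
      s_mod <- unlist(lapply(data_groups[[g]], function(d)
        predict_survival(fit$variant, params, d$profile,
                         d$observation_times)))
      out[[paste0("log_likelihood_", g)]] <- ll
      out[[paste0("mpe_", g)]] <- mean_percentage_error(s_obs,
                                                        pmax(s_mod, 1e-12))
      total <- total + ll
    }
    out$total_log_likelihood <- total
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
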