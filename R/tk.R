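#' One-compartment toxicokinetic parameters
#'
#' Uptake and elimination rate constants of the one-compartment model
#' dC_int/dt = C_ext(t) * k_in - C_int(t) * k_out. `k_out` is the total loss
#' rate of the parent compound (elimination plus biotransformation).
#'
#' @param k_in uptake rate constant (mL g^-1 d^-1), > 0.
#' @param k_out elimination rate constant (d^-1), > 0.
#' @return An object of class `tk_params`.
#' @export
tk_params <- function(k_in, k_out) {
  if (!is.finite(k_in) || k_in <= 0) stop("k_in must be positive")
  if (!is.finite(k_out) || k_out <= 0) stop("k_out must be positive")
  structure(list(k_in = k_in, k_out = k_out), class = "tk_params")
}

#' @export
print.tk_params <- function(x, ...) {
  cat(sprintf("TK parameters: k_in = %g mL/g/d, k_out = %g 1/d (BAF = %.3g L/kg)\n",
              x$k_in, x$k_out, x$k_in / x$k_out))
  invisible(x)
}

#' Simulate internal concentrations
#'
#' Solves the one-compartment uptake/elimination ODE exactly, segment by
#' segment: within an exposure segment of constant concentration c,
#' C_int(t) = k_in*c/k_out + (C_int(t_seg) - k_in*c/k_out) * exp(-k_out*(t - t_seg)).
#'
#' @param profile an [exposure_profile()].
#' @param params a [tk_params()].
#' @param times sorted numeric vector of output times (days) within the
#'   profile domain.
#' @param c0 initial internal concentration at t = 0 (nmol/g), default 0
#'   (organisms start uncontaminated).
#' @return Numeric vector of internal concentrations (nmol/g) at `times`.
#' @export
simulate_internal <- function(profile, params, times, c0 = 0) {
  stopifnot(inherits(profile, "exposure_profile"), inherits(params, "tk_params"))
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("times must be sorted")
  if (any(times < 0) || any(times > profile$end_time))
    stop("times must lie within the profile domain")
  if (!is.finite(c0) || c0 < 0) stop("c0 must be non-negative")
  kin <- params$k_in; kout <- params$k_out
  brk <- sort(unique(c(profile$start_times, times, profile$end_time)))
  conc <- concentration_at(profile, brk[-length(brk)])
  state <- c0
  vals <- numeric(length(brk))
  vals[1L] <- c0
  for (i in seq_along(conc)) {
    ss <- kin * conc[i] / kout
    state <- ss + (state - ss) * exp(-kout * (brk[i + 1L] - brk[i]))
    vals[i + 1L] <- state
  }
  vals[match(times, brk)]
}

#' Toxicokinetic observations
#'
#' Internal-concentration measurements paired with the exposure profile the
#' animals experienced.
#'
#' @param times observation times (days), within the profile domain.
#' @param internal_concentrations measured internal concentrations (nmol/g),
#'   non-negative.
#' @param profile the [exposure_profile()] of the experiment.
#' @return An object of class `tk_observations`.
#' @export
tk_observations <- function(times, internal_concentrations, profile) {
  stopifnot(inherits(profile, "exposure_profile"))
  times <- as.numeric(times)
  cint <- as.numeric(internal_concentrations)
  if (length(times) != length(cint)) stop("times and concentrations differ in length")
  if (any(times < 0) || any(times > profile$end_time))
    stop("observation times outside the profile domain")
  if (any(!is.finite(cint)) || any(cint < 0))
    stop("internal concentrations must be finite and non-negative")
  structure(list(times = times, internal_concentrations = cint,
                 profile = profile), class = "tk_observations")
}

#' Read TK observations from CSV
#'
#' Expects columns `time_d` and `cint_nmol_per_g`; the exposure profile is
#' supplied separately.
#'
#' @param path CSV file path.
#' @param profile the matching [exposure_profile()].
#' @return A [tk_observations()] object.
#' @export
read_tk_csv <- function(path, profile) {
  d <- utils::read.csv(path)
  if (!all(c("time_d", "cint_nmol_per_g") %in% names(d)))
    stop("TK CSV needs columns time_d, cint_nmol_per_g")
  tk_observations(d$time_d, d$cint_nmol_per_g, profile)
}

#' Write TK observations to CSV
#'
#' @param obs a [tk_observations()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tk_csv <- function(obs, path) {
  stopifnot(inherits(obs, "tk_observations"))
  utils::write.csv(data.frame(time_d = obs$times,
                              cint_nmol_per_g = obs$internal_concentrations),
                   path, row.names = FALSE)
  invisible(path)
}

#' Fit the one-compartment TK model
#'
#' Least-squares estimation of (k_in, k_out) fitted jointly to one or more
#' TK datasets (e.g. an uptake/depuration experiment and a shorter repeat)
#' by Levenberg-Marquardt on log-parameters. Residuals are on untransformed
#' concentrations with equal weight for every point.
#'
#' @param datasets a [tk_observations()] object or a list of them.
#' @param init optional [tk_params()] starting values.
#' @return A list of class `tk_fit` with elements `params` (a
#'   [tk_params()]), `estimates`, `std_errors` (approximate, from the
#'   Jacobian at the optimum), `rss`, `n_obs`, `converged`.
#' @export
fit_tk <- function(datasets, init = NULL) {
  if (inherits(datasets, "tk_observations")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "tk_observations")))
  n_obs <- sum(vapply(datasets, function(d) length(d$times), 0L))
  if (n_obs < 2L) stop("need at least as many observations as parameters")
  if (is.null(init)) {
    # crude moment start: peak ratio for BAF-ish scale, 1/d elimination
    peak <- max(vapply(datasets, function(d) max(d$internal_concentrations), 0))
    cmax <- max(vapply(datasets, function(d) max(d$profile$concentrations), 0))
    init <- tk_params(max(peak / max(cmax, 1e-6), 1), 1)
  }
  resid_fn <- function(logp) {
    p <- tk_params(exp(logp[1L]), exp(logp[2L]))
    unlist(lapply(datasets, function(d)
      simulate_internal(d$profile, p, d$times) - d$internal_concentrations))
  }
  fit <- minpack.lm::nls.lm(par = log(c(init$k_in, init$k_out)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- exp(fit$par)
  names(est) <- c("k_in", "k_out")
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("TK fit did not converge: ", fit$message)
  # delta method: se(exp(theta)) = exp(theta) * se(theta)
  se <- rep(NA_real_, 2L)
  dof <- n_obs - 2L
  if (dof > 0L) {
    covar <- try(solve(fit$hessian) * fit$deviance / dof, silent = TRUE)
    if (!inherits(covar, "try-error") && all(diag(covar) >= 0))
      se <- est * sqrt(diag(covar))
  }
  names(se) <- names(est)
  structure(list(params = tk_params(est[["k_in"]], est[["k_out"]]),
                 estimates = est, std_errors = se, rss = fit$deviance,
                 n_obs = n_obs, converged = converged),
            class = "tk_fit")
}

#' @export
print.tk_fit <- function(x, ...) {
  cat("One-compartment TK fit (", x$n_obs, " observations)\n", sep = "")
  cat(sprintf("  k_in  = %8.3f mL/g/d (se %.3f)\n", x$estimates["k_in"],
              x$std_errors["k_in"]))
  cat(sprintf("  k_out = %8.3f 1/d    (se %.3f)\n", x$estimates["k_out"],
              x$std_errors["k_out"]))
  cat(sprintf("  RSS = %.4g; converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Bioaccumulation factor
#'
#' Steady-state ratio of internal to external concentration, k_in / k_out
#' (mL/g, numerically equal to L/kg).
#'
#' @param params a [tk_params()].
#' @return BAF (L/kg).
#' @export
baf <- function(params) {
  stopifnot(inherits(params, "tk_params"))
  params$k_in / params$k_out
}

#' Time to eliminate a given fraction of body burden
#'
#' Under pure depuration C_int decays as exp(-k_out t), so the time at which
#' a fraction `fraction` of the compound has been lost is
#' -log(1 - fraction) / k_out.
#'
#' @param params a [tk_params()].
#' @param fraction fraction eliminated, in (0, 1); 0.95 gives the 95%
#'   elimination time.
#' @return Time (days).
#' @export
elimination_time <- function(params, fraction = 0.95) {
  stopifnot(inherits(params, "tk_params"))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  -log(1 - fraction) / params$k_out
}

#' Lipid-normalized internal lethal concentration
#'
#' ILC50 = BAF x LC50, normalized by the organism's lipid fraction and
#' converted from nmol to umol: baf * lc50 / lipid_fraction / 1000.
#'
#' @param baf bioaccumulation factor (L/kg).
#' @param lc50 external LC50 (nmol/mL).
#' @param lipid_fraction lipid content (g lipid per g wet weight), in (0, 1].
#' @return ILC50 in umol per g lipid.
#' @export
lipid_normalized_ilc50 <- function(baf, lc50, lipid_fraction) {
  if (!is.finite(baf) || baf <= 0) stop("baf must be positive")
  if (!is.finite(lc50) || lc50 <= 0) stop("lc50 must be positive")
  if (!is.finite(lipid_fraction) || lipid_fraction <= 0 || lipid_fraction > 1)
    stop("lipid_fraction must be in (0, 1]")
  baf * lc50 / lipid_fraction / 1000
}
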