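#' Fit a log-logistic dose-response curve (LC50)
#'
#' Least-squares fit of percent survival against log10 concentration to the
#' two-parameter sigmoid `100 / (1 + (c / LC50)^slope)` with top fixed at
#' 100% and bottom at 0%, as in standard dose-response software. The 95%
#' confidence interval comes from the asymptotic parameter covariance at
#' the optimum (delta method on log10 LC50).
#'
#' @param concentrations exposure concentrations (nmol/mL), > 0.
#' @param fractions_surviving observed surviving fractions in `[0, 1]`.
#' @param n optional per-concentration group sizes (recorded, not used as
#'   weights).
#' @return An object of class `lcx_fit`: list with `lc50`, `hill_slope`,
#'   `ci_95` (lower, upper), `rss`, `identifiable`.
#' @export
fit_lc50 <- function(concentrations, fractions_surviving, n = NULL) {
  x <- as.numeric(concentrations)
  y <- as.numeric(fractions_surviving)
  if (length(x) != length(y)) stop("lengths differ")
  if (any(!is.finite(x)) || any(x <= 0)) stop("concentrations must be positive")
  if (any(y < 0) || any(y > 1)) stop("fractions must lie in [0, 1]")
  if (length(unique(x)) < 3L) stop("need at least 3 distinct concentrations")
  pct <- 100 * y
  identifiable <- any(pct < 50) && any(pct > 50)
  if (!identifiable)
    warning("responses do not span 50% survival; LC50 not identifiable")
  lx <- log10(x)
  # parameters: p = (log10 LC50, slope); curve on the log10-concentration axis
  resid_fn <- function(p)
    100 / (1 + 10^((lx - p[1L]) * p[2L])) - pct
  init <- c(stats::median(lx), 5)
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  lc50 <- 10^fit$par[1L]
  slope <- fit$par[2L]
  ci <- c(NA_real_, NA_real_)
  dof <- length(x) - 2L
  if (dof > 0L && identifiable) {
    covar <- try(solve(fit$hessian) * fit$deviance / dof, silent = TRUE)
    if (!inherits(covar, "try-error") && covar[1L, 1L] >= 0) {
      se_log <- sqrt(covar[1L, 1L])
      tq <- stats::qt(0.975, dof)
      ci <- 10^(fit$par[1L] + c(-1, 1) * tq * se_log)
    }
  }
  structure(list(lc50 = lc50, hill_slope = slope,
                 ci_95 = c(lower = ci[1L], upper = ci[2L]),
                 rss = fit$deviance, identifiable = identifiable,
                 n = n), class = "lcx_fit")
}

#' @export
print.lcx_fit <- function(x, ...) {
  cat(sprintf("LC50 = %.3g (%.3g-%.3g) nmol/mL, hill slope = %.3g%s\n",
              x$lc50, x$ci_95[1L], x$ci_95[2L], x$hill_slope,
              if (x$identifiable) "" else " [not identifiable]"))
  invisible(x)
}

#' Daily LC50 profile from acute constant-exposure data
#'
#' Applies [fit_lc50()] at each observation day of a set of acute
#' constant-exposure survival datasets (one dataset per concentration).
#' LC50 is expected to be non-increasing with exposure duration; violations
#' are flagged with a warning, not corrected.
#'
#' @param acute_datasets list of [survival_dataset()] objects, each with a
#'   constant exposure profile.
#' @param days observation days at which to fit; defaults to all shared
#'   positive observation times.
#' @return A data frame with columns `day`, `lc50`, `lower`, `upper`,
#'   `hill_slope`, `identifiable`.
#' @export
lc_profile_over_days <- function(acute_datasets, days = NULL) {
  stopifnot(length(acute_datasets) >= 3L)
  conc <- vapply(acute_datasets, function(d) d$profile$concentrations[1L], 0)
  if (is.null(days)) {
    days <- sort(unique(unlist(lapply(acute_datasets, function(d)
      d$observation_times))))
    days <- days[days > 0]
  }
  rows <- lapply(days, function(day) {
    frac <- vapply(acute_datasets, function(d) {
      i <- match(day, d$observation_times)
      if (is.na(i)) NA_real_ else d$survivor_counts[i] / d$n_initial
    }, 0)
    ok <- !is.na(frac)
    if (sum(ok) < 3L) {
      warning("day ", day, " skipped: fewer than 3 concentrations observed")
      return(NULL)
    }
    fit <- suppressWarnings(fit_lc50(conc[ok], frac[ok]))
    data.frame(day = day, lc50 = fit$lc50, lower = fit$ci_95[1L],
               upper = fit$ci_95[2L], hill_slope = fit$hill_slope,
               identifiable = fit$identifiable)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(out) && nrow(out) > 1L &&
      any(diff(out$lc50[out$identifiable]) > 1e-8))
    warning("LC50 sequence is not non-increasing across days")
  out
}
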