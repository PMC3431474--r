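#' Piecewise-constant exposure profile
#'
#' An exposure profile describes the external (water) concentration an
#' organism experiences over time as a step function: segments are
#' left-closed, right-open, so the value *at* a breakpoint is the new
#' segment's concentration. Time is in days, concentration in nmol/mL.
#'
#' @param start_times numeric vector of segment start times (days), strictly
#'   increasing, first element 0.
#' @param concentrations numeric vector of segment concentrations (nmol/mL),
#'   one per segment, all non-negative.
#' @param end_time end of the profile domain (days), greater than the last
#'   start time.
#' @return An object of class `exposure_profile`.
#' @examples
#' # two 1-day pulses at 28 nmol/mL separated by 2 days of clean water
#' p <- exposure_profile(c(0, 1, 3, 4), c(28, 0, 28, 0), end_time = 10)
#' concentration_at(p, c(0.5, 1, 3.2))
#' time_weighted_average(p, 0, 10)
#' @export
exposure_profile <- function(start_times, concentrations, end_time) {
  start_times <- as.numeric(start_times)
  concentrations <- as.numeric(concentrations)
  end_time <- as.numeric(end_time)
  if (length(start_times) != length(concentrations))
    stop("need one concentration per segment start time")
  if (length(start_times) == 0L)
    stop("profile needs at least one segment")
  if (start_times[1L] != 0)
    stop("first segment must start at time 0")
  if (any(diff(start_times) <= 0))
    stop("segment start times must be strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and non-negative")
  if (!is.finite(end_time) || end_time <= start_times[length(start_times)])
    stop("end_time must exceed the last segment start time")
  structure(
    list(start_times = start_times, concentrations = concentrations,
         end_time = end_time),
    class = "exposure_profile")
}

#' Constant exposure profile
#'
#' @param concentration water concentration (nmol/mL).
#' @param end_time duration (days).
#' @return An `exposure_profile` with a single segment.
#' @export
constant_profile <- function(concentration, end_time) {
  exposure_profile(0, concentration, end_time)
}

#' Single-pulse exposure profile
#'
#' A constant pulse starting at time 0 followed by clean water.
#'
#' @param concentration pulse concentration (nmol/mL).
#' @param pulse_duration pulse length (days).
#' @param end_time total profile duration (days), `> pulse_duration`.
#' @return An `exposure_profile`.
#' @export
pulse_profile <- function(concentration, pulse_duration = 1, end_time = 10) {
  if (pulse_duration <= 0) stop("pulse_duration must be positive")
  if (end_time <= pulse_duration) stop("end_time must exceed pulse_duration")
  exposure_profile(c(0, pulse_duration), c(concentration, 0), end_time)
}

#' @export
print.exposure_profile <- function(x, ...) {
  n <- length(x$start_times)
  ends <- c(x$start_times[-1L], x$end_time)
  cat("Exposure profile:", n, "segment(s) over", x$end_time, "d\n")
  for (i in seq_len(n))
    cat(sprintf("  [%g, %g%s  %g nmol/mL\n", x$start_times[i], ends[i],
                if (i == n) "]" else ")", x$concentrations[i]))
  invisible(x)
}

#' External concentration at given times
#'
#' Evaluates the step function; segments are left-closed, right-open, so at
#' an internal breakpoint the new segment's value is returned. The profile's
#' end time is included in the domain (it takes the last segment's value).
#'
#' @param profile an [exposure_profile()].
#' @param t numeric vector of times (days) within `[0, end_time]`.
#' @return Numeric vector of concentrations (nmol/mL).
#' @export
concentration_at <- function(profile, t) {
  stopifnot(inherits(profile, "exposure_profile"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t > profile$end_time))
    stop("t must lie within [0, end_time]")
  idx <- findInterval(t, profile$start_times)  # right-open by default
  profile$concentrations[idx]
}

#' Time-weighted average concentration
#'
#' Integral of the exposure concentration over `[t0, t1]` divided by the
#' window length.
#'
#' @param profile an [exposure_profile()].
#' @param t0,t1 window bounds (days), `0 <= t0 < t1 <= end_time`.
#' @return TWA concentration (nmol/mL).
#' @export
time_weighted_average <- function(profile, t0 = 0, t1 = profile$end_time) {
  stopifnot(inherits(profile, "exposure_profile"))
  if (!is.finite(t0) || !is.finite(t1) || t0 < 0 || t1 > profile$end_time)
    stop("window must lie within [0, end_time]")
  if (t1 <= t0) stop("t1 must exceed t0")
  brk <- sort(unique(c(t0, t1,
    profile$start_times[profile$start_times > t0 & profile$start_times < t1])))
  widths <- diff(brk)
  conc <- concentration_at(profile, brk[-length(brk)])
  sum(widths * conc) / (t1 - t0)
}

#' Read an exposure profile from CSV
#'
#' Expects columns `time_d` and `conc_nmol_per_mL`. Each row but the last is
#' a segment start; the final row marks the profile end time (its
#' concentration is ignored and conventionally repeats the last segment's).
#'
#' @param path CSV file path.
#' @return An [exposure_profile()].
#' @export
read_exposure_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_d", "conc_nmol_per_mL") %in% names(d)))
    stop("exposure CSV needs columns time_d, conc_nmol_per_mL")
  if (nrow(d) < 2L) stop("exposure CSV needs at least two rows")
  n <- nrow(d)
  exposure_profile(d$time_d[-n], d$conc_nmol_per_mL[-n], d$time_d[n])
}

#' Write an exposure profile to CSV
#'
#' Inverse of [read_exposure_csv()]: one row per segment start plus a final
#' row at the end time repeating the last concentration.
#'
#' @param profile an [exposure_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_csv <- function(profile, path) {
  stopifnot(inherits(profile, "exposure_profile"))
  n <- length(profile$start_times)
  d <- data.frame(
    time_d = c(profile$start_times, profile$end_time),
    conc_nmol_per_mL = c(profile$concentrations, profile$concentrations[n]))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
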