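#' Time-integrated relative metabolic rate
#'
#' The true 24-h maintenance rate implied by a sleep architecture and a
#' state rate profile: the time-weighted mean
#' `p_wake * rate_wake + p_nrem * rate_nrem + p_rem * rate_rem`.
#'
#' @param arch A [sleep_architecture()].
#' @param profile A [state_rate_profile()].
#' @return A single relative rate in the units of `profile`.
#' @export
#' @examples
#' integrated_rate(sleep_architecture(0.5, 0.375, 0.125),
#'                 state_rate_profile(44.03, 36.73, 19.18))
integrated_rate <- function(arch, profile) {
  a <- as_state_vector(arch, "architecture")
  p <- as_state_vector(profile, "profile")
  stopifnot(setequal(names(a), names(p)))
  sum(a * p[names(a)])
}

#' State-restricted SMR estimate
#'
#' The rate that would be measured if sampling were confined to a subset of
#' states: the time-weighted mean rate over only those states.
#'
#' @param arch A [sleep_architecture()].
#' @param profile A [state_rate_profile()].
#' @param states Non-empty subset of `c("WAKE", "NREM", "REM")`; e.g.
#'   `c("NREM", "REM")` for sleep-only measurement.
#' @return A single relative rate.
#' @export
#' @examples
#' state_restricted_estimate(sleep_architecture(0.5, 0.375, 0.125),
#'                           state_rate_profile(44.03, 36.73, 19.18),
#'                           c("NREM", "REM"))
state_restricted_estimate <- function(arch, profile, states) {
  a <- as_state_vector(arch, "architecture")
  p <- as_state_vector(profile, "profile")
  if (length(states) == 0) stop("'states' must be non-empty", call. = FALSE)
  if (!all(states %in% names(a))) {
    stop("unknown state(s): ", paste(setdiff(states, names(a)), collapse = ", "),
         call. = FALSE)
  }
  tw <- sum(a[states])
  if (tw <= 0) {
    stop("no time is spent in the measured states; estimate undefined", call. = FALSE)
  }
  sum(a[states] * p[states]) / tw
}

#' Per cent error of an estimate relative to truth
#'
#' @param estimate,truth Rates on a common scale; `truth` must be positive.
#' @return `100 * (estimate - truth) / truth`.
#' @export
percent_error <- function(estimate, truth) {
  if (any(truth <= 0)) stop("'truth' must be positive", call. = FALSE)
  100 * (estimate - truth) / truth
}

#' Sampling-error curves for sleep-only and wake-only SMR measurement
#'
#' For a grid of wake proportions, computes the per cent error in estimated
#' SMR (relative to the true time-integrated 24-h rate) when measurement is
#' restricted to sleep (NREM + REM) or to wakefulness. Sleep time is split
#' between NREM and REM by `rem_share_of_sleep`. Sleep-only measurement
#' underestimates the integrated rate increasingly as the proportion of the
#' day spent awake grows; wake-only measurement overestimates it increasingly
#' as the unmeasured sleep fraction grows.
#'
#' @param profile A [state_rate_profile()].
#' @param rem_share_of_sleep Fraction of sleep spent in REM (default 0.25,
#'   a mid-range mammalian value).
#' @param p_wake_range Range of wake proportions covered (default
#'   `c(0.10, 0.90)`; a day fully asleep or fully awake makes one of the two
#'   restricted estimates undefined).
#' @param n_points Number of grid points (default 81).
#' @return A data.frame of class `error_curve` with columns `p_wake`,
#'   `sleep_only_error_pct`, `wake_only_error_pct`, `rem_share_of_sleep`.
#' @export
#' @examples
#' head(error_curve(state_totals(maintenance_partition())))
error_curve <- function(profile, rem_share_of_sleep = 0.25,
                        p_wake_range = c(0.10, 0.90), n_points = 81) {
  if (length(rem_share_of_sleep) != 1 || rem_share_of_sleep < 0 ||
      rem_share_of_sleep > 1) {
    stop("'rem_share_of_sleep' must be a fraction in [0, 1]", call. = FALSE)
  }
  if (length(p_wake_range) != 2 || any(p_wake_range < 0) || any(p_wake_range > 1) ||
      diff(p_wake_range) <= 0) {
    stop("'p_wake_range' must be an increasing pair within [0, 1]", call. = FALSE)
  }
  if (n_points < 2) stop("'n_points' must be at least 2", call. = FALSE)
  grid <- seq(p_wake_range[1], p_wake_range[2], length.out = n_points)
  sleep_err <- numeric(n_points)
  wake_err <- numeric(n_points)
  for (i in seq_along(grid)) {
    p_sleep <- 1 - grid[i]
    arch <- sleep_architecture(grid[i],
                               p_sleep * (1 - rem_share_of_sleep),
                               p_sleep * rem_share_of_sleep)
    truth <- integrated_rate(arch, profile)
    sleep_err[i] <- percent_error(
      state_restricted_estimate(arch, profile, c("NREM", "REM")), truth)
    wake_err[i] <- percent_error(
      state_restricted_estimate(arch, profile, "WAKE"), truth)
  }
  out <- data.frame(p_wake = grid,
                    sleep_only_error_pct = sleep_err,
                    wake_only_error_pct = wake_err,
                    rem_share_of_sleep = rem_share_of_sleep)
  class(out) <- c("error_curve", "data.frame")
  out
}

#' Write an error curve to CSV
#'
#' @param curve An [error_curve()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_curve <- function(curve, path) {
  stopifnot(inherits(curve, "error_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
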