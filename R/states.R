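#' Sleep-wake state labels
#'
#' The three behavioural states used throughout the package, in their
#' canonical order: quiet wakefulness, non-rapid-eye-movement sleep and
#' rapid-eye-movement sleep. All files, configs and reports use exactly these
#' labels.
#'
#' @return Character vector `c("WAKE", "NREM", "REM")`.
#' @export
#' @examples
#' smr_states()
smr_states <- function() c("WAKE", "NREM", "REM")

#' State-specific relative metabolic rate profile
#'
#' A named non-negative vector of relative metabolic rate levels, one per
#' sleep-wake state. Units are arbitrary but shared across states; only
#' ratios and time-weighted combinations of the rates matter downstream.
#'
#' @param wake,nrem,rem Non-negative relative metabolic rate levels.
#' @return A named numeric vector of class `state_rate_profile`.
#' @seealso [state_totals()] which builds a profile from a partition table.
#' @export
#' @examples
#' state_rate_profile(44.03, 36.73, 19.18)
state_rate_profile <- function(wake, nrem, rem) {
  x <- c(WAKE = as.numeric(wake), NREM = as.numeric(nrem), REM = as.numeric(rem))
  if (anyNA(x) || any(x < 0)) {
    stop("state rates must be non-negative and non-missing", call. = FALSE)
  }
  if (all(x == 0)) stop("at least one state rate must be > 0", call. = FALSE)
  structure(x, class = c("state_rate_profile", "numeric"))
}

#' Sleep architecture (daily state time budget)
#'
#' Fractions of the day spent awake, in NREM sleep and in REM sleep.
#' Fractions must be in [0, 1] and sum to 1 (tolerance 1e-9).
#'
#' @param p_wake,p_nrem,p_rem Fractions of the period spent in each state.
#' @return A named numeric vector of class `sleep_architecture`.
#' @export
#' @examples
#' sleep_architecture(0.5, 0.375, 0.125)
sleep_architecture <- function(p_wake, p_nrem, p_rem) {
  x <- c(WAKE = as.numeric(p_wake), NREM = as.numeric(p_nrem), REM = as.numeric(p_rem))
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("state fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop("state fractions must sum to 1 (got ", format(sum(x), digits = 12), ")",
         call. = FALSE)
  }
  structure(x, class = c("sleep_architecture", "numeric"))
}

#' State time budget for IDME
#'
#' Alias constructor for the time-allocation terms of the integrated daily
#' maintenance expenditure: the proportions of the 24-h period spent in each
#' state, summing to 1. Identical in structure to [sleep_architecture()].
#'
#' @inheritParams sleep_architecture
#' @return A named numeric vector of class `sleep_architecture`.
#' @export
state_time_budget <- function(p_wake, p_nrem, p_rem) {
  sleep_architecture(p_wake, p_nrem, p_rem)
}

#' @export
print.state_rate_profile <- function(x, ...) {
  cat("State rate profile (relative units):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.sleep_architecture <- function(x, ...) {
  cat("Sleep architecture (fractions of period):\n")
  print(unclass(x), ...)
  invisible(x)
}

# internal: coerce a profile-or-named-vector to named numeric over given labels
as_state_vector <- function(x, what = "rates") {
  v <- unclass(x)
  if (is.null(names(v)) && length(v) == 3L) names(v) <- smr_states()
  if (is.null(names(v)) || anyNA(names(v)) || any(names(v) == "")) {
    stop(what, " must be a named numeric vector (or of length 3 in WAKE/NREM/REM order)",
         call. = FALSE)
  }
  if (anyDuplicated(names(v))) stop("duplicate state labels in ", what, call. = FALSE)
  v
}
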