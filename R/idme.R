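#' Integrated daily maintenance expenditure (IDME)
#'
#' The time-weighted sum of state-specific metabolic rates,
#' `sum_i M_i * T_i`, where `M_i` is the mean metabolic rate during state `i`
#' and `T_i` the proportion of the 24-h period spent in it (`sum T_i = 1`).
#' Any number of labelled states is accepted; rates and times are matched by
#' label. The result is in the units of the supplied rates.
#'
#' @param rates A [state_rate_profile()] or named non-negative numeric vector.
#' @param times A [sleep_architecture()] / [state_time_budget()] or named
#'   numeric vector of fractions summing to 1.
#' @return A single expenditure rate.
#' @export
#' @examples
#' compute_idme(state_rate_profile(44.03, 36.73, 19.18),
#'              state_time_budget(0.5, 0.375, 0.125))
compute_idme <- function(rates, times) {
  m <- as_state_vector(rates, "rates")
  t <- as_state_vector(times, "times")
  if (!setequal(names(m), names(t))) {
    stop("state labels of 'rates' and 'times' must match; got {",
         paste(names(m), collapse = ","), "} vs {",
         paste(names(t), collapse = ","), "}", call. = FALSE)
  }
  if (any(m < 0)) stop("rates must be non-negative", call. = FALSE)
  if (any(t < 0) || abs(sum(t) - 1) > 1e-9) {
    stop("time fractions must be non-negative and sum to 1", call. = FALSE)
  }
  sum(m * t[names(m)])
}

#' State rates from a wake-measured SMR and state multipliers
#'
#' Applies state-specific correction factors to a quiet-wake SMR baseline:
#' `rate_i = wake_smr * multiplier_i` with the WAKE multiplier fixed at 1.
#' Literature-style defaults are 0.83 (NREM) and 0.44 (REM); exact ratios for
#' a partition table come from [state_multipliers()].
#'
#' @param wake_smr Positive rate measured during quiet wakefulness.
#' @param multipliers Named non-negative multipliers for the non-wake states
#'   (a `WAKE` entry, if present, must equal 1).
#' @return A [state_rate_profile()].
#' @export
#' @examples
#' rates_from_wake_baseline(100, c(NREM = 0.83, REM = 0.44))
rates_from_wake_baseline <- function(wake_smr,
                                     multipliers = c(NREM = 0.83, REM = 0.44)) {
  if (length(wake_smr) != 1 || !is.finite(wake_smr) || wake_smr <= 0) {
    stop("'wake_smr' must be a single positive rate", call. = FALSE)
  }
  mult <- as_state_vector(multipliers, "multipliers")
  if (any(mult < 0)) stop("multipliers must be non-negative", call. = FALSE)
  if ("WAKE" %in% names(mult) && abs(mult[["WAKE"]] - 1) > 1e-12) {
    stop("the WAKE multiplier is the reference and must be 1", call. = FALSE)
  }
  mult[["WAKE"]] <- 1
  need <- setdiff(smr_states(), names(mult))
  if (length(need) > 0) {
    stop("missing multiplier(s) for: ", paste(need, collapse = ", "), call. = FALSE)
  }
  state_rate_profile(wake_smr * mult[["WAKE"]],
                     wake_smr * mult[["NREM"]],
                     wake_smr * mult[["REM"]])
}

#' State time budget realized by a hypnogram
#'
#' Per-state summed bout durations divided by the total duration; the
#' fractions sum to 1 by construction.
#'
#' @param h A [hypnogram()].
#' @return A [sleep_architecture()].
#' @export
times_from_hypnogram <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  dur <- h$end_h - h$start_h
  total <- sum(dur)
  if (total <= 0) stop("hypnogram has zero duration", call. = FALSE)
  by_state <- vapply(smr_states(),
                     function(s) sum(dur[h$state == s]) / total, numeric(1))
  sleep_architecture(by_state[["WAKE"]], by_state[["NREM"]], by_state[["REM"]])
}
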