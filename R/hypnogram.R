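#' Bout-generator configuration
#'
#' Target daily time fractions per state plus state-specific mean bout
#' lengths. Bout lengths are drawn from exponential distributions; defaults
#' (WAKE 30 min, NREM 20 min, REM 8 min) emulate fragmented mammalian sleep.
#'
#' @param fractions Named fractions over WAKE/NREM/REM summing to 1, or a
#'   [sleep_architecture()].
#' @param mean_bout_min Named positive mean bout lengths in minutes.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `bout_config`.
#' @export
#' @examples
#' bout_config(c(WAKE = 0.5, NREM = 0.375, REM = 0.125), seed = 1)
bout_config <- function(fractions,
                        mean_bout_min = c(WAKE = 30, NREM = 20, REM = 8),
                        seed = NULL) {
  f <- as_state_vector(fractions, "fractions")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    stop("'fractions' must be non-negative and sum to 1", call. = FALSE)
  }
  m <- as_state_vector(mean_bout_min, "mean_bout_min")
  if (!all(names(f) %in% names(m))) {
    stop("'mean_bout_min' must cover every state in 'fractions'", call. = FALSE)
  }
  if (any(m[names(f)] <= 0)) {
    stop("mean bout lengths must be positive", call. = FALSE)
  }
  structure(list(fractions = f, mean_bout_min = m[names(f)], seed = seed),
            class = "bout_config")
}

# internal: next-state weights for the rejection chain. Sampling the next
# state proportional to w over the non-current states gives stationary visit
# frequencies proportional to w*(1-w); we solve w by damped fixed-point so
# stationary TIME shares w*(1-w)*m match the target fractions f. Any residual
# (inevitable with two states, whose visit frequencies are pinned to 1/2) is
# absorbed into per-state effective bout means so that long-run realized
# fractions converge to f for any feasible configuration.
solve_bout_process <- function(f, m) {
  k <- length(f)
  if (k == 1) return(list(w = stats::setNames(1, names(f)), mean_eff = m))
  if (k == 2) {
    w <- stats::setNames(rep(0.5, 2), names(f))
  } else {
    r <- f / m
    w <- r / sum(r)
    for (it in 1:2000) {
      prop <- r / pmax(1 - w, 1e-8)
      prop <- prop / sum(prop)
      w_new <- 0.5 * w + 0.5 * prop
      if (max(abs(w_new - w)) < 1e-13) { w <- w_new; break }
      w <- w_new
    }
  }
  visit <- w * (1 - w)
  share <- visit * m / sum(visit * m)
  mean_eff <- m * (f / share)            # residual correction; ~1 when solvable
  list(w = w, mean_eff = mean_eff)
}

#' Generate a bout-structured hypnogram
#'
#' Simulates an alternating sequence of WAKE/NREM/REM bouts with
#' state-specific exponential bout lengths. The next state is sampled with
#' rejection of the current state, with transition weights solved so that
#' realized per-state time fractions converge to the configured targets as
#' duration grows. With `exact = TRUE`, per-state bout durations are rescaled
#' after generation so the realized fractions equal the targets exactly
#' (useful for fixed measurement windows and analytic cross-checks).
#'
#' @param cfg A [bout_config()].
#' @param duration_h Total duration in hours (> 0).
#' @param exact Rescale bouts so realized fractions match targets exactly.
#' @return A data.frame of class `hypnogram` with columns `start_h`, `end_h`,
#'   `state` (contiguous half-open bouts) and attribute `duration_h`.
#' @export
#' @examples
#' h <- generate_hypnogram(bout_config(c(WAKE = 0.5, NREM = 0.375, REM = 0.125),
#'                                     seed = 42), 24)
#' times_from_hypnogram(h)
generate_hypnogram <- function(cfg, duration_h, exact = FALSE) {
  stopifnot(inherits(cfg, "bout_config"))
  if (length(duration_h) != 1 || !is.finite(duration_h) || duration_h <= 0) {
    stop("'duration_h' must be a positive duration in hours", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  f <- cfg$fractions[cfg$fractions > 0]
  m_h <- cfg$mean_bout_min[names(f)] / 60
  if (length(f) == 1L) {
    return(hypnogram(data.frame(start_h = 0, end_h = duration_h,
                                state = names(f))))
  }
  proc <- solve_bout_process(f, m_h)
  states <- character(0)
  lens <- numeric(0)
  time_in <- stats::setNames(numeric(length(f)), names(f))
  cur <- sample(names(f), 1, prob = f)
  total <- 0
  while (total < duration_h) {
    len <- stats::rexp(1, rate = 1 / proc$mean_eff[[cur]])
    states <- c(states, cur)
    lens <- c(lens, len)
    total <- total + len
    time_in[[cur]] <- time_in[[cur]] + len
    others <- setdiff(names(f), cur)
    # deficit feedback: boost states running behind their target time share
    # (in units of their own mean bout length) so realized fractions converge
    # at better than the plain 1/sqrt(T) renewal rate
    deficit <- (f[others] * total - time_in[others]) / m_h[others]
    w_fb <- proc$w[others] * exp(pmin(5, pmax(-5, deficit)))
    cur <- sample(others, 1, prob = w_fb)
  }
  lens[length(lens)] <- lens[length(lens)] - (total - duration_h)
  lens <- lens[lens > 0]
  states <- states[seq_along(lens)]
  if (exact) {
    # every targeted state must be present before rescaling; a state with a
    # very small target can miss a short window, so splice one bout in
    for (s in setdiff(names(f), unique(states))) {
      at <- sample(seq_along(states), 1)
      states <- append(states, s, after = at)
      lens <- append(lens, proc$mean_eff[[s]], after = at)
    }
    realized <- tapply(lens, factor(states, levels = names(f)), sum)
    scale <- (f * duration_h) / as.numeric(realized)
    lens <- lens * scale[states]
  }
  ends <- cumsum(lens)
  h <- data.frame(start_h = c(0, ends[-length(ends)]), end_h = ends,
                  state = states, stringsAsFactors = FALSE)
  h$end_h[nrow(h)] <- duration_h   # guard cumulative rounding
  hypnogram(h)
}

#' Construct/validate a hypnogram
#'
#' @param bouts A data.frame with columns `start_h`, `end_h`, `state`:
#'   contiguous, non-overlapping half-open bouts starting at 0, with states
#'   among WAKE/NREM/REM.
#' @return The validated data.frame with class `hypnogram`.
#' @export
hypnogram <- function(bouts) {
  required <- c("start_h", "end_h", "state")
  if (!all(required %in% names(bouts))) {
    stop("hypnogram needs columns start_h, end_h, state", call. = FALSE)
  }
  if (nrow(bouts) == 0) stop("hypnogram has no bouts", call. = FALSE)
  if (!all(bouts$state %in% smr_states())) {
    stop("unknown state label(s): ",
         paste(setdiff(unique(bouts$state), smr_states()), collapse = ", "),
         call. = FALSE)
  }
  if (any(bouts$end_h <= bouts$start_h)) {
    stop("every bout must have positive duration", call. = FALSE)
  }
  if (abs(bouts$start_h[1]) > 1e-9 ||
      any(abs(bouts$start_h[-1] - bouts$end_h[-nrow(bouts)]) > 1e-9)) {
    stop("bouts must be contiguous and start at 0", call. = FALSE)
  }
  bouts <- as.data.frame(bouts[, required], stringsAsFactors = FALSE)
  class(bouts) <- c("hypnogram", "data.frame")
  attr(bouts, "duration_h") <- bouts$end_h[nrow(bouts)]
  bouts
}

#' @export
print.hypnogram <- function(x, ...) {
  td <- attr(x, "duration_h")
  frac <- times_from_hypnogram(x)
  cat(sprintf("Hypnogram: %d bouts over %.3g h (WAKE %.3f, NREM %.3f, REM %.3f)\n",
              nrow(x), td, frac[["WAKE"]], frac[["NREM"]], frac[["REM"]]))
  invisible(x)
}

#' Read / write hypnogram CSV (`start_h,end_h,state`)
#'
#' @param path File path.
#' @return `read_hypnogram()` returns a [hypnogram()]; `write_hypnogram()`
#'   returns `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  hypnogram(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_hypnogram
#' @param h A [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  utils::write.csv(as.data.frame(h), path, row.names = FALSE)
  invisible(path)
}
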