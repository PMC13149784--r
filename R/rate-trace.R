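#' Synthesize a respirometry-like rate trace from a hypnogram
#'
#' Produces a uniformly sampled oxygen-uptake-like trace whose state-conditional
#' mean follows the rate profile: each sample's expected value is
#' `baseline * rate_state / rate_wake`, so the trace equals `baseline` during
#' quiet wakefulness and drops to the NREM and REM levels during sleep.
#' Noise is multiplicative Gaussian with coefficient of variation `noise_cv`,
#' truncated at zero so rates stay non-negative. Samples are taken at bin
#' midpoints; each sample carries the state occupying that midpoint.
#'
#' @param h A [hypnogram()].
#' @param profile A [state_rate_profile()]; its WAKE rate must be positive.
#' @param baseline Rate level during quiet wakefulness (rate units; default 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param dt_min Sampling interval in minutes (default 1, an
#'   intermittent-flow-respirometry-like resolution).
#' @param seed Optional integer seed.
#' @return A data.frame of class `rate_trace` with columns `time_h`, `rate`,
#'   `state`, and attribute `dt_min`.
#' @export
#' @examples
#' h <- generate_hypnogram(bout_config(c(WAKE = 0.5, NREM = 0.375, REM = 0.125),
#'                                     seed = 7), 24)
#' tr <- rate_trace(h, state_totals(maintenance_partition()), baseline = 0.4)
#' mean(tr$rate)
rate_trace <- function(h, profile, baseline = 1, noise_cv = 0, dt_min = 1,
                       seed = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  p <- as_state_vector(profile, "profile")
  if (!"WAKE" %in% names(p) || p[["WAKE"]] <= 0) {
    stop("'profile' must have a positive WAKE rate", call. = FALSE)
  }
  if (baseline < 0) stop("'baseline' must be non-negative", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be non-negative", call. = FALSE)
  if (dt_min <= 0) stop("'dt_min' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  duration_h <- attr(h, "duration_h")
  n <- floor(duration_h * 60 / dt_min)
  if (n < 1) stop("trace would contain no samples; reduce 'dt_min'", call. = FALSE)
  t_mid <- ((seq_len(n) - 0.5) * dt_min) / 60
  idx <- findInterval(t_mid, h$start_h)
  state <- h$state[idx]
  mu <- baseline * p[state] / p[["WAKE"]]
  rate <- if (noise_cv > 0) pmax(0, mu * (1 + noise_cv * stats::rnorm(n))) else mu
  out <- data.frame(time_h = t_mid, rate = as.numeric(rate), state = state,
                    stringsAsFactors = FALSE)
  class(out) <- c("rate_trace", "data.frame")
  attr(out, "dt_min") <- dt_min
  out
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("Rate trace: %d samples at %.3g-min intervals; mean rate %.4g\n",
              nrow(x), attr(x, "dt_min"), mean(x$rate)))
  invisible(x)
}

#' Read / write rate-trace CSV (`time_h,rate,state`)
#'
#' @param path File path.
#' @return `read_rate_trace()` returns a `rate_trace` data.frame (the `state`
#'   column is optional on input); `write_rate_trace()` returns `path`
#'   invisibly.
#' @export
read_rate_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "rate") %in% names(df))) {
    stop("rate trace needs columns time_h and rate", call. = FALSE)
  }
  if (nrow(df) < 1) stop("empty rate trace", call. = FALSE)
  if (!"state" %in% names(df)) df$state <- NA_character_
  dt <- if (nrow(df) > 1) diff(df$time_h[1:2]) * 60 else NA_real_
  if (nrow(df) > 2 && max(abs(diff(df$time_h) - dt / 60)) > 1e-6) {
    stop("rate trace must be uniformly sampled", call. = FALSE)
  }
  out <- df[, c("time_h", "rate", "state")]
  class(out) <- c("rate_trace", "data.frame")
  attr(out, "dt_min") <- dt
  out
}

#' @rdname read_rate_trace
#' @param trace A `rate_trace`.
#' @export
write_rate_trace <- function(trace, path) {
  stopifnot(inherits(trace, "rate_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

# internal: pull the numeric rate vector out of a trace or numeric input
trace_rates <- function(trace) {
  if (inherits(trace, "rate_trace") || is.data.frame(trace)) trace$rate
  else as.numeric(trace)
}

#' Lower-quantile SMR estimate
#'
#' The classic quantile extraction method for intermittent-flow respirometry:
#' the empirical `q`-quantile of the rate values. On traces spanning sleep,
#' low quantiles disproportionately sample sleep states and sit below the
#' time-integrated 24-h mean.
#'
#' @param trace A `rate_trace` (or numeric vector of rates).
#' @param q Quantile in (0, 1); 0.2 is a common choice.
#' @return A single rate estimate.
#' @export
quantile_smr <- function(trace, q = 0.2) {
  x <- trace_rates(trace)
  if (length(x) == 0) stop("empty trace", call. = FALSE)
  if (length(q) != 1 || q <= 0 || q >= 1) {
    stop("'q' must lie strictly inside (0, 1)", call. = FALSE)
  }
  as.numeric(stats::quantile(x, probs = q, names = FALSE))
}

#' SMR as the mean of the lowest normal distribution (MLND)
#'
#' Fits a two-component Gaussian mixture to the rate values by EM and returns
#' the mean of the lower-mean component. Initialization is deterministic
#' (component means at the 10th and 90th percentiles, equal variances and
#' weights), so repeated fits on the same data agree. A variance floor keeps
#' the fit stable on noise-free, well-separated traces.
#'
#' @param trace A `rate_trace` (or numeric vector of rates).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return The lower component mean. A constant trace returns that constant
#'   with a warning. The full fit (means, sds, weights, log-likelihood) is
#'   attached as attribute `"fit"`.
#' @export
mlnd_smr <- function(trace, max_iter = 500, tol = 1e-10) {
  x <- trace_rates(trace)
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(x)) == 1L) {
    warning("constant trace: returning the constant; no mixture fitted")
    return(x[1])
  }
  mu <- as.numeric(stats::quantile(x, c(0.1, 0.9)))
  sd_floor <- max(1e-8, 1e-6 * stats::sd(x))
  sig <- rep(max(stats::sd(x) / 2, sd_floor), 2)
  lambda <- c(0.5, 0.5)
  ll_old <- -Inf
  n <- length(x)
  for (it in seq_len(max_iter)) {
    # E-step in log space for stability with tiny variances
    logd <- cbind(log(lambda[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE),
                  log(lambda[2]) + stats::dnorm(x, mu[2], sig[2], log = TRUE))
    m <- pmax(logd[, 1], logd[, 2])
    lse <- m + log(exp(logd[, 1] - m) + exp(logd[, 2] - m))
    resp <- exp(logd - lse)
    ll <- sum(lse)
    # M-step
    nk <- colSums(resp)
    if (any(nk < 1e-12)) break          # a component died; keep last estimate
    lambda <- nk / n
    mu <- colSums(resp * x) / nk
    sig <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
                     sd_floor^2))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  low <- which.min(mu)
  structure(mu[low],
            fit = list(means = mu, sds = sig, weights = lambda,
                       loglik = ll_old, iterations = it))
}

#' Zero-activity extrapolation of SMR
#'
#' Ordinary least-squares regression of measurement-phase oxygen-uptake rates
#' on concurrent activity scores; the intercept estimates SMR at zero
#' activity, i.e. the maintenance rate during quiet wakefulness.
#'
#' @param activity Numeric activity scores (not all equal; length >= 3).
#' @param rate Numeric rates, same length.
#' @return The fitted intercept, with the `lm` fit attached as attribute
#'   `"fit"`.
#' @export
#' @examples
#' activity_extrapolation(0:5, 0.3 + 0.2 * (0:5))
activity_extrapolation <- function(activity, rate) {
  if (length(activity) != length(rate)) {
    stop("'activity' and 'rate' must have equal length", call. = FALSE)
  }
  if (length(activity) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(activity) == 0) {
    stop("all activity scores are equal; regression is singular", call. = FALSE)
  }
  fit <- stats::lm(rate ~ activity)
  structure(unname(stats::coef(fit)[1]), fit = fit)
}
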