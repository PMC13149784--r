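#' Define a process-targeted treatment
#'
#' A treatment multiplies the total daily cost of one or more named
#' maintenance processes by a constant factor, across all sleep-wake states
#' (the process's state partitioning is unchanged). A factor of 0.5 halves
#' the targeted costs; 1.5 raises them by half.
#'
#' @param name Treatment label.
#' @param targets Character vector of process names (must match the partition
#'   table rows exactly).
#' @param factor Multiplicative cost factor (>= 0).
#' @return A list of class `smr_treatment`.
#' @export
#' @examples
#' treatment("protein-synthesis inhibitor", "Protein synthesis", 0.5)
treatment <- function(name, targets, factor) {
  if (length(targets) == 0) stop("'targets' must be non-empty", call. = FALSE)
  if (length(factor) != 1 || !is.finite(factor) || factor < 0) {
    stop("'factor' must be a single non-negative number", call. = FALSE)
  }
  structure(list(name = name, targets = targets, factor = factor),
            class = "smr_treatment")
}

#' The three reference treatments
#'
#' A protein-synthesis inhibitor (factor 0.5, the only magnitude fixed by the
#' model narrative), an ion-transport blocker acting on both brain and
#' peripheral ion regulation (default factor 0.5), and thermal stress raising
#' thermoregulation costs (default factor 1.5). The latter two magnitudes are
#' configurable defaults.
#'
#' @param ion_factor,thermal_factor Cost factors for the ion blocker and the
#'   thermal-stress treatment.
#' @return A named list of [treatment()]s.
#' @export
default_treatments <- function(ion_factor = 0.5, thermal_factor = 1.5) {
  list(
    protein_inhibitor = treatment("protein-synthesis inhibitor",
                                  "Protein synthesis", 0.5),
    ion_blocker = treatment("ion-transport blocker",
                            c("Ion regulation (brain)",
                              "Ion regulation (peripheral)"), ion_factor),
    thermal_stress = treatment("thermal stress", "Thermoregulation",
                               thermal_factor))
}

#' Apply a treatment to a partition table
#'
#' Multiplies the `total_smr_pct` of the targeted processes by the treatment
#' factor; partitions and untargeted rows are unchanged.
#'
#' @param table A [partition_table()].
#' @param t A [treatment()].
#' @return A modified `partition_table` (its total-SMR column no longer sums
#'   to 100 unless `factor = 1`).
#' @export
#' @examples
#' tr <- treatment("protein-synthesis inhibitor", "Protein synthesis", 0.5)
#' state_contribution(apply_treatment(maintenance_partition(), tr),
#'                    "Protein synthesis", "NREM")  # 5.4
apply_treatment <- function(table, t) {
  stopifnot(inherits(table, "partition_table"), inherits(t, "smr_treatment"))
  idx <- match(t$targets, table$process)
  if (anyNA(idx)) {
    stop("unknown target process(es): ",
         paste(t$targets[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(table)
  out$total_smr_pct[idx] <- out$total_smr_pct[idx] * t$factor
  # a factor of 0 zeroes a row; bypass the >0 row check deliberately
  class(out) <- c("partition_table", "data.frame")
  out
}

# the four sampling windows of the detectability analysis
detection_windows <- function() c("WAKE", "NREM", "REM", "INTEGRATED")

#' Detected treatment effect under a given sampling window
#'
#' The proportional SMR change a measurement confined to one state (or
#' integrating the whole day) would report:
#' `100 * (treated rate - base rate) / base rate`, where a state window uses
#' that state's total and `INTEGRATED` uses the time-weighted 24-h rate under
#' `arch`.
#'
#' @param base,treated Partition tables before and after [apply_treatment()].
#' @param window `"WAKE"`, `"NREM"`, `"REM"` or `"INTEGRATED"`.
#' @param arch A [sleep_architecture()]; required for `INTEGRATED`.
#' @return Per cent change (signed).
#' @export
#' @examples
#' base <- maintenance_partition()
#' treated <- apply_treatment(base, default_treatments()$protein_inhibitor)
#' detected_effect(base, treated, "NREM")  # about -14.70
detected_effect <- function(base, treated, window, arch = NULL) {
  if (!window %in% detection_windows()) {
    stop("'window' must be one of ", paste(detection_windows(), collapse = ", "),
         call. = FALSE)
  }
  tb <- state_totals(base)
  tt <- state_totals(treated)
  if (window == "INTEGRATED") {
    if (is.null(arch)) {
      stop("'arch' is required for the INTEGRATED window", call. = FALSE)
    }
    b <- integrated_rate(arch, tb)
    tr <- integrated_rate(arch, tt)
  } else {
    b <- tb[[window]]
    tr <- tt[[window]]
  }
  if (b <= 0) stop("base rate in window ", window, " is zero", call. = FALSE)
  100 * (tr - b) / b
}

#' Treatment-detection matrix across sampling windows
#'
#' For each treatment, computes the detected proportional SMR change under
#' wake-only, NREM-only, REM-only and 24-h integrated sampling, and a
#' normalized variant where each row is divided by its largest-magnitude
#' entry (so each row's maximum is 1: the proportion of the maximum treatment
#' effect detected in each window).
#'
#' @param table A [partition_table()].
#' @param treatments A list of [treatment()]s (e.g. [default_treatments()]).
#' @param arch A [sleep_architecture()] for the integrated window (default
#'   12 h awake, 9 h NREM, 3 h REM).
#' @return A list of class `detection_matrix`: `effect` (signed per cent
#'   changes), `normalized` (|effect| / row max |effect|), `max_window` (the
#'   window holding each row's maximum; ties broken by window order
#'   WAKE < NREM < REM < INTEGRATED and flagged in `ties`).
#' @export
#' @examples
#' effect_heatmap(maintenance_partition(), default_treatments())
effect_heatmap <- function(table, treatments,
                           arch = sleep_architecture(0.5, 0.375, 0.125)) {
  if (length(treatments) == 0) stop("need at least one treatment", call. = FALSE)
  if (inherits(treatments, "smr_treatment")) treatments <- list(treatments)
  wins <- detection_windows()
  eff <- matrix(NA_real_, length(treatments), length(wins),
                dimnames = list(vapply(treatments, `[[`, "", "name"), wins))
  for (i in seq_along(treatments)) {
    treated <- apply_treatment(table, treatments[[i]])
    for (w in wins) eff[i, w] <- detected_effect(table, treated, w, arch)
  }
  amax <- apply(abs(eff), 1, max)
  amax[amax == 0] <- NA_real_   # a no-op treatment has no maximum to scale by
  norm <- abs(eff) / amax
  max_window <- wins[apply(abs(eff), 1, which.max)]
  ties <- apply(abs(eff), 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1)
  structure(list(effect = eff, normalized = norm, max_window = max_window,
                 ties = ties, arch = arch),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("Detected treatment effect (% change) by sampling window:\n")
  print(round(x$effect, 2))
  cat("Proportion of maximum effect detected:\n")
  print(round(x$normalized, 3))
  if (any(x$ties)) cat("note: tie(s) in row maxima broken by window order\n")
  invisible(x)
}

#' Export a detection matrix as CSV
#'
#' @param dm A [effect_heatmap()] result.
#' @param path Output path.
#' @param normalized Write the normalized matrix (default) or the signed
#'   effects.
#' @return `path`, invisibly.
#' @export
write_detection_matrix <- function(dm, path, normalized = TRUE) {
  stopifnot(inherits(dm, "detection_matrix"))
  m <- if (normalized) dm$normalized else dm$effect
  df <- data.frame(treatment = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sleep-only versus integrated treatment-effect discrepancy
#'
#' Simulates a population of individuals varying in sleep duration and REM
#' share, applies a treatment, and for each individual-day computes the
#' treatment effect as it would be estimated from sleep-only sampling (the
#' individual's NREM/REM mix that day) and from full 24-h integration. Both
#' effects are expressed as per cent change relative to the untreated
#' time-integrated SMR. Day-to-day variation jitters sleep duration by
#' `cfg$night_sd_h`; measurement noise (CV `cfg$noise_cv` per trace sample)
#' propagates to the window means as `noise_cv / sqrt(n samples)`. An
#' individual-day with zero sleep cannot be sampled sleep-only and is flagged
#' rather than computed.
#'
#' @param cfg A [simulation_config()] (`n_nights` is the number of days).
#' @param t A [treatment()].
#' @param table A [partition_table()] (default: packaged table).
#' @return A data.frame of class `treatment_discrepancy` with columns `id`,
#'   `day`, `day_sleep_h`, `rem_share`, `sleep_only_effect_pct`,
#'   `integrated_effect_pct`, `flagged`.
#' @export
#' @examples
#' cfg <- simulation_config(n_individuals = 10, seed = 3)
#' head(sleep_only_bias_experiment(cfg, default_treatments()$protein_inhibitor))
sleep_only_bias_experiment <- function(cfg, t, table = maintenance_partition()) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(t, "smr_treatment"))
  base_tot <- state_totals(table)
  treat_tot <- state_totals(apply_treatment(table, t))
  pop <- simulate_population(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 2L)
  measured <- function(mu, hours) {
    n <- max(1, round(hours * 60 / cfg$dt_min))
    if (cfg$noise_cv == 0) mu
    else mu * (1 + cfg$noise_cv / sqrt(n) * stats::rnorm(1))
  }
  rows <- vector("list", nrow(pop) * cfg$n_nights)
  k <- 0
  for (i in seq_len(nrow(pop))) {
    for (day in seq_len(cfg$n_nights)) {
      sleep_day <- min(max(pop$sleep_h[i] + stats::rnorm(1, 0, cfg$night_sd_h), 0), 24)
      rs <- pop$rem_share[i]
      k <- k + 1
      if (sleep_day <= 0) {
        rows[[k]] <- data.frame(id = pop$id[i], day = day, day_sleep_h = 0,
                                rem_share = rs, sleep_only_effect_pct = NA_real_,
                                integrated_effect_pct = NA_real_, flagged = TRUE)
        next
      }
      arch <- daily_architecture(sleep_day, rs)
      sleep_mix <- c(NREM = 1 - rs, REM = rs)
      base_sleep <- measured(sum(sleep_mix * base_tot[names(sleep_mix)]), sleep_day)
      trt_sleep <- measured(sum(sleep_mix * treat_tot[names(sleep_mix)]), sleep_day)
      base_int <- measured(integrated_rate(arch, base_tot), 24)
      trt_int <- measured(integrated_rate(arch, treat_tot), 24)
      rows[[k]] <- data.frame(
        id = pop$id[i], day = day, day_sleep_h = sleep_day, rem_share = rs,
        sleep_only_effect_pct = 100 * (trt_sleep - base_sleep) / base_int,
        integrated_effect_pct = 100 * (trt_int - base_int) / base_int,
        flagged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("treatment_discrepancy", "data.frame")
  out
}
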