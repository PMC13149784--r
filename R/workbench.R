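# Workbench entry point: subcommand dispatch over the analysis modules, with
# CSV outputs and a JSON run manifest (seed, options, versions) per run so
# every artifact can be reproduced. A thin Rscript wrapper lives in
# inst/scripts/smrmosaic-cli.R.

parse_opts <- function(args, allowed, defaults) {
  opts <- defaults
  i <- 1
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop("expected an option, got '", key, "'", call. = FALSE)
    key <- sub("^--", "", key)
    if (!key %in% allowed) {
      stop("unknown option '--", key, "' for this subcommand", call. = FALSE)
    }
    if (i + 1 > length(args)) stop("option '--", key, "' needs a value", call. = FALSE)
    val <- args[i + 1]
    num <- suppressWarnings(as.numeric(val))
    opts[[key]] <- if (!is.na(num)) num else val
    i <- i + 2
  }
  opts
}

write_manifest <- function(out_dir, subcommand, opts) {
  manifest <- list(
    subcommand = subcommand,
    options = opts,
    seed = opts$seed,
    package = "smrmosaic",
    package_version = as.character(utils::packageVersion("smrmosaic")),
    r_version = as.character(getRversion()))
  path <- file.path(out_dir, paste0(gsub("-", "_", subcommand), "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Workbench command-line entry point
#'
#' Dispatches the subcommands `partition`, `error-curve`,
#' `simulate-population`, `treatment`, `idme` and `synth` over the package's
#' modules, writing CSV outputs plus a JSON run manifest (options, seed,
#' versions) into `--out-dir`. All stochastic subcommands are reproducible
#' given the same seed and options. Options are `--key value` pairs; unknown
#' keys are rejected.
#'
#' @param argv Character vector: the subcommand followed by options (defaults
#'   to the trailing command-line arguments when run via the bundled script).
#' @return Invisibly, a character vector of the files written.
#' @export
#' @examples
#' out <- tempfile(); dir.create(out)
#' workbench_main(c("partition", "--out-dir", out))
#' read.csv(file.path(out, "state_totals.csv"))
workbench_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    stop("usage: smrmosaic <partition|error-curve|simulate-population|",
         "treatment|idme|synth> [--key value ...]", call. = FALSE)
  }
  sub <- argv[1]
  args <- argv[-1]
  common <- list(`out-dir` = ".", seed = 1, table = "")
  get_table <- function(opts) {
    if (nzchar(opts$table)) load_partition_table(opts$table)
    else maintenance_partition()
  }
  files <- character(0)
  emit <- function(df, opts, name) {
    path <- file.path(opts$`out-dir`, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  if (sub == "partition") {
    opts <- parse_opts(args, names(common), common)
    tab <- get_table(opts)
    tot <- state_totals(tab)
    mult <- state_multipliers(tab)
    emit(data.frame(state = names(tot), total = as.numeric(tot),
                    multiplier_vs_wake = as.numeric(mult[names(tot)])),
         opts, "state_totals.csv")
  } else if (sub == "error-curve") {
    defaults <- c(common, list(`rem-share` = 0.25, `n-points` = 81,
                               `p-min` = 0.10, `p-max` = 0.90))
    opts <- parse_opts(args, names(defaults), defaults)
    curve <- error_curve(state_totals(get_table(opts)),
                         rem_share_of_sleep = opts$`rem-share`,
                         p_wake_range = c(opts$`p-min`, opts$`p-max`),
                         n_points = opts$`n-points`)
    emit(as.data.frame(curve), opts, "error_curve.csv")
  } else if (sub == "simulate-population") {
    defaults <- c(common, list(n = 200, nights = 5, window = 12,
                               `mean-smr` = 0.35, `noise-cv` = 0.05))
    opts <- parse_opts(args, names(defaults), defaults)
    cfg <- simulation_config(n_individuals = opts$n, n_nights = opts$nights,
                             window_h = opts$window, mean_smr = opts$`mean-smr`,
                             noise_cv = opts$`noise-cv`, seed = opts$seed)
    pop <- simulate_population(cfg)
    rec <- simulate_measurements(pop, state_totals(get_table(opts)))
    emit(as.data.frame(pop), opts, "population.csv")
    emit(as.data.frame(rec), opts, "measurements.csv")
  } else if (sub == "treatment") {
    defaults <- c(common, list(`ion-factor` = 0.5, `thermal-factor` = 1.5,
                               `p-wake` = 0.5, `p-nrem` = 0.375, `p-rem` = 0.125))
    opts <- parse_opts(args, names(defaults), defaults)
    dm <- effect_heatmap(get_table(opts),
                         default_treatments(opts$`ion-factor`,
                                            opts$`thermal-factor`),
                         sleep_architecture(opts$`p-wake`, opts$`p-nrem`,
                                            opts$`p-rem`))
    emit(data.frame(treatment = rownames(dm$effect), dm$effect,
                    check.names = FALSE), opts, "detected_effects.csv")
    emit(data.frame(treatment = rownames(dm$normalized), dm$normalized,
                    check.names = FALSE), opts, "detection_matrix.csv")
  } else if (sub == "idme") {
    defaults <- c(common, list(`wake-smr` = 1, `nrem-mult` = 0.83,
                               `rem-mult` = 0.44, `t-wake` = NA, `t-nrem` = NA,
                               `t-rem` = NA, hypnogram = ""))
    opts <- parse_opts(args, names(defaults), defaults)
    rates <- rates_from_wake_baseline(opts$`wake-smr`,
                                      c(NREM = opts$`nrem-mult`,
                                        REM = opts$`rem-mult`))
    times <- if (nzchar(opts$hypnogram)) {
      times_from_hypnogram(read_hypnogram(opts$hypnogram))
    } else if (!anyNA(c(opts$`t-wake`, opts$`t-nrem`, opts$`t-rem`))) {
      state_time_budget(opts$`t-wake`, opts$`t-nrem`, opts$`t-rem`)
    } else {
      stop("idme needs either --hypnogram or --t-wake/--t-nrem/--t-rem",
           call. = FALSE)
    }
    emit(data.frame(state = c(names(rates), "IDME"),
                    rate = c(as.numeric(rates), compute_idme(rates, times)),
                    time_fraction = c(as.numeric(times[names(rates)]), 1),
                    contribution = c(as.numeric(rates * times[names(rates)]),
                                     compute_idme(rates, times))),
         opts, "idme.csv")
  } else if (sub == "synth") {
    defaults <- c(common, list(duration = 24, `p-wake` = 0.5,
                               `p-nrem` = 0.375, `p-rem` = 0.125,
                               baseline = 1, `noise-cv` = 0.05, dt = 1))
    opts <- parse_opts(args, names(defaults), defaults)
    cfg <- bout_config(c(WAKE = opts$`p-wake`, NREM = opts$`p-nrem`,
                         REM = opts$`p-rem`), seed = opts$seed)
    h <- generate_hypnogram(cfg, opts$duration)
    tr <- rate_trace(h, state_totals(get_table(opts)),
                     baseline = opts$baseline, noise_cv = opts$`noise-cv`,
                     dt_min = opts$dt)
    emit(as.data.frame(h), opts, "hypnogram.csv")
    emit(as.data.frame(tr), opts, "rate_trace.csv")
  } else {
    stop("unknown subcommand '", sub, "'", call. = FALSE)
  }
  files <- c(files, write_manifest(opts$`out-dir`, sub, opts))
  invisible(files)
}
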