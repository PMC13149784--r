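#' Maintenance-process partition table
#'
#' The central object of the partition model: one row per maintenance process
#' (ion regulation, protein synthesis, thermoregulation, ...), with the
#' percentage of that process's daily energetic cost expended in each
#' sleep-wake state (`wake_pct`, `nrem_pct`, `rem_pct`), the percentage of
#' whole-day SMR attributed to the process (`total_smr_pct`), and ordinal
#' uncertainty rankings for both.
#'
#' @param df A data.frame with columns `process`, `wake_pct`, `nrem_pct`,
#'   `rem_pct`, `total_smr_pct`, `state_uncertainty`, `smr_uncertainty`.
#' @return `df` validated and classed as `partition_table`.
#' @details Partition percentages must be non-negative, `total_smr_pct`
#'   positive, and process names unique. Row partition sums are expected near
#'   100 (the residual-background row is conventionally printed as 33/33/33,
#'   summing to 99); deviations are reported by [validate_table()] rather
#'   than rejected here.
#' @export
partition_table <- function(df) {
  required <- c("process", "wake_pct", "nrem_pct", "rem_pct", "total_smr_pct",
                "state_uncertainty", "smr_uncertainty")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("partition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("partition table has no rows", call. = FALSE)
  num_cols <- c("wake_pct", "nrem_pct", "rem_pct", "total_smr_pct")
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      stop("column '", col, "' could not be parsed as numeric", call. = FALSE)
    }
    if (anyNA(df[[col]])) {
      stop("column '", col, "' contains missing or non-numeric values", call. = FALSE)
    }
  }
  if (anyDuplicated(df$process)) {
    stop("duplicate process name(s): ",
         paste(unique(df$process[duplicated(df$process)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$wake_pct < 0 | df$nrem_pct < 0 | df$rem_pct < 0)) {
    stop("partition percentages must be non-negative", call. = FALSE)
  }
  if (any(df$total_smr_pct <= 0)) {
    stop("total_smr_pct must be positive for every process", call. = FALSE)
  }
  df <- as.data.frame(df[, required], stringsAsFactors = FALSE)
  class(df) <- c("partition_table", "data.frame")
  df
}

#' Read a partition table from a CSV file
#'
#' Expects the header
#' `process,wake_pct,nrem_pct,rem_pct,total_smr_pct,state_uncertainty,smr_uncertainty`.
#' Percentages are on the 0-100 scale.
#'
#' @param path Path to a comma-separated file.
#' @return A [partition_table()].
#' @export
#' @examples
#' tab <- load_partition_table(
#'   system.file("extdata", "maintenance_partition.csv", package = "smrmosaic"))
#' nrow(tab)
load_partition_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  partition_table(df)
}

#' The packaged 12-process maintenance partition table
#'
#' Loads the package's default estimate of how the daily cost of each of 12
#' maintenance processes is partitioned across wakefulness, NREM and REM
#' sleep, together with each process's contribution to whole-day SMR. The
#' per-process contributions sum to 100% and yield state totals of
#' 44.03 / 36.73 / 19.18 (WAKE / NREM / REM).
#'
#' @return A [partition_table()] with 12 rows.
#' @export
#' @examples
#' state_totals(maintenance_partition())
maintenance_partition <- function() {
  load_partition_table(
    system.file("extdata", "maintenance_partition.csv", package = "smrmosaic"))
}

#' @export
print.partition_table <- function(x, ...) {
  cat("Maintenance-process partition table (", nrow(x), " processes)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, ...)
  tot <- state_totals(x)
  cat(sprintf("State totals: WAKE %.4g  NREM %.4g  REM %.4g  (total SMR %.4g%%)\n",
              tot[["WAKE"]], tot[["NREM"]], tot[["REM"]], sum(x$total_smr_pct)))
  invisible(x)
}

#' Validate a partition table against its accounting identities
#'
#' Reports, without erroring, the deviation of each row's state-partition sum
#' from 100 and the deviation of the total-SMR column sum from 100. A row or
#' the column total is flagged when its absolute deviation exceeds `tol`
#' percentage points. The conventional residual-background row (33/33/33)
#' deviates by exactly 1 and is unflagged at the default tolerance.
#'
#' @param table A [partition_table()].
#' @param tol Tolerance in percentage points (default 1).
#' @return A list of class `partition_validation` with elements
#'   `row_sum_deviations` (named, per process), `column_total_deviation`,
#'   `flags` (character), and `tol`.
#' @export
#' @examples
#' validate_table(maintenance_partition())
validate_table <- function(table, tol = 1) {
  stopifnot(inherits(table, "partition_table"))
  row_dev <- 100 - (table$wake_pct + table$nrem_pct + table$rem_pct)
  names(row_dev) <- table$process
  col_dev <- sum(table$total_smr_pct) - 100
  flags <- character(0)
  bad_rows <- names(row_dev)[abs(row_dev) > tol]
  if (length(bad_rows) > 0) {
    flags <- c(flags, paste0("partition sum of '", bad_rows,
                             "' deviates from 100 by more than ", tol, " points"))
  }
  if (abs(col_dev) > tol) {
    flags <- c(flags, paste0("total_smr_pct column sums to ", 100 + col_dev,
                             ", not 100"))
  }
  structure(list(row_sum_deviations = row_dev,
                 column_total_deviation = col_dev,
                 flags = flags, tol = tol),
            class = "partition_validation")
}

#' @export
print.partition_validation <- function(x, ...) {
  cat("Partition-table validation (tol = ", x$tol, " points)\n", sep = "")
  cat("  column total deviation: ", format(x$column_total_deviation), "\n", sep = "")
  if (length(x$flags) == 0) cat("  no flags\n") else {
    cat("  flags:\n"); for (f in x$flags) cat("   - ", f, "\n", sep = "")
  }
  invisible(x)
}

# internal: map a WAKE/NREM/REM label to the partition column
state_column <- function(state) {
  cols <- c(WAKE = "wake_pct", NREM = "nrem_pct", REM = "rem_pct")
  if (length(state) != 1L || !state %in% names(cols)) {
    stop("unknown state '", paste(state, collapse = ","),
         "'; use one of WAKE, NREM, REM", call. = FALSE)
  }
  cols[[state]]
}

#' Contribution of one process to SMR measured in one state
#'
#' The percentage of whole-day SMR a process would contribute to a rate
#' measurement made wholly within the given state:
#' `total_smr_pct * partition_state / 100`.
#'
#' @param table A [partition_table()].
#' @param process Process name (exact match).
#' @param state One of `"WAKE"`, `"NREM"`, `"REM"`.
#' @return A single percentage.
#' @export
#' @examples
#' state_contribution(maintenance_partition(), "Protein synthesis", "NREM")  # 10.8
state_contribution <- function(table, process, state) {
  stopifnot(inherits(table, "partition_table"))
  i <- match(process, table$process)
  if (is.na(i)) stop("unknown process '", process, "'", call. = FALSE)
  table$total_smr_pct[i] * table[[state_column(state)]][i] / 100
}

#' State totals of a partition table
#'
#' Sums the per-process state contributions into the relative metabolic rate
#' level of each state. For the packaged table these are the printed totals
#' 44.03 (WAKE), 36.73 (NREM) and 19.18 (REM).
#'
#' @param table A [partition_table()].
#' @return A [state_rate_profile()].
#' @export
state_totals <- function(table) {
  stopifnot(inherits(table, "partition_table"))
  w <- sum(table$total_smr_pct * table$wake_pct) / 100
  n <- sum(table$total_smr_pct * table$nrem_pct) / 100
  r <- sum(table$total_smr_pct * table$rem_pct) / 100
  state_rate_profile(w, n, r)
}

#' Wake-referenced (or any-state-referenced) rate multipliers
#'
#' Ratios of the state totals to a reference state's total. With the packaged
#' table and WAKE as reference these reproduce the literature-style correction
#' factors 0.83 (NREM) and 0.44 (REM) at two decimals.
#'
#' @param table A [partition_table()].
#' @param reference Reference state (default `"WAKE"`).
#' @param decimals Optional rounding of the returned multipliers; `NULL`
#'   (default) returns exact ratios.
#' @return Named numeric vector of multipliers over WAKE/NREM/REM; the
#'   reference entry is exactly 1.
#' @export
#' @examples
#' state_multipliers(maintenance_partition(), decimals = 2)
state_multipliers <- function(table, reference = "WAKE", decimals = NULL) {
  totals <- state_totals(table)
  state_column(reference)  # validates the label
  ref <- totals[[reference]]
  if (ref <= 0) stop("reference state total is zero; multipliers undefined", call. = FALSE)
  mult <- unclass(totals) / ref
  if (!is.null(decimals)) mult <- round(mult, decimals)
  mult[reference] <- 1
  mult
}
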