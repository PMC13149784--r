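# Fixtures built in code; the printed reference cells below are the hand
# arithmetic total_smr_pct * partition / 100 for the packaged table.

packaged_table <- function() maintenance_partition()

# per-state contribution cells of the packaged table, in row order
printed_cells <- function() {
  cbind(
    WAKE = c(7.5, 7.2, 1.8, 1.75, 10.5, 0.8, 4.5, 1.5, 0.9, 4.2, 1.4, 1.98),
    NREM = c(2.25, 4.2, 10.8, 4.2, 3.75, 1.8, 0.25, 3, 0.7, 1.4, 2.4, 1.98),
    REM = c(5.25, 0.6, 5.4, 1.05, 0.75, 1.4, 0.25, 0.5, 0.4, 1.4, 0.2, 1.98))
}

printed_totals <- function() c(WAKE = 44.03, NREM = 36.73, REM = 19.18)

# a minimal two-process table: equal processes, each 50/30/20 with total 50
two_process_table <- function() {
  partition_table(data.frame(
    process = c("A", "B"),
    wake_pct = c(50, 50), nrem_pct = c(30, 30), rem_pct = c(20, 20),
    total_smr_pct = c(50, 50),
    state_uncertainty = "Low", smr_uncertainty = "Low"))
}

single_process_table <- function(wake = 100, nrem = 0, rem = 0, total = 100) {
  partition_table(data.frame(
    process = "Only", wake_pct = wake, nrem_pct = nrem, rem_pct = rem,
    total_smr_pct = total,
    state_uncertainty = "Low", smr_uncertainty = "Low"))
}

# zero-noise trace with share `p_low` of samples at `low` and the rest at
# `high` (plain numeric; the estimators accept raw rate vectors)
two_level_values <- function(n = 1000, p_low = 0.3, low = 0.5, high = 1.0) {
  c(rep(low, round(p_low * n)), rep(high, n - round(p_low * n)))
}

default_arch <- function() sleep_architecture(0.5, 0.375, 0.125)
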