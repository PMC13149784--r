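tab <- maintenance_partition()
arch <- sleep_architecture(0.5, 0.375, 0.125)
protein <- default_treatments()$protein_inhibitor

test_that("treatments rescale targeted process costs and nothing else", {
  treated <- apply_treatment(tab, protein)
  expect_equal(state_contribution(treated, "Protein synthesis", "NREM"), 5.4)
  expect_equal(state_contribution(treated, "Thermoregulation", "WAKE"), 10.5)
  expect_equal(treated$wake_pct, tab$wake_pct)  # partitions untouched
  expect_equal(apply_treatment(tab, treatment("noop", "Protein synthesis", 1)),
               tab)
  knockout <- apply_treatment(tab, treatment("ko", "Protein synthesis", 0))
  for (s in smr_states()) {
    expect_equal(state_contribution(knockout, "Protein synthesis", s), 0)
  }
  expect_error(apply_treatment(tab, treatment("x", "Dark energy", 0.5)),
               "unknown target")
  expect_error(treatment("x", character(0), 0.5), "non-empty")
  expect_error(treatment("x", "Protein synthesis", -1), "non-negative")
})

test_that("detected effects match the hand-derived window arithmetic", {
  treated <- apply_treatment(tab, protein)
  expect_equal(detected_effect(tab, treated, "NREM"), 100 * -0.5 * 10.8 / 36.73)
  expect_equal(round(detected_effect(tab, treated, "NREM"), 2), -14.70)
  expect_equal(round(detected_effect(tab, treated, "WAKE"), 2), -2.04)
  expect_equal(round(detected_effect(tab, treated, "REM"), 2), -14.08)
  # hand oracle: -0.5 * (0.5*1.8 + 0.375*10.8 + 0.125*5.4) / 38.18625
  expect_equal(round(detected_effect(tab, treated, "INTEGRATED", arch), 2), -7.37)
  expect_error(detected_effect(tab, treated, "INTEGRATED"), "required")
  expect_error(detected_effect(tab, treated, "ASLEEP"), "must be one of")
  noop <- apply_treatment(tab, treatment("noop", "Thermoregulation", 1))
  for (w in c("WAKE", "NREM", "REM")) {
    expect_equal(detected_effect(tab, noop, w), 0)
  }
  expect_equal(detected_effect(tab, noop, "INTEGRATED", arch), 0)
})

test_that("the integrated effect decomposes over state effects exactly", {
  base_tot <- state_totals(tab)
  for (t in default_treatments()) {
    treated <- apply_treatment(tab, t)
    int_eff <- detected_effect(tab, treated, "INTEGRATED", arch)
    state_eff <- vapply(smr_states(),
                        function(s) detected_effect(tab, treated, s), numeric(1))
    w <- unclass(arch) * unclass(base_tot)  # base-rate x time-share weights
    expect_equal(int_eff, sum(w * state_eff[names(w)]) / sum(w),
                 tolerance = 1e-9)
  }
})

test_that("the detection heatmap normalizes rows to their maximum window", {
  dm <- effect_heatmap(tab, default_treatments(), arch)
  expect_equal(unname(dm$max_window),
               c("NREM", "WAKE", "WAKE"))
  expect_equal(unname(dm$normalized[1, "NREM"]), 1)
  expect_equal(unname(dm$normalized[2, "WAKE"]), 1)
  expect_equal(unname(dm$normalized[3, "WAKE"]), 1)
  expect_true(all(dm$normalized >= 0 & dm$normalized <= 1))
  expect_equal(unname(apply(dm$normalized, 1, max)), rep(1, 3))
  expect_false(any(dm$ties))
  single <- effect_heatmap(tab, list(protein), arch)
  expect_equal(max(single$normalized), 1)
})

test_that("window ranking of a single-process treatment follows its SMR share", {
  tot <- state_totals(tab)
  for (proc in c("Protein synthesis", "Thermoregulation", "Sensory processing")) {
    t <- treatment("probe", proc, 0.5)
    treated <- apply_treatment(tab, t)
    eff <- vapply(smr_states(),
                  function(s) abs(detected_effect(tab, treated, s)), numeric(1))
    share <- vapply(smr_states(),
                    function(s) state_contribution(tab, proc, s) / tot[[s]],
                    numeric(1))
    expect_equal(order(eff), order(share))
  }
})

test_that("sleep-only sampling exaggerates a sleep-active treatment effect", {
  cfg <- simulation_config(n_individuals = 200, seed = 13)
  dis <- sleep_only_bias_experiment(cfg, protein)
  expect_equal(nrow(dis), 1000L)
  ok <- !dis$flagged
  expect_gt(mean(abs(dis$sleep_only_effect_pct[ok])),
            mean(abs(dis$integrated_effect_pct[ok])))
  # individuals identical except for REM share report different sleep-only
  # effects (the protein inhibitor acts more on NREM than on REM)
  run_rs <- function(rs) {
    cfg0 <- simulation_config(n_individuals = 1, n_nights = 1, sd_smr = 0,
                              sleep_mean_h = 9, sleep_sd_h = 0,
                              rem_share_range = c(rs, rs), night_sd_h = 0,
                              noise_cv = 0, seed = 2)
    sleep_only_bias_experiment(cfg0, protein)$sleep_only_effect_pct
  }
  expect_false(isTRUE(all.equal(run_rs(0.10), run_rs(0.30))))
})

test_that("an individual asleep all day shows no sleep-only discrepancy", {
  cfg <- simulation_config(n_individuals = 3, n_nights = 2, window_h = 24,
                           sleep_mean_h = 24, sleep_sd_h = 0,
                           sleep_range_h = c(24, 24), night_sd_h = 0,
                           noise_cv = 0, seed = 5)
  dis <- sleep_only_bias_experiment(cfg, protein)
  expect_equal(dis$sleep_only_effect_pct, dis$integrated_effect_pct,
               tolerance = 1e-9)
})
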