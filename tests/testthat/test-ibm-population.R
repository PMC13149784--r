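tab_profile <- state_totals(maintenance_partition())

test_that("population draws honour the configured distributions", {
  cfg <- simulation_config(seed = 101)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop), 200L)
  se <- cfg$sd_smr / sqrt(cfg$n_individuals)
  expect_lt(abs(mean(pop$true_smr) - 0.35), 3 * se)
  expect_true(all(pop$sleep_h >= 6 & pop$sleep_h <= 12))
  expect_true(all(pop$rem_share >= 0.10 & pop$rem_share <= 0.35))
  expect_equal(pop$mmr, 3 * pop$true_smr)

  degenerate <- simulate_population(simulation_config(n_individuals = 10,
                                                      sd_smr = 0, seed = 1))
  expect_equal(degenerate$true_smr, rep(0.35, 10))
  expect_error(simulation_config(n_individuals = 0), "at least 1")
  expect_error(simulation_config(window_h = 30), "\\(0, 24\\]")
})

test_that("individual state rates conserve the true integrated SMR", {
  pop <- simulate_population(simulation_config(n_individuals = 25, seed = 7))
  rates <- individual_rates(pop$true_smr, pop$sleep_h, pop$rem_share, tab_profile)
  for (i in seq_len(nrow(pop))) {
    p_sleep <- pop$sleep_h[i] / 24
    arch <- c(1 - p_sleep, p_sleep * (1 - pop$rem_share[i]),
              p_sleep * pop$rem_share[i])
    expect_equal(sum(arch * rates[i, ]), pop$true_smr[i], tolerance = 1e-9)
  }
  expect_equal(individual_rates(0.35, 12, 0.25)[1, "WAKE"],
               c(WAKE = 0.40356), tolerance = 1e-5)
})

test_that("overnight estimates are convex combinations of the state rates", {
  rates <- individual_rates(0.35, 9, 0.2)[1, ]
  # fully asleep, no REM: the window mean is exactly the NREM rate
  est <- overnight_estimate(0.35, 12, 0, window_h = 12)
  expect_equal(est, individual_rates(0.35, 12, 0)[1, "NREM"],
               tolerance = 1e-12, ignore_attr = TRUE)
  est2 <- overnight_estimate(0.35, 9, 0.2, window_h = 12)
  expect_true(est2 <= rates[["WAKE"]] && est2 >= rates[["REM"]])
  expect_error(overnight_estimate(0.35, 13, 0.2, window_h = 12),
               "exceeds the measurement window")
})

test_that("relative error is architecture-determined; absolute error scales with SMR", {
  # two individuals sharing sleep traits but differing in true SMR
  for (smr in c(0.25, 0.35, 0.5)) {
    est <- overnight_estimate(smr, 9, 0.2, window_h = 12)
    truth_rel <- (est - smr) / smr
    if (smr == 0.25) rel_ref <- truth_rel
    expect_equal(truth_rel, rel_ref, tolerance = 1e-12)
  }
  abs_err <- vapply(c(0.25, 0.35, 0.5), function(smr) {
    abs(overnight_estimate(smr, 9, 0.2, window_h = 12) - smr)
  }, numeric(1))
  expect_true(all(diff(abs_err) > 0))
  expect_equal(abs_err[3] / abs_err[1], 0.5 / 0.25, tolerance = 1e-9)
})

test_that("nightly estimates repeat exactly without noise or night-to-night jitter", {
  cfg <- simulation_config(n_individuals = 4, night_sd_h = 0, noise_cv = 0,
                           seed = 17)
  pop <- simulate_population(cfg)
  rec <- simulate_measurements(pop, tab_profile)
  per_ind <- tapply(rec$estimate, rec$id, function(x) length(unique(x)))
  expect_true(all(per_ind == 1))
  expect_true(all(rec$estimate < rec$true_smr))  # sleep-weighted window
})

test_that("aerobic scope ordering follows the inverted state-rate ordering", {
  pop <- simulate_population(simulation_config(n_individuals = 50, seed = 23))
  s_w <- aerobic_scope(pop, "WAKE", tab_profile)
  s_n <- aerobic_scope(pop, "NREM", tab_profile)
  s_r <- aerobic_scope(pop, "REM", tab_profile)
  expect_true(all(s_r > s_n & s_n > s_w))
  expect_true(all(s_w > 0))
  low_mmr <- pop
  low_mmr$mmr <- 0.1
  expect_error(aerobic_scope(low_mmr, "WAKE", tab_profile), "MMR must exceed")
})

test_that("bias summaries capture underestimation and its scaling", {
  cfg <- simulation_config(n_individuals = 60, seed = 31)
  pop <- simulate_population(cfg)
  rec <- simulate_measurements(pop, tab_profile)
  bs <- bias_summary(pop, rec)
  expect_true(all(bs$per_individual$mean_signed_error < 0))
  expect_lt(unname(coef(bs$regression)[2]), 1)  # shallower than the identity line
  expect_gt(unname(bs$abs_error_cor$estimate), 0)
  # a normally sleeping individual kept awake all night is measured at its
  # wake rate, above its integrated truth
  est_awake <- overnight_estimate(0.35, 9, 0.2, window_h = 12,
                                  night_sleep_h = 0)
  expect_gt(est_awake, 0.35)
  expect_equal(est_awake, individual_rates(0.35, 9, 0.2)[1, "WAKE"],
               ignore_attr = TRUE)
})
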