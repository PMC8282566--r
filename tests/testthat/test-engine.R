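test_that("degenerate configurations reproduce closed forms", {
  cfg <- degenerate_config()
  res <- run_arm(cfg, NULL, n_trials = 50, seed = 1)
  # nobody dies or fractures, utility 1, no discounting: 40 life-years
  expect_equal(res$mean_qaly, 40, tolerance = 1e-6)
  expect_equal(res$mean_cost_total, 0, tolerance = 1e-3)
  expect_equal(res$p_any_hip, 0)
  expect_equal(res$p_any_vert, 0)
  expect_equal(res$p_dead_by_horizon, 0)

  oracle <- cohort_oracle(cfg)
  expect_equal(oracle$mean_qaly, 40, tolerance = 1e-6)
  expect_equal(oracle$mean_cost_total, 0, tolerance = 1e-3)

  # certain death in the first cycle: no utility accrues (no half-cycle)
  dead_cfg <- attach_life_table(cfg, flat_life_table(1))
  res_dead <- run_arm(dead_cfg, NULL, n_trials = 20, seed = 1)
  expect_equal(res_dead$mean_qaly, 0)
  expect_equal(res_dead$p_dead_by_horizon, 1)
  # the dying still get charged the first treatment cycle
  res_tx <- run_arm(dead_cfg, "za", n_trials = 20, seed = 1)
  expect_equal(res_tx$mean_cost_total,
               annual_treatment_cost("za", 1, "persistent_full_year",
                                     dead_cfg))
})

test_that("the engine is deterministic given (config, seed, n_trials)", {
  cfg <- make_toy_config()
  a <- run_arm(cfg, "za", 500, seed = 7)
  b <- run_arm(cfg, "za", 500, seed = 7)
  expect_identical(a, b)
  c <- run_arm(cfg, "za", 500, seed = 8)
  expect_false(identical(a$mean_cost_total, c$mean_cost_total))

  # a single trial's means are that individual's totals
  one <- run_arm(cfg, "za", 1, seed = 3)
  expect_identical(one$n_trials, 1L)
  expect_equal(one$mc_se_qaly, 0)
})

test_that("microsimulation agrees with the exact cohort expectation", {
  cfg <- make_toy_config(n_trials = 20000L)

  # no-treatment arm against the cohort oracle (primary correctness check)
  oracle <- cohort_oracle(cfg)
  sim <- run_validation(cfg, n_trials = 20000, seed = 11)
  expect_lt(abs(sim$mean_qaly - oracle$mean_qaly), 3 * sim$mc_se_qaly)
  expect_lt(abs(sim$mean_cost_total - oracle$mean_cost_total),
            3 * sim$mc_se_cost_total)
  for (p in c("p_any_hip", "p_any_vert", "p_dead_by_horizon")) {
    se <- sqrt(oracle[[p]] * (1 - oracle[[p]]) / 20000)
    expect_lt(abs(sim[[p]] - oracle[[p]]), 3 * se + 1e-9)
  }

  # treated arms against the trajectory-mixed expectation
  for (arm in c("za", "da")) {
    exact <- arm_expectation(cfg, arm)
    sim <- run_arm(cfg, arm, n_trials = 20000, seed = 13)
    expect_lt(abs(sim$mean_qaly - exact$mean_qaly), 3 * sim$mc_se_qaly)
    expect_lt(abs(sim$mean_cost_total - exact$mean_cost_total),
              3 * sim$mc_se_cost_total)
  }
})

test_that("the scalar reference path agrees with the oracle", {
  cfg <- make_toy_config()
  oracle <- cohort_oracle(cfg)
  set.seed(99)
  runs <- replicate(3000, simulate_individual(cfg, NULL), simplify = FALSE)
  qa <- vapply(runs, `[[`, 0, "qaly")
  cost <- vapply(runs, function(r) r$cost_hc + r$cost_ltc, 0)
  expect_lt(abs(mean(qa) - oracle$mean_qaly), 3 * sd(qa) / sqrt(3000))
  expect_lt(abs(mean(cost) - oracle$mean_cost_total),
            3 * sd(cost) / sqrt(3000))
  expect_lt(abs(mean(vapply(runs, `[[`, TRUE, "any_vert")) -
                  oracle$p_any_vert), 0.03)
})

test_that("neutral treatment efficacy collapses the arms onto no treatment", {
  ones <- list(rr_hip = 1, rr_hip_ci = c(1, 1), rr_vert = 1,
               rr_vert_ci = c(1, 1))
  cfg <- make_toy_config(overrides = list(
    efficacy = list(za = ones, deno = ones, aln = ones)))
  nt <- run_arm(cfg, NULL, 4000, seed = 5)
  for (arm in c("za", "da")) {
    tx <- run_arm(cfg, arm, 4000, seed = 5)
    # common random numbers: identical event histories, bit for bit
    expect_identical(tx$p_any_hip, nt$p_any_hip)
    expect_identical(tx$p_any_vert, nt$p_any_vert)
    expect_identical(tx$p_dead_by_horizon, nt$p_dead_by_horizon)
    expect_identical(tx$mean_qaly, nt$mean_qaly)
    # only treatment costs differ
    expect_gt(tx$mean_cost_total, nt$mean_cost_total)
  }
})

test_that("Monte-Carlo error shrinks like one over root n", {
  cfg <- make_toy_config()
  a <- run_arm(cfg, "za", 4000, seed = 21)
  b <- run_arm(cfg, "za", 16000, seed = 21)
  ratio <- b$mc_se_qaly / a$mc_se_qaly
  expect_gt(ratio, 0.38)
  expect_lt(ratio, 0.65)
  # qaly bound: cannot exceed discounted years to horizon
  n_cycles <- cfg$horizon_age - cfg$start_age
  expect_lt(b$mean_qaly, sum(discount_factor(1:n_cycles, 0.02)))
  expect_gte(b$mean_cost_total, 0)
})

test_that("an incomplete configuration is rejected", {
  cfg <- default_parameters()
  expect_error(run_arm(cfg, "za", 10, 1), "life table")
  lt_short <- load_life_table(c("age,qx", "70,0.01", "105,0.5"))
  expect_error(attach_life_table(cfg, lt_short), "coverage")
})
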