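test_that("discounting is annual with an undiscounted first cycle", {
  expect_equal(discount_factor(1, 0.02), 1.0)
  expect_equal(discount_factor(3, 0.02), 1 / 1.02^2)
  expect_equal(discount_factor(17, 0), 1.0)
  expect_error(discount_factor(0, 0.02), ">= 1")
  # discounted totals never exceed undiscounted ones
  expect_true(all(discount_factor(1:50, 0.02) <= 1))
})

test_that("annual treatment costs follow the fee schedule", {
  cfg <- default_parameters()
  # zoledronic acid: infusion + 2 visits (one first-visit fee in year 1)
  # + 2 blood tests
  expect_equal(annual_treatment_cost("za", 1, "persistent_full_year", cfg),
               38000 + 5500 + 3900 + 2 * 2900)
  expect_equal(annual_treatment_cost("za", 2, "persistent_full_year", cfg),
               38000 + 2 * 3900 + 2 * 2900)
  # denosumab: 4 visits, 4 blood tests
  expect_equal(annual_treatment_cost("deno", 2, "persistent_full_year", cfg),
               58000 + 4 * 1500 + 4 * 2900)  # 75600
  expect_equal(annual_treatment_cost("deno", 1, "persistent_full_year", cfg),
               58000 + 3100 + 3 * 1500 + 4 * 2900)
  # alendronate: medication scaled by that year's adherence
  expect_equal(annual_treatment_cost("aln", 1, "persistent_full_year", cfg),
               8700 * 0.706 + 1700 + 3600 + 3 * 1900 + 2 * 2900)
  # stop years: half of every annual component ...
  expect_equal(annual_treatment_cost("za", 2, "stops_this_year", cfg),
               (38000 + 2 * 3900 + 2 * 2900) / 2)
  # ... except the printed floors
  expect_equal(annual_treatment_cost("aln", 1, "stops_this_year", cfg),
               8700 / 4 + 1700 / 4 + 3600 + 2900)
  expect_equal(annual_treatment_cost("deno", 1, "stops_this_year", cfg),
               58000 / 2 + 3100 + 2 * 2900)
  expect_error(annual_treatment_cost("teriparatide", 1,
                                     "persistent_full_year", cfg),
               "unknown drug")
})

test_that("scenario flags reprice denosumab", {
  bios <- default_parameters()
  bios$scenario_flags$biosimilar_deno <- TRUE
  expect_equal(annual_treatment_cost("deno", 2, "persistent_full_year", bios),
               0.6 * 58000 + 4 * 1500 + 4 * 2900)
  fewer <- default_parameters()
  fewer$scenario_flags$reduced_deno_visits <- TRUE
  expect_equal(annual_treatment_cost("deno", 2, "persistent_full_year", fewer),
               58000 + 2 * 1500 + 2 * 2900)
})

test_that("monitoring, fracture and long-term care costs follow the rules", {
  cfg <- default_parameters()
  expect_equal(dxa_cost_due(3, cfg), 4500)
  expect_equal(dxa_cost_due(6, cfg), 4500)
  expect_equal(dxa_cost_due(4, cfg), 0)

  expect_equal(fracture_event_cost("vert", 0, cfg), 420000)
  expect_equal(fracture_event_cost("vert", 2, cfg), 842000)
  expect_equal(fracture_event_cost("hip", 1, cfg), 1726000)

  post_hip <- list(hip_count = 1L, vert_count = 2L)
  post_vert <- list(hip_count = 0L, vert_count = 1L)
  none <- list(hip_count = 0L, vert_count = 0L)
  expect_equal(annual_ltc_cost(post_hip, "healthcare_plus_ltc", cfg), 876000)
  expect_equal(annual_ltc_cost(post_vert, "healthcare_plus_ltc", cfg), 213000)
  expect_equal(annual_ltc_cost(none, "healthcare_plus_ltc", cfg), 0)
  expect_equal(annual_ltc_cost(post_hip, "healthcare_only", cfg), 0)
})

test_that("cycle utility applies event-year and lifelong multipliers", {
  u <- default_parameters()$utilities
  fresh <- c(new_fracture_history())
  expect_equal(cycle_utility(68, fresh, u), 0.862)
  hip_now <- fresh
  hip_now$hip_count <- 1L
  hip_now$hip_event_this_cycle <- TRUE
  expect_equal(cycle_utility(72, hip_now, u), 0.810 * 0.776)
  # vertebral event in a post-hip woman takes the vertebral event multiplier
  vert_in_post_hip <- fresh
  vert_in_post_hip$hip_count <- 1L
  vert_in_post_hip$vert_count <- 1L
  vert_in_post_hip$vert_event_this_cycle <- TRUE
  expect_equal(cycle_utility(72, vert_in_post_hip, u), 0.810 * 0.724)
  # post-hip dominates post-vertebral in later years
  both_later <- fresh
  both_later$hip_count <- 1L
  both_later$vert_count <- 1L
  expect_equal(cycle_utility(87, both_later, u), 0.684 * 0.855)
  vert_later <- fresh
  vert_later$vert_count <- 1L
  expect_equal(cycle_utility(87, vert_later, u), 0.684 * 0.868)
})

test_that("strategy comparison classifies dominance and computes ICERs", {
  arm <- function(name, cost, qaly) {
    structure(list(strategy = name, start_age = 65L,
                   perspective = "healthcare_plus_ltc",
                   mean_cost_total = cost * 105, mean_cost_hc = cost * 105,
                   mean_qaly = qaly), class = "arm_result")
  }
  za <- arm("za", 23710, 14.219)
  da <- arm("da", 24160, 14.218)
  cmp <- compare(za, da)
  expect_identical(cmp$verdict, "cost_saving")
  expect_true(cmp$delta_cost < 0 && cmp$delta_qaly > 0)

  cmp2 <- compare(arm("a", 24660, 14.229), da)
  expect_identical(cmp2$verdict, "icer")
  expect_equal(cmp2$icer_value, 500 * 105 / 0.011, tolerance = 1e-9)

  expect_identical(compare(arm("a", 25000, 14.0), da)$verdict, "dominated")
  expect_error(compare(da, da), "indeterminate")
  tie <- compare(arm("a", 24000, 14.218), da)
  expect_true(tie$qaly_tie)
  expect_identical(tie$verdict, "cost_saving")

  # verdict is currency-invariant: scaling both costs by the exchange rate
  # changes nothing qualitative
  cmp_usd <- compare(arm("za", 23710 / 105, 14.219),
                     arm("da", 24160 / 105, 14.218))
  expect_identical(cmp_usd$verdict, cmp$verdict)
})

test_that("acceptability is the share of draws with positive net benefit", {
  deltas <- data.frame(delta_cost = c(-1, 10, 5),
                       delta_qaly = c(0.01, 0.001, -0.01))
  expect_equal(ceac(deltas, 5000)$probability, 1 / 3)
  all_saving <- data.frame(delta_cost = c(-5, -1), delta_qaly = c(0.1, 0.2))
  expect_equal(ceac(all_saving, 1)$probability, 1)
  expect_equal(ceac(all_saving, 1e9)$probability, 1)
  # exact tie counts as not cost-effective
  tie <- data.frame(delta_cost = 50, delta_qaly = 0.01)
  expect_equal(ceac(tie, 5000)$probability, 0)
  expect_error(ceac(data.frame(delta_cost = numeric(0),
                               delta_qaly = numeric(0)), 5000),
               "at least one")
})
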