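test_that("on-treatment relative risk scales linearly with adherence", {
  expect_equal(on_treatment_rr("aln", "hip", 0.706), 1 - 0.706 * (1 - 0.64))
  expect_equal(on_treatment_rr("za", "vert", 1.0), 0.40)
  expect_equal(on_treatment_rr("deno", "vert", 1.0), 0.30)
  for (drug in c("za", "deno", "aln")) {
    expect_equal(on_treatment_rr(drug, "hip", 0), 1.0)
  }
  expect_error(on_treatment_rr("xx", "hip", 1), "unknown drug")
  expect_error(on_treatment_rr("za", "arm", 1), "unknown site")
})

test_that("offset ramps linearly to baseline over the treated period", {
  expect_equal(offset_rr("za", "vert", 3, 1.5, 0.40), 0.70)
  expect_equal(offset_rr("aln", "hip", 3, 3, 0.76), 1.0)
  expect_equal(offset_rr("za", "hip", 3, 7, 0.64), 1.0)  # past the ramp
  expect_equal(offset_rr("deno", "vert", 3, 0.1, 0.30), 1.0)  # cliff
  expect_equal(offset_rr("za", "hip", 0, 1, 0.64), 1.0)  # never treated
  expect_error(offset_rr("za", "hip", 3, 0, 0.64), "> 0")
  # non-decreasing in time since stop, capped at 1
  ts <- seq(0.1, 8, by = 0.1)
  rr <- vapply(ts, function(t) offset_rr("za", "hip", 3, t, 0.64), 0)
  expect_true(all(diff(rr) >= 0))
  expect_true(all(rr >= 0.64 & rr <= 1))
})

test_that("the status machine hands denosumab completers to alendronate", {
  cfg <- default_parameters()
  da <- resolve_strategy(cfg, cfg$strategies$da)

  # completer of the denosumab episode starts alendronate in year 4
  st <- new_treatment_status()
  for (t in 1:3) st <- advance_status(st, TRUE, da, cfg)
  expect_identical(st$current_drug, "deno")
  expect_identical(st$episode_year, 3L)
  st <- advance_status(st, TRUE, da, cfg)
  expect_identical(st$current_drug, "aln")
  expect_identical(st$episode_year, 1L)
  expect_true(st$started_alendronate)

  # denosumab stopper in year 2 has no protection from year 2 on (cliff,
  # and no alendronate)
  st <- new_treatment_status()
  st <- advance_status(st, TRUE, da, cfg)
  st <- advance_status(st, FALSE, da, cfg)  # stops during year 2
  expect_identical(st$phase, "stop_year")
  expect_equal(cycle_rr(st, "vert", cfg), 1.0)
  st <- advance_status(st, TRUE, da, cfg)   # year 3
  expect_identical(st$phase, "offset")
  expect_false(st$started_alendronate)
  expect_equal(cycle_rr(st, "vert", cfg), 1.0)
  expect_equal(cycle_rr(st, "hip", cfg), 1.0)
})

test_that("the long-duration ZA strategy inserts a 2-year gap between courses", {
  cfg <- default_parameters()
  cfg$scenario_flags$long_duration <- TRUE
  za <- resolve_strategy(cfg, cfg$strategies$za)
  expect_length(za$episodes, 2)
  expect_identical(za$episodes[[2]]$gap_before, 2L)
  expect_length(za$episodes[[1]]$curve, 6)
  # year-4..6 persistence extends the printed 3-year curve
  expect_equal(round(100 * za$episodes[[1]]$curve[4:6]), c(25, 17, 12))

  st <- new_treatment_status()
  for (t in 1:6) st <- advance_status(st, TRUE, za, cfg)
  expect_identical(st$episode_year, 6L)
  st <- advance_status(st, TRUE, za, cfg)  # gap year 1
  expect_identical(st$phase, "gap")
  expect_lt(cycle_rr(st, "hip", cfg), 1.0)  # residual effect during the gap
  st <- advance_status(st, TRUE, za, cfg)  # gap year 2
  expect_identical(st$phase, "gap")
  st <- advance_status(st, TRUE, za, cfg)  # second course begins
  expect_identical(st$phase, "on")
  expect_identical(st$episode_index, 2L)
  expect_identical(st$episode_year, 1L)

  # sequential arm under long durations: alendronate holds flat after year 7
  da <- resolve_strategy(cfg, cfg$strategies$da)
  aln_curve <- da$episodes[[2]]$curve
  expect_length(aln_curve, 10)
  expect_equal(aln_curve[8:10], rep(aln_curve[7], 3))
})

test_that("trajectory schedules encode the treatment rules cycle by cycle", {
  cfg <- attach_life_table(default_parameters(), make_synthetic_life_table())
  sched <- build_strategy_schedules(cfg, cfg$strategies$za)
  expect_equal(sum(sched$prob), 1, tolerance = 1e-12)

  stops1 <- vapply(sched$trajectories, function(tr) tr$stops[1], 1L)
  completer <- which(is.na(stops1))
  # completer: 3 on-treatment years, then the mid-cycle linear ramp over 3
  # post-years, then no effect
  expect_equal(sched$rr_hip[completer, 1:8],
               c(rep(0.64, 3),
                 0.64 + 0.36 * c(0.5, 1.5, 2.5) / 3, 1, 1),
               tolerance = 1e-12)
  # year-2 stopper: protected year 1 only; one completed year gives a
  # 1-year ramp: mid-cycle value in the first post-year, gone afterwards
  s2 <- which(stops1 == 2L)
  expect_equal(sched$rr_hip[s2, 1:4], c(0.64, 1, 0.64 + 0.36 * 0.5, 1),
               tolerance = 1e-12)
  expect_equal(sched$prob[s2], 0.48)

  # all cycle relative risks lie in (0, 1]
  for (s in list(sched, build_strategy_schedules(cfg, cfg$strategies$da))) {
    expect_true(all(s$rr_hip > 0 & s$rr_hip <= 1))
    expect_true(all(s$rr_vert > 0 & s$rr_vert <= 1))
    expect_true(all(s$cost >= 0))
  }
})

test_that("alendronate uptake equals the denosumab completion probability", {
  cfg <- attach_life_table(default_parameters(), make_synthetic_life_table())
  sched <- build_strategy_schedules(cfg, cfg$strategies$da)
  started_aln <- vapply(sched$trajectories,
                        function(tr) is.na(tr$stops[1]), TRUE)
  expect_equal(sum(sched$prob[started_aln]), 0.37, tolerance = 1e-12)
  # and the microsimulated fraction agrees within Monte-Carlo error
  sd_deno <- stop_distribution(cfg$persistence$deno$cumulative)
  expect_equal(sd_deno$complete, 0.37)
})
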