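test_that("base-case parameters reproduce the published parameter table", {
  cfg <- default_parameters()

  expect_equal(cfg$efficacy$za$rr_hip, 0.64)
  expect_equal(cfg$efficacy$za$rr_vert, 0.40)
  expect_equal(cfg$efficacy$za$rr_vert_ci, c(0.29, 0.55))
  expect_equal(cfg$efficacy$deno$rr_hip, 0.56)
  expect_equal(cfg$efficacy$deno$rr_vert, 0.30)
  expect_equal(cfg$efficacy$aln$rr_hip, 0.64)
  expect_equal(cfg$efficacy$aln$rr_vert, 0.50)

  expect_equal(cfg$persistence$za$cumulative, c(1.00, 0.52, 0.36))
  expect_equal(cfg$persistence$deno$cumulative, c(0.81, 0.55, 0.37))
  expect_equal(cfg$persistence$aln$cumulative, c(0.55, 0.39, 0.28))
  expect_equal(cfg$adherence$anchors$fraction, c(0.706, 0.609))

  expect_equal(cfg$incidence$hip$rate,
               c(83.9, 158.1, 362.2, 851.1, 1580.2, 2466.0, 2961.7, 2471.0))
  expect_equal(cfg$incidence$vert$rate,
               c(156.7, 513.9, 1106.2, 2034.1, 2331.2, 3638.0, 4369.3,
                 3645.4))
  expect_equal(cfg$risk$rr_osteo_hip$rr, c(2.39, 1.89, 1.57, 1.35, 1.25))
  expect_equal(cfg$risk$rr_osteo_vert$rr, c(2.47, 2.09, 1.86))
  expect_equal(cfg$risk$rr_prior_hip, 2.3)
  expect_equal(cfg$risk$rr_prior_vert, 4.4)
  expect_equal(cfg$risk$rh_mort_hip_year1, 2.87)
  expect_equal(cfg$risk$rh_mort_hip_later, 1.73)
  expect_equal(cfg$risk$attributable_fraction_hip, 0.25)
  expect_equal(cfg$risk$attributable_fraction_vert, 0)

  expect_equal(unname(cfg$costs$med_annual),
               c(38000, 58000, 8700))
  expect_equal(cfg$costs$rx_charge_aln, 1700)
  expect_equal(unname(cfg$costs$visit_first), c(5500, 3100, 3600))
  expect_equal(unname(cfg$costs$visit_subsequent), c(3900, 1500, 1900))
  expect_equal(cfg$costs$blood_test, 2900)
  expect_equal(cfg$costs$dxa, 4500)
  expect_equal(cfg$costs$fx_hip, 1726000)
  expect_equal(cfg$costs$fx_vert_first, 420000)
  expect_equal(cfg$costs$fx_vert_subsequent, 842000)
  expect_equal(cfg$costs$ltc_post_hip, 876000)
  expect_equal(cfg$costs$ltc_post_vert, 213000)

  expect_equal(cfg$utilities$base_by_age$utility,
               c(0.862, 0.810, 0.771, 0.769, 0.684))
  expect_equal(cfg$utilities$mult_hip_y1, 0.776)
  expect_equal(cfg$utilities$mult_hip_later, 0.855)
  expect_equal(cfg$utilities$mult_vert_y1, 0.724)
  expect_equal(cfg$utilities$mult_vert_later, 0.868)

  expect_equal(cfg$econ$discount_cost, 0.02)
  expect_equal(cfg$econ$discount_qaly, 0.02)
  expect_equal(cfg$econ$wtp, c(5e6, 1e7))
  expect_equal(cfg$econ$yen_per_usd, 105)
  expect_identical(cfg$econ$perspective, "healthcare_plus_ltc")
  expect_identical(cfg$start_age, 65L)
  expect_identical(cfg$n_trials, 100000L)
  expect_null(cfg$life_table)
})

test_that("configuration loading merges, validates and round-trips", {
  # empty override document is the identity
  cfg0 <- default_parameters()
  expect_equal(osteosim:::config_to_list(load_config("")), osteosim:::config_to_list(cfg0))

  # a targeted override lands where aimed, everything else defaults
  cfg <- load_config("efficacy:\n  za:\n    rr_hip: 0.50\n")
  expect_equal(cfg$efficacy$za$rr_hip, 0.50)
  expect_equal(cfg$efficacy$za$rr_vert, 0.40)

  # invariant breaches are range errors naming the field
  expect_error(
    load_config("efficacy:\n  za:\n    rr_hip: 1.3\n    rr_hip_ci: [1.0, 1.5]"),
    "rr_hip")
  expect_error(load_config("econ:\n  discount_cost: 0.5\n"), "discount")
  expect_error(load_config("nonsense_key: 1\n"), "unknown field")

  # serialisation round-trip is lossless
  cfg <- load_config("start_age: 75\ncosts:\n  fx_hip: 1000000\n")
  back <- load_config(serialize_config(cfg))
  expect_equal(osteosim:::config_to_list(back), osteosim:::config_to_list(cfg))
})

test_that("abridged life tables are filled by log-linear interpolation", {
  lt <- load_life_table(c("age,qx", "65,0.004", "105,0.5"))
  expect_equal(lt$qx[lt$age == 85], exp(mean(log(c(0.004, 0.5)))),
               tolerance = 1e-12)
  expect_equal(lt$qx[lt$age == 65], 0.004)
  expect_equal(lt$qx[lt$age == 105], 0.5)
  # monotone between anchors, every single year present
  expect_equal(lt$age, 65:105)
  expect_true(all(diff(lt$qx) > 0))

  # headerless input works
  lt2 <- load_life_table(c("65,0.004", "105,0.5"))
  expect_equal(lt2$qx, lt$qx)

  expect_error(load_life_table(c("age,qx", "65,1.2", "105,0.5")),
               "\\[0, 1\\]")
  expect_error(load_life_table(c("age,qx", "65,0.004", "100,0.5")),
               "coverage")
})

test_that("set_param replaces nested fields and rejects unknown paths", {
  cfg <- make_toy_config()
  cfg2 <- set_param(cfg, "efficacy.za.rr_vert", 0.55)
  expect_equal(cfg2$efficacy$za$rr_vert, 0.55)
  expect_equal(cfg$efficacy$za$rr_vert, 0.40)
  expect_error(set_param(cfg, "efficacy.za.nope", 1), "unknown parameter")
})
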