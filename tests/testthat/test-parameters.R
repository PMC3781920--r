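test_that("default parameter set carries the published basecase values and validates", {
  ps <- af_parameters()
  expect_equal(ps$cost_ablation_total_per_procedure, 9590)
  expect_equal(ps$n_procedures * ps$cost_ablation_total_per_procedure,
               12179, tolerance = 0.5)
  expect_equal(ps$p_complication_pv_stenosis, 0.016)
  expect_equal(ps$discount_rate, 0.05)
  expect_equal(unname(ps$chads2_stroke_table[["2"]]), 0.04)
  expect_identical(nrow(validate_parameters(ps)), 0L)
})

test_that("validation reports each violated field by name", {
  v <- validate_parameters(af_parameters(p_nsr_aad_1y = 1.2))
  expect_identical(v$field, "p_nsr_aad_1y")
  v <- validate_parameters(af_parameters(cost_gi_bleed = -5))
  expect_identical(v$field, "cost_gi_bleed")
  v <- validate_parameters(af_parameters(p_nsr_aad_1y = -0.1,
                                         utility_ich = 2))
  expect_setequal(v$field, c("p_nsr_aad_1y", "utility_ich"))
})

test_that("unknown parameter overrides are rejected with the valid field list", {
  expect_error(af_parameters(not_a_field = 1), "not_a_field")
  expect_error(af_parameters(not_a_field = 1), "valid fields")
})

test_that("profile invariants are enforced", {
  expect_error(af_profile(chads2 = 7), "0..6")
  expect_error(af_profile(prop_warfarin = 1.5), "\\[0, 1\\]")
  expect_error(af_profile(start_age = 10), ">= 18")
  p <- af_profile(70, "female", 3, 0.5)
  expect_equal(p$start_age, 70)
  expect_equal(p$sex, "female")
})

test_that("parameter sets round-trip through the YAML configuration", {
  ps <- af_parameters(discount_rate = 0.03, horizon = 10,
                      disutility_af = 0.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(ps, path)
  back <- read_parameters(path)
  expect_equal(unclass(back), unclass(ps), tolerance = 1e-12)
})

test_that("distribution map means match the basecase where sources agree", {
  d <- af_distributions()
  ps <- af_parameters()
  agree <- c("rr_nsr_ablation", "p_recur_ablation", "p_recur_aad",
             "disutility_af", "cost_ablation_hosp", "p_complication_stroke",
             "p_pulm_tox_annual", "prop_pulm_tox_irreversible",
             "cost_pulm_tox_irrev_annual", "utility_pulm_tox_irrev",
             "rr_stroke_af_vs_nsr", "cost_ischemic_stroke_later_annual",
             "utility_ischemic_stroke", "p_bleed_no_warfarin",
             "rr_bleed_placebo_vs_warfarin", "utility_ich")
  for (nm in agree) {
    expect_equal(dist_mean(d[[nm]]), ps[[nm]], tolerance = 0.05, label = nm)
  }
  # the sinus-rhythm beta is recalibrated to the published mean
  expect_equal(dist_mean(d$p_nsr_aad_1y), 0.26, tolerance = 0.005)
})
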