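test_that("dead is absorbing and transition rows always sum to one", {
  ps <- af_parameters()
  prof <- af_profile()
  row <- cycle_transition("DEAD", "aad", ps, prof, fx, cycle = 3)
  expect_equal(unname(row["DEAD"]), 1)
  expect_true(all(row[names(row) != "DEAD"] == 0))
  for (strategy in c("ablation", "aad")) {
    for (k in c(0, 1, 4, 10, 19)) {
      M <- transition_matrix(strategy, ps, prof, fx, k)
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
      expect_true(all(M >= 0))
    }
  }
  expect_error(cycle_transition("NOPE", "aad", ps, prof, fx), "valid states")
})

test_that("stroke risk in sinus rhythm carries the published AF-vs-NSR differential", {
  # annual component 0.04 x (1/1.6) = 0.025, visible with other risks off
  ps <- params_no_events(chads2_stroke_table = af_parameters()$chads2_stroke_table)
  row <- cycle_transition("NSR", "aad", ps, af_profile(), fx_inert, cycle = 4)
  p_stroke_cycle <- unname(row["S1_0"])
  expect_equal(cycle_to_annual_prob(p_stroke_cycle, 0.25), 0.025,
               tolerance = 1e-9)
  row_af <- cycle_transition("AF", "aad", ps, af_profile(), fx_inert, cycle = 4)
  expect_equal(cycle_to_annual_prob(unname(row_af["S1_0"]), 0.25), 0.04,
               tolerance = 1e-9)
})

test_that("degenerate transitions: AF with all risks zeroed stays put", {
  ps <- params_no_events()
  row <- cycle_transition("AF", "aad", ps, af_profile(), fx_inert, cycle = 4)
  expect_equal(unname(row["AF"]), 1, tolerance = 1e-12)
})

test_that("forced pathway: no complications, certain rhythm success, no mortality", {
  ps <- params_no_events(p_nsr_aad_1y = 1, rr_nsr_ablation = 1)
  fy <- run_first_year("ablation", ps, af_profile(), fx_inert)
  expect_equal(unname(fy$entry_distribution["NSR"]), 1, tolerance = 1e-12)
  expect_equal(fy$deaths, 0)
})

test_that("expected procedural complication cost matches the hand-computed dot product", {
  base <- af_parameters()
  ps <- params_no_events(
    p_complication_stroke = base$p_complication_stroke,
    p_complication_tia = base$p_complication_tia,
    p_complication_tamponade = base$p_complication_tamponade,
    p_complication_pv_stenosis = base$p_complication_pv_stenosis,
    cost_amiodarone_annual = 0, cost_warfarin_annual = 0,
    cost_warfarin_monitoring_annual = 0,
    cost_ischemic_stroke_y1 = 0, cost_ischemic_stroke_later_annual = 0,
    cost_ablation_hosp = 0, cost_ablation_md = 0,
    cost_ablation_followup_y1 = 0)
  fy <- run_first_year("ablation", ps, af_profile(), fx_inert)
  per_procedure <- 0.003 * 14872 + 0.002 * 4296 + 0.008 * 5842 +
    0.016 * 8487
  expect_equal(fy$cost, 1.27 * per_procedure, tolerance = 1e-9)
  expect_equal(fy$strokes, 1.27 * 0.003, tolerance = 1e-12)
})

test_that("drug-arm entry split matches an independent scalar chain", {
  ps <- af_parameters()
  prof <- af_profile()
  fy <- run_first_year("aad", ps, prof, fx)
  # independent arithmetic: survival-through-year of the clean NSR mass
  p_warf_bleed <- 0.0058 / 0.45
  b_annual <- prof$prop_warfarin * p_warf_bleed +
    (1 - prof$prop_warfarin) * 0.0058
  nsr <- ps$p_nsr_aad_1y
  for (k in 0:3) {
    age <- 65 + 0.25 * k
    d <- 1 - (1 - lookup_value(fx$life_table, age, "male"))^0.25
    s <- 1 - (1 - 0.04 * 0.625)^0.25
    b <- 1 - (1 - b_annual)^0.25
    x <- 1 - (1 - ps$p_pulm_tox_annual)^0.25
    keep <- 1 - x * ps$p_pulm_tox_death -
      x * (1 - ps$p_pulm_tox_death) * ps$prop_pulm_tox_irreversible
    nsr <- nsr * (1 - d) * (1 - s) * (1 - b * ps$prop_bleed_ich) * keep
  }
  expect_equal(unname(fy$entry_distribution["NSR"]), nsr, tolerance = 1e-9)
  # no recurrence before the rhythm outcome is resolved
  expect_equal(unname(fy$entry_distribution["AF"]) > 1 - ps$p_nsr_aad_1y - 0.05,
               TRUE)
})

test_that("first-year masses and full traces conserve probability", {
  for (strategy in c("ablation", "aad")) {
    fy <- run_first_year(strategy, af_parameters(), af_profile(), fx)
    expect_equal(sum(fy$entry_distribution) + fy$deaths, 1, tolerance = 1e-9)
    tr <- run_markov(fy, fixtures = fx)
    expect_equal(unname(rowSums(tr$occupancy)),
                 rep(1, nrow(tr$occupancy)), tolerance = 1e-9)
    dead <- tr$occupancy[, "DEAD"]
    expect_true(all(diff(dead) >= -1e-12))
    expect_true(all(tr$cycles$cost >= 0))
  }
})

test_that("with identical effectiveness and no procedure effects the arms coincide", {
  ps <- af_parameters(rr_nsr_ablation = 1, n_procedures = 0,
                      p_complication_stroke = 0, p_complication_tia = 0,
                      p_complication_tamponade = 0,
                      p_complication_pv_stenosis = 0,
                      p_pulm_tox_annual = 0, p_bleed_no_warfarin = 0)
  a <- run_first_year("ablation", ps, af_profile(), fx)
  b <- run_first_year("aad", ps, af_profile(), fx)
  expect_equal(a$entry_distribution, b$entry_distribution, tolerance = 1e-12)
})

test_that("event-free cohort matches the discounted-annuity closed form", {
  ps <- params_no_events(p_nsr_aad_1y = 1)
  run <- run_strategy("aad", ps, af_profile(), fx_inert)
  u <- 0.83
  # occupancy constant in NSR; yearly discounting of four quarter-cycles
  expect_equal(run$expected_qaly, u * sum(1.05^-(0:4)), tolerance = 1e-9)
  ps0 <- params_no_events(p_nsr_aad_1y = 1, discount_rate = 0)
  run0 <- run_strategy("aad", ps0, af_profile(), fx_inert)
  expect_equal(run0$expected_qaly, u * 5, tolerance = 1e-9)
  expect_equal(run0$undiscounted_qaly, run0$expected_qaly)
})

test_that("cohort expectations agree with a 10,000-individual microsimulation", {
  ps <- af_parameters(horizon = 2)
  prof <- af_profile()
  # 8-cycle instance started from pure NSR, drug arm
  n_ind <- 10000
  micro <- microsimulate(n_ind, 0:7, "aad", ps, prof, fx)
  # cohort expectation for the same start
  states <- rownames(transition_matrix("aad", ps, prof, fx, 0))
  occ0 <- stats::setNames(numeric(length(states)), states)
  occ0["NSR"] <- 1
  strokes_exp <- 0
  dead_exp <- 0
  occ <- occ0
  for (k in 0:7) {
    M <- transition_matrix("aad", ps, prof, fx, k)
    strokes_exp <- strokes_exp +
      sum(occ * M[, "S1_0"]) + sum(occ * M[, "S1_0_tox"])
    occ <- as.numeric(occ %*% M)
    names(occ) <- states
  }
  dead_exp <- unname(occ["DEAD"])
  se_strokes <- sqrt(strokes_exp * (1 - strokes_exp) / n_ind)
  se_dead <- sqrt(dead_exp * (1 - dead_exp) / n_ind)
  expect_lt(abs(micro$strokes - strokes_exp), 3 * se_strokes)
  expect_lt(abs(micro$dead - dead_exp), 3 * se_dead)
})

test_that("removing the rhythm-stroke differential collapses the stroke gap", {
  ps <- af_parameters(rr_stroke_af_vs_nsr = 1)
  fit <- af_cea(af_profile(), ps, fx)
  # remaining difference is procedural strokes plus survival second-order terms
  proc <- 1.27 * 0.003
  expect_lt(abs(fit$delta_strokes - proc), 0.01)
})

test_that("markov accumulation handles constant rewards by geometric series", {
  # fabricated two-phase result with constant per-cycle rewards
  cyc1 <- data.frame(cycle = 0:3, time = (0:3) / 4, cost = 100, qaly = 0.2,
                     strokes = 0, ich = 0, gi_bleeds = 0, tox_events = 0,
                     deaths = 0)
  cyc2 <- data.frame(cycle = 4:19, time = (4:19) / 4, cost = 100, qaly = 0.2,
                     strokes = 0.001, ich = 0, gi_bleeds = 0, tox_events = 0,
                     deaths = 0)
  occ <- matrix(0, 17, 2, dimnames = list(NULL, c("NSR", "DEAD")))
  fy <- structure(list(strategy = "aad", cycles = cyc1,
                       profile = af_profile(),
                       ps = af_parameters()),
                  class = "af_first_year")
  tr <- structure(list(strategy = "aad", cycles = cyc2, occupancy = occ),
                  class = "af_trace")
  res <- accumulate_results(fy, tr, af_parameters())
  expect_equal(res$expected_cost, 400 * sum(1.05^-(0:4)), tolerance = 1e-9)
  expect_equal(res$expected_qaly, 0.8 * sum(1.05^-(0:4)), tolerance = 1e-9)
  expect_equal(res$expected_strokes, 0.016)
  res0 <- accumulate_results(fy, tr, af_parameters(discount_rate = 0))
  expect_equal(res0$expected_cost, 2000)
})
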