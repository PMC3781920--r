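fabricate_result <- function(strategy, cost, qaly, strokes = 0.1,
                             horizon = 5, discount = 0.05,
                             profile = af_profile()) {
  structure(list(strategy = strategy, expected_cost = cost,
                 expected_qaly = qaly, expected_strokes = strokes,
                 expected_ich = 0, horizon = horizon,
                 discount_rate = discount, profile = profile),
            class = "af_strategy_result")
}

test_that("incremental comparison reproduces the published table arithmetic", {
  abl <- fabricate_result("ablation", 21150, 3.416, 0.122)
  aad <- fabricate_result("aad", 12611, 3.272, 0.155)
  cmp <- compare_strategies(abl, aad)
  expect_equal(cmp$delta_cost, 8539)
  expect_equal(cmp$delta_qaly, 0.144, tolerance = 1e-9)
  expect_equal(cmp$delta_strokes, -0.033, tolerance = 1e-9)
  expect_equal(cmp$icer, 8539 / 0.144, tolerance = 1e-9)
  # rounding of the published inputs puts the ratio near the published ICER
  expect_equal(cmp$icer, 59194, tolerance = 0.005)
  expect_identical(cmp$label, "icer")
})

test_that("dominance and degenerate cases are labelled, not divided", {
  same <- compare_strategies(fabricate_result("ablation", 100, 1),
                             fabricate_result("aad", 100, 1))
  expect_identical(same$label, "undefined")
  expect_true(is.na(same$icer))
  dom <- compare_strategies(fabricate_result("ablation", 90, 1.2),
                            fabricate_result("aad", 100, 1))
  expect_identical(dom$label, "dominates")
  dominated <- compare_strategies(fabricate_result("ablation", 110, 0.9),
                                  fabricate_result("aad", 100, 1))
  expect_identical(dominated$label, "dominated")
})

test_that("deltas are antisymmetric under argument swap", {
  a <- fabricate_result("ablation", 21000, 3.4)
  b <- fabricate_result("aad", 12000, 3.3)
  ab <- compare_strategies(a, b)
  ba <- compare_strategies(b, a)
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_qaly, -ba$delta_qaly)
})

test_that("results from different settings cannot be compared", {
  a <- fabricate_result("ablation", 21000, 3.4, horizon = 10)
  b <- fabricate_result("aad", 12000, 3.3, horizon = 5)
  expect_error(compare_strategies(a, b), "different settings")
  b2 <- fabricate_result("aad", 12000, 3.3, horizon = 10,
                         profile = af_profile(chads2 = 3))
  expect_error(compare_strategies(a, b2), "different settings")
})

test_that("the full deterministic analysis returns coherent classed output", {
  fit <- af_cea(fixtures = fx)
  expect_s3_class(fit, "af_cea")
  expect_equal(fit$delta_cost,
               fit$ablation$expected_cost - fit$aad$expected_cost)
  s <- summary(fit)
  expect_identical(s$strategy, c("ablation", "aad", "incremental"))
  expect_equal(s$icer[3], fit$icer)
  expect_output(print(fit), "increment")
})
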