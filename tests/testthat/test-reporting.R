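test_that("basecase command writes a coherent report set", {
  dir <- withr::local_tempdir()
  files <- cmd_basecase(load_run_config(), dir)
  expect_true(all(file.exists(files)))
  rep <- jsonlite::read_json(files[["json"]])
  expect_true(all(c("ablation", "aad", "incremental", "settings") %in%
                    names(rep)))
  expect_type(rep$incremental$icer, "double")
  expect_equal(rep$incremental$delta_cost,
               rep$ablation$expected_cost - rep$aad$expected_cost,
               tolerance = 1e-6)
  tr <- utils::read.csv(files[["trace_aad"]])
  expect_true(all(c("cycle", "state", "occupancy", "cost", "qaly") %in%
                    names(tr)))
})

test_that("configuration errors name the offending field", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "bad.yaml")
  writeLines(c("parameters:", "  not_a_parameter: 3"), cfg)
  expect_error(load_run_config(cfg), "not_a_parameter")
  cfg2 <- file.path(dir, "bad2.yaml")
  writeLines(c("fixtures:", "  life_table: /no/such/file.tsv"), cfg2)
  expect_error(load_run_config(cfg2), "life_table")
})

test_that("a horizon-3 configuration matches the matching sensitivity scenario", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "h3.yaml")
  writeLines(c("parameters:", "  horizon: 3"), cfg)
  config <- load_run_config(cfg)
  fit <- af_cea(config$profile, config$ps, config$fixtures)
  grid <- run_scenarios(list(scenario("h3", params = list(horizon = 3)))
  )
  expect_equal(fit$delta_cost, grid$delta_cost, tolerance = 1e-9)
  expect_equal(fit$icer, grid$icer, tolerance = 1e-9)
})

test_that("probabilistic outputs are byte-identical under a fixed seed", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "psa.yaml")
  writeLines(c("options:", "  n_draws: 8", "  seed: 4"), cfg)
  config <- load_run_config(cfg)
  f1 <- cmd_psa(config, file.path(dir, "a"))
  f2 <- cmd_psa(config, file.path(dir, "b"))
  expect_identical(readLines(f1[["draws"]]), readLines(f2[["draws"]]))
  expect_identical(readLines(f1[["ceac"]]), readLines(f2[["ceac"]]))
  draws <- utils::read.csv(f1[["draws"]], comment.char = "#")
  expect_identical(nrow(draws), 8L)
  curve <- utils::read.csv(f1[["ceac"]])
  expect_equal(curve$probability[curve$wtp == 0],
               mean(draws$delta_cost < 0))
})

test_that("sensitivity command writes one row per scenario", {
  dir <- withr::local_tempdir()
  specs <- list(scenario("a"), scenario("b", params = list(horizon = 3)))
  files <- cmd_owsa(load_run_config(), dir, specs)
  grid <- utils::read.csv(files[["owsa"]])
  expect_identical(nrow(grid), 2L)
  expect_identical(grid$name, c("a", "b"))
})
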