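test_that("generated life table has the tuned magnitude and monotone structure", {
  lt <- make_life_table()
  expect_true(all(lt$value >= 0 & lt$value <= 1))
  q65 <- lookup_value(lt, 65, "male")
  expect_gt(q65, 0.010)
  expect_lt(q65, 0.020)
  # monotone in age beyond 30, both sexes; female below male
  for (s in c("male", "female")) {
    v <- lt$value[lt$sex == s & lt$age >= 30]
    expect_true(all(diff(v) > 0))
  }
  expect_lt(lookup_value(lt, 65, "female"), q65)
  # five-year survival of a 65-year-old male near 0.92
  surv <- prod(1 - sapply(65:69, lookup_value, tab = lt, sex = "male"))
  expect_equal(surv, 0.92, tolerance = 0.02)
  # degenerate: zero hazard everywhere
  expect_true(all(make_life_table(0, 0.09, 0, 1)$value == 0))
})

test_that("event mortality table is anchored to the published case-fatality figures", {
  em <- make_event_mortality_table()
  expect_true(all(em$value >= 0 & em$value <= 1))
  # cohort-level anchors: average over the basecase cohort's first years
  isch <- mean(sapply(65:70, lookup_value, tab = em, sex = "male",
                      event = "ischemic"))
  expect_equal(isch, 0.189, tolerance = 0.02)
  ich <- mean(sapply(65:70, lookup_value, tab = em, sex = "male",
                     event = "ich"))
  expect_equal(ich, 0.48, tolerance = 0.02)
  zero <- make_event_mortality_table(c(ischemic = 0, ich = 0))
  expect_true(all(zero$value == 0))
})

test_that("utility table is linear in age, clamped, and non-increasing", {
  ut <- make_utility_table()
  expect_true(all(ut$value >= 0 & ut$value <= 1))
  for (s in c("male", "female")) {
    expect_true(all(diff(ut$value[ut$sex == s]) <= 0))
  }
  expect_equal(lookup_value(make_utility_table(0.83, 0.03), 75, "male"), 0.80)
  expect_true(all(make_utility_table(1, 0)$value == 1))
})

test_that("table generation is deterministic and round-trips through delimited files", {
  expect_identical(make_life_table(), make_life_table())
  expect_identical(make_event_mortality_table(), make_event_mortality_table())
  dir <- withr::local_tempdir()
  lt <- make_life_table()
  f <- file.path(dir, "lt.tsv")
  write.table(lt, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_life_table(f)
  expect_equal(back$value, lt$value, tolerance = 1e-9)
  em <- make_event_mortality_table()
  f2 <- file.path(dir, "em.tsv")
  write.table(em, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_event_mortality_table(f2)$value, em$value,
               tolerance = 1e-9)
  # an event table misread as a life table collapses age/sex keys
  expect_error(read_life_table(f2), "duplicate")
})
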