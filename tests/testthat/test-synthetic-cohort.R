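test_that("generator is deterministic and structurally sound", {
  cfg <- syntheticConfig(300, seed = 11, maskedAgeFraction = 0.05)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a, b)

  expect_false(anyDuplicated(a$stays$stay_id) > 0)
  expect_true(all(a$stays$outtime > a$stays$intime))
  expect_true(all(a$stays$age_years >= 18))
  expect_true(any(a$stays$age_years > 300))  # masked-age sentinel present
  first <- a$stays[grepl("-1$", a$stays$stay_id), ]
  expect_identical(nrow(first), 300L)
  # decoy stays only for survivors, and strictly later than the first stay
  decoy <- a$stays[grepl("-2$", a$stays$stay_id), ]
  expect_true(all(!decoy$icu_death))
  m <- match(decoy$subject_id, first$subject_id)
  expect_true(all(decoy$intime > first$outtime[m]))
})

test_that("empty configuration yields empty tables", {
  sim <- generateCohort(syntheticConfig(0))
  expect_identical(nrow(sim$stays), 0L)
  expect_identical(nrow(sim$events), 0L)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("seeded death count reproduces the frozen regression fixture", {
  sim <- generateCohort(syntheticConfig(1000, seed = 123,
                                        deathProbability = 0.2))
  first <- sim$stays[grepl("-1$", sim$stays$stay_id), ]
  expect_identical(sum(first$icu_death), 213L)  # pinned on first run
  sim2 <- generateCohort(syntheticConfig(1000, seed = 123,
                                         deathProbability = 0.2))
  expect_identical(sum(sim2$stays$icu_death), sum(sim$stays$icu_death))
})

test_that("configured death-group shift is recovered as empirical SMD", {
  an <- syntheticAnalyte("probe", "normal", location = 5, scale = 2,
                         shifts = c(0, 0, 0, 0, -2))
  cfg <- syntheticConfig(5000, seed = 21, deathProbability = 0.5,
                         panel = list(an), eventsPerFirstDay = 1,
                         multiStayFraction = 0)
  sim <- generateCohort(cfg)
  first <- sim$stays
  ev <- sim$events
  death <- first$icu_death[match(ev$subject_id, first$subject_id)]
  smd <- standardizedMeanDifference(ev$value[death], ev$value[!death])
  expect_lt(abs(smd - (-2)), 0.1)
})

test_that("group-conditional means converge to configured truth", {
  cfg <- syntheticConfig(4000, seed = 5, eventsPerFirstDay = 1,
                         multiStayFraction = 0)
  sim <- generateCohort(cfg)
  groups <- assignOutcomeGroups(selectFirstStays(sim$stays))
  g <- setNames(as.character(groups$outcome), groups$stay_id)
  for (tid in c("albumin", "sodium")) {
    ev <- sim$events[sim$events$test_id == tid, ]
    tr <- sim$truth[sim$truth$test_id == tid, ]
    for (grp in outcomeLevels()) {
      x <- ev$value[g[ev$stay_id] == grp]
      mu <- tr$location[tr$group == grp]
      sc <- tr$scale[tr$group == grp]
      expect_lt(abs(mean(x) - mu), 3 * sc / sqrt(length(x)))
    }
  }
})

test_that("per-analyte substreams are independent of panel composition", {
  base <- syntheticAnalytes()[1:2]
  extended <- c(base, syntheticAnalytes()[3])
  a <- generateCohort(syntheticConfig(400, seed = 9, panel = base))
  b <- generateCohort(syntheticConfig(400, seed = 9, panel = extended))
  expect_identical(a$stays, b$stays)
  for (tid in c("albumin", "hemoglobin"))
    expect_identical(a$events[a$events$test_id == tid, ],
                     b$events[b$events$test_id == tid, ])
})

test_that("analyte and config invariants are enforced", {
  expect_error(syntheticAnalyte("x", "normal", 0, -1), "scale")
  expect_error(
    syntheticAnalyte("x", "normal", 0, 1, shifts = c(1, 0, 0, 0, 0.5)),
    "severity-monotone")
  expect_error(syntheticConfig(10, deathProbability = 1.5), "\\[0, 1\\]")
  expect_error(syntheticConfig(10, losSdlog = 0), "> 0")
  expect_error(syntheticConfig(-1), "non-negative")
})

test_that("analyticNormalOvl matches the closed form and its properties", {
  expect_equal(analyticNormalOvl(3, 3, 2), 1.0)
  expect_equal(analyticNormalOvl(0, 1, 1), 2 * pnorm(-0.5))
  expect_equal(round(analyticNormalOvl(0, 1, 1), 4), 0.6171)
  expect_equal(round(analyticNormalOvl(0, 2, 1), 4), 0.3173)
  # symmetry and strict monotone decrease in |mu1 - mu2|
  ds <- seq(0, 4, by = 0.25)
  ovl <- vapply(ds, function(d) analyticNormalOvl(0, d, 1), 0)
  expect_equal(ovl, vapply(ds, function(d) analyticNormalOvl(d, 0, 1), 0))
  expect_true(all(diff(ovl) < 0))
  expect_error(analyticNormalOvl(0, 1, 0), "sigma")
})

test_that("synthetic tables round-trip through CSV", {
  sim <- generateCohort(syntheticConfig(50, seed = 2))
  dir <- withr::local_tempdir()
  writeSyntheticTables(sim, dir)
  stays <- readStays(file.path(dir, "stays.csv"))
  events <- readEvents(file.path(dir, "events.csv"))
  expect_identical(stays$stay_id, sim$stays$stay_id)
  expect_equal(stays$intime, sim$stays$intime)
  expect_equal(events$value, sim$events$value)
  expect_equal(events$charttime, sim$events$charttime)
})
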