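test_that("selectFirstStays keeps the earliest adult stay per subject", {
  stays <- makeStays(2)
  # give subject 1 a later second stay
  extra <- stays[1, ]
  extra$stay_id <- "P001-2"
  extra$intime <- stays$intime[1] + 5 * 86400
  extra$outtime <- extra$intime + 86400
  out <- selectFirstStays(rbind(extra, stays))
  expect_identical(sort(out$stay_id), c("P001-1", "P002-1"))

  # age filter, with masked sentinel retained as adult
  stays <- makeStays(3, age = c(10, 50, 308))
  out <- selectFirstStays(stays, adultAgeMin = 18)
  expect_identical(out$subject_id, c("P002", "P003"))

  expect_error(selectFirstStays(rbind(stays, stays[1, ])), "duplicate stay_id")
})

test_that("first-stay selection matches a per-subject scan on synthetic data", {
  sim <- generateCohort(syntheticConfig(500, seed = 33,
                                        multiStayFraction = 0.3))
  out <- selectFirstStays(sim$stays)
  expect_identical(nrow(out), length(unique(sim$stays$subject_id)))
  # brute-force: per subject, earliest intime
  byHand <- vapply(split(sim$stays, sim$stays$subject_id), function(d)
    d$stay_id[order(d$intime, d$stay_id)][1], "")
  expect_setequal(out$stay_id, unname(byHand))
})

test_that("worst first-day extraction follows direction and window rules", {
  stays <- makeStays(1)
  panel <- labPanel(c("glucose", "albumin"), units = "u",
                    directions = c("both", "min"),
                    ref_lower = c(70, 3.5), ref_upper = c(105, 5.5))
  ev1 <- data.frame(subject_id = "P001", stay_id = "P001-1",
                    test_id = "glucose", charttime = stays$intime + 3600,
                    value = 7.0, stringsAsFactors = FALSE)
  rec <- extractWorstFirstDay(ev1, stays, panel)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$value, c(7.0, 7.0))
  expect_setequal(rec$direction, c("min", "max"))

  # albumin is minimum-only
  ev2 <- data.frame(subject_id = "P001", stay_id = "P001-1",
                    test_id = "albumin",
                    charttime = stays$intime + c(1, 2, 3) * 3600,
                    value = c(3.1, 2.4, 3.6), stringsAsFactors = FALSE)
  rec <- extractWorstFirstDay(ev2, stays, panel)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$direction, "min")
  expect_equal(rec$value, 2.4)

  # event on the 24 h boundary is outside the half-open window
  ev3 <- ev2
  ev3$charttime <- stays$intime + c(0, 24, 25) * 3600
  rec <- extractWorstFirstDay(ev3, stays, panel)
  expect_equal(rec$value, 3.1)

  expect_error(
    extractWorstFirstDay(transform(ev2, value = c("3.1", "oops", "3.6")),
                         stays, panel),
    "non-numeric")
})

test_that("extraction equals the brute-force oracle and is order-invariant", {
  withr::local_seed(404)
  for (rep in 1:20) {
    fx <- makeRandomFixture(nStays = 12, nEvents = 120)
    got <- extractWorstFirstDay(fx$events, fx$stays, fx$panel)
    expect_equal(got, oracleWorst(fx$events, fx$stays, fx$panel))
    shuffled <- fx$events[sample(nrow(fx$events)), ]
    expect_equal(extractWorstFirstDay(shuffled, fx$stays, fx$panel), got)
  }
})

test_that("no extracted record refers to a non-first stay", {
  sim <- generateCohort(syntheticConfig(300, seed = 8,
                                        multiStayFraction = 0.4))
  first <- selectFirstStays(sim$stays)
  rec <- extractWorstFirstDay(sim$events, first, defaultPanel())
  expect_true(all(rec$stay_id %in% first$stay_id))
  expect_true(all(grepl("-1$", rec$stay_id)))
})

test_that("outcome groups follow the survivor-quartile rule", {
  stays <- makeStays(5, losDays = c(1, 2, 3, 4, 2),
                     death = c(rep(FALSE, 4), TRUE))
  g <- assignOutcomeGroups(stays)
  expect_identical(as.character(g$outcome),
                   c("Q1_BEST", "Q2", "Q3", "Q4", "DIED_WORST"))

  # all-tied LOS: deterministic groups of 2 via stay_id tie-break
  stays <- makeStays(8, losDays = rep(3, 8))
  g <- assignOutcomeGroups(stays)
  expect_identical(as.character(g$outcome),
                   rep(c("Q1_BEST", "Q2", "Q3", "Q4"), each = 2))
  expect_equal(g$outcome, oracleGroups(stays$stay_id, stays$los_days,
                                       stays$icu_death))

  expect_error(assignOutcomeGroups(makeStays(0)), "empty")
  expect_error(assignOutcomeGroups(makeStays(3)), "too few")
})

test_that("group assignment is permutation-invariant with balanced quartiles", {
  withr::local_seed(77)
  for (n in c(17, 40, 101)) {
    stays <- makeStays(n, losDays = round(runif(n, 0.2, 9), 1),
                       death = runif(n) < 0.15)
    if (sum(!stays$icu_death) < 4) next
    g1 <- assignOutcomeGroups(stays)
    perm <- sample(n)
    g2 <- assignOutcomeGroups(stays[perm, ])
    expect_equal(g2$outcome[match(g1$stay_id, g2$stay_id)], g1$outcome)
    expect_equal(g1$outcome, oracleGroups(stays$stay_id, stays$los_days,
                                          stays$icu_death))
    sizes <- table(g1$outcome)[c("Q1_BEST", "Q2", "Q3", "Q4")]
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("buildCohort assembles the expected container", {
  stays <- makeStays(5, losDays = 1:5, death = c(rep(FALSE, 4), TRUE))
  panel <- labPanel(c("a", "b"), units = "u", directions = c("min", "both"),
                    ref_lower = 0, ref_upper = 10)
  records <- data.frame(
    stay_id = c("P001-1", "P001-1", "P002-1"),
    test_id = c("a", "b", "b"), direction = c("min", "min", "max"),
    value = c(1.5, 2.5, 9), stringsAsFactors = FALSE)
  cohort <- buildCohort(records, stays, panel)
  expect_s4_class(cohort, "IcuCohort")
  expect_identical(dim(cohort), c(3L, 5L))  # a_min, b_min, b_max x 5 stays
  wv <- worstValues(cohort)
  expect_equal(wv["a_min", "P001-1"], 1.5)
  expect_equal(wv["b_max", "P002-1"], 9)
  expect_true(is.na(wv["b_max", "P001-1"]))
  expect_identical(as.character(outcomeGroups(cohort)[["P005-1"]]),
                   "DIED_WORST")

  # empty records: container keeps covariates, assay all missing
  empty <- buildCohort(records[0, ], stays, panel)
  expect_true(all(is.na(worstValues(empty))))
  expect_identical(ncol(empty), 5L)

  bad <- transform(records, stay_id = c("P001-1", "NOPE", "P002-1"))
  expect_error(buildCohort(bad, stays, panel), "unknown stay_id")

  wide <- asCohortDataFrame(cohort)
  expect_identical(nrow(wide), 5L)
  expect_true(all(c("a_min", "b_min", "b_max", "outcome") %in%
                    colnames(wide)))
})

test_that("per-test missingness survives into the cohort", {
  cfg <- syntheticConfig(1000, seed = 55, multiStayFraction = 0)
  sim <- generateCohort(cfg)
  first <- selectFirstStays(sim$stays)
  panel <- defaultPanel()
  rec <- extractWorstFirstDay(sim$events, first, panel)
  cohort <- buildCohort(rec, first, panel)
  miss <- vapply(syntheticAnalytes(), `[[`, 0, "missingness")
  names(miss) <- vapply(syntheticAnalytes(), `[[`, "", "test_id")
  for (tid in names(miss)) {
    feat <- grep(paste0("^", tid, "_"), rownames(cohort), value = TRUE)[1]
    nonMissing <- sum(!is.na(worstValues(cohort)[feat, ]))
    p <- 1 - miss[[tid]]
    expect_lt(abs(nonMissing - 1000 * p), 3 * sqrt(1000 * p * (1 - p)) + 1)
  }
})
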