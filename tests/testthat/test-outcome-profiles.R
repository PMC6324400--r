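test_that("extreme-support trimming follows the quantile convention", {
  kept <- trimExtremeSupport(1:200, 0.05)
  expect_equal(kept, c(low = 5.975, high = 195.025))
  inRange <- (1:200)[1:200 >= kept[1] & 1:200 <= kept[2]]
  expect_identical(inRange, 6:195)  # exactly the 190 central order statistics

  expect_equal(trimExtremeSupport(1:100, 0), c(low = 1, high = 100))
  expect_equal(trimExtremeSupport(rep(7, 5)), c(low = 7, high = 7))
  # asymmetric per-tail option
  expect_equal(trimExtremeSupport(1:200, c(0, 0.05)),
               c(low = 1, high = oracleQuantile(1:200, 0.95)))
  expect_error(trimExtremeSupport(numeric()), "non-empty")
})

test_that("outcome proportions tally hand-built fixtures", {
  # one group only: every bin is an indicator for it
  v <- runif(50, 0, 10)
  g <- rep("Q2", 50)
  pr <- outcomeProportions(v, g, nBins = 5, trimFraction = 0)
  p <- binProportions(pr)
  nonEmpty <- rowSums(binCounts(pr)) > 0
  expect_true(all(p[nonEmpty, "Q2"] == 1))
  expect_true(all(p[nonEmpty, colnames(p) != "Q2"] == 0))

  # two bins with hand-tallied counts
  v <- c(1, 1, 1, 1, 9, 9)
  g <- c("Q1_BEST", "Q1_BEST", "Q1_BEST", "DIED_WORST", "Q3", "DIED_WORST")
  pr <- outcomeProportions(v, g, nBins = 2, trimFraction = 0)
  expect_equal(unname(binCounts(pr)[1, ]), c(3L, 0L, 0L, 0L, 1L))
  expect_equal(unname(binProportions(pr)[1, ]), c(0.75, 0, 0, 0, 0.25))
  expect_equal(unname(binCounts(pr)[2, ]), c(0L, 0L, 1L, 0L, 1L))

  expect_error(outcomeProportions(v, g, nBins = 1), "at least 2")
  expect_error(outcomeProportions(c(1, 2), c("Q1_BEST", NA), nBins = 2),
               "outcome group")
})

test_that("profile invariants: row sums, marginals, permutation invariance", {
  withr::local_seed(88)
  for (rep in 1:5) {
    n <- 400
    v <- rlnorm(n, 1, 0.6)
    g <- sample(outcomeLevels(), n, replace = TRUE,
                prob = c(0.25, 0.25, 0.2, 0.2, 0.1))
    pr <- outcomeProportions(v, g, nBins = 15)
    counts <- binCounts(pr)
    props <- binProportions(pr)
    tot <- rowSums(counts)
    expect_true(all(abs(rowSums(props[tot > 0, , drop = FALSE]) - 1) < 1e-9))
    # count-weighted average of rows equals the marginal group proportions
    marginal <- colSums(counts) / sum(counts)
    weighted <- colSums(props[tot > 0, , drop = FALSE] * tot[tot > 0]) /
      sum(tot)
    expect_equal(weighted, marginal, tolerance = 1e-9)
    # counts cover exactly the values inside the kept range
    kr <- keptRange(pr)
    expect_identical(sum(counts), sum(v >= kr[1] & v <= kr[2]))
    # permutation invariance
    perm <- sample(n)
    pr2 <- outcomeProportions(v[perm], g[perm], nBins = 15)
    expect_equal(binCounts(pr2), counts)
    expect_equal(binEdges(pr2), binEdges(pr))
  }
})

test_that("a lactate-like death shift yields a rising worst-group profile", {
  withr::local_seed(5150)
  n <- 3000
  death <- runif(n) < 0.2
  g <- ifelse(death, "DIED_WORST",
              sample(c("Q1_BEST", "Q2", "Q3", "Q4"), n, replace = TRUE))
  v <- exp(rnorm(n, log(2) + ifelse(death, 0.9, 0) * 0.5, 0.5))
  pr <- outcomeProportions(v, g, nBins = 12, testId = "lactate",
                           direction = "max")
  props <- binProportions(pr)
  ok <- rowSums(binCounts(pr)) > 0
  trend <- cor(seq_len(sum(ok)), props[ok, "DIED_WORST"],
               method = "spearman")
  expect_gt(trend, 0)
})

test_that("profiles flatten to a long data frame and plot quietly", {
  v <- runif(200, 0, 10)
  g <- sample(outcomeLevels(), 200, replace = TRUE)
  pr <- outcomeProportions(v, g, nBins = 8, testId = "demo",
                           direction = "min")
  df <- profileToDataFrame(pr)
  expect_identical(nrow(df), 8L * 5L)
  expect_equal(sum(df$count), sum(binCounts(pr)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(pr))
})
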