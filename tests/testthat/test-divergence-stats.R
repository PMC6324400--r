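test_that("kernel density estimates are normalized and well shaped", {
  withr::local_seed(101)
  x <- rnorm(100000)
  d <- estimateDensity(x)
  expect_s4_class(d, "DensityEstimate")
  # density at 0 close to the closed-form normal pdf 1/sqrt(2*pi)
  at0 <- approx(densityGrid(d), densityValues(d), xout = 0)$y
  expect_lt(abs(at0 - dnorm(0)), 0.01)
  expect_equal(sum(diff(densityGrid(d)) *
                     (head(densityValues(d), -1) +
                        densityValues(d)[-1]) / 2), 1, tolerance = 1e-3)

  # two points: bimodal kernel sum, symmetric about the midpoint
  d2 <- estimateDensity(c(0, 10), bandwidthRule = 1)
  g <- densityGrid(d2)
  f <- densityValues(d2)
  expect_equal(f, rev(f), tolerance = 1e-9)  # symmetry about 5
  at5 <- approx(g, f, xout = 5)$y
  expect_lt(at5, max(f))  # trough between the two modes

  # support floor clips the grid
  d3 <- estimateDensity(rlnorm(500), supportFloor = 0)
  expect_gte(min(densityGrid(d3)), 0)

  expect_error(estimateDensity(rep(3, 10)), "distinct")
  expect_error(estimateDensity(c(1, NA, 3)), "finite")
})

test_that("centralInterval applies the linear-interpolation convention", {
  expect_equal(centralInterval(rep(4.2, 9)), c(lower = 4.2, upper = 4.2))
  expect_equal(centralInterval(1:1000), c(lower = 25.975, upper = 975.025))
  expect_equal(centralInterval(1:1000),
               c(lower = oracleQuantile(1:1000, 0.025),
                 upper = oracleQuantile(1:1000, 0.975)))
  withr::local_seed(7)
  ci <- centralInterval(rnorm(100000))
  expect_lt(abs(ci[["lower"]] + 1.96), 0.03)
  expect_lt(abs(ci[["upper"]] - 1.96), 0.03)
  expect_error(centralInterval(numeric()), "non-empty")
})

test_that("overlapCoefficient is symmetric, bounded and shift-monotone", {
  withr::local_seed(42)
  base <- rnorm(5000)
  d0 <- estimateDensity(base)
  expect_equal(overlapCoefficient(d0, d0), 1, tolerance = 1e-6)
  shifts <- c(0.5, 1, 2, 3)
  ovl <- vapply(shifts, function(s) {
    ds <- estimateDensity(base + s)
    o1 <- overlapCoefficient(d0, ds)
    o2 <- overlapCoefficient(ds, d0)
    expect_equal(o1, o2, tolerance = 1e-12)  # symmetry
    o1
  }, 0)
  expect_true(all(ovl >= 0 & ovl <= 1))
  expect_true(all(diff(ovl) < 0))  # monotone decreasing in the shift
})

test_that("SMD matches hand computation with its invariances", {
  expect_equal(standardizedMeanDifference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(standardizedMeanDifference(c(0, 1, 2), c(2, 3, 4)), -2)
  withr::local_seed(13)
  x <- rnorm(200, 1, 2)
  y <- rnorm(300, 0, 2)
  expect_equal(standardizedMeanDifference(x, y),
               -standardizedMeanDifference(y, x))
  expect_equal(standardizedMeanDifference(3 * x + 7, 3 * y + 7),
               standardizedMeanDifference(x, y), tolerance = 1e-12)
  expect_error(standardizedMeanDifference(c(5, 5), c(5, 5)), "pooled")
  expect_error(standardizedMeanDifference(1, c(1, 2)), "at least 2")
})

test_that("effect-size bands split on |SMD| at 0.2 and 0.8", {
  got <- classifyEffectSize(c(0.1, -0.5, 1.0, 0.2, -0.8, 0, -3))
  expect_identical(as.character(got),
                   c("small", "moderate", "large", "moderate", "moderate",
                     "small", "large"))
  expect_error(classifyEffectSize(NaN), "finite")
})

test_that("location shift test behaves across symmetry, shift and edge cases", {
  expect_equal(locationShiftTest(c(-1, 1, -2, 2, -3, 3), 0), 1)
  x <- seq(0.5, 10, length.out = 100)
  expect_lt(locationShiftTest(x, 0), 0.001)
  d <- intervalToDistribution(0.5, 2.0)
  expect_lt(locationShiftTest(rep(c(3, 4, 5), 10), d), 0.01)
  expect_error(locationShiftTest(1:5, 0), "n >= 6")
  expect_warning(p <- locationShiftTest(rep(2, 10), 2), "zero")
  expect_equal(p, 1)
})

test_that("group comparisons match hand-computed statistics", {
  res <- groupComparison(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                         "continuous")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- groupComparison(matrix(c(10, 0, 0, 10), 2), kind = "categorical")
  expect_equal(res$statistic, 20)  # n(ad-bc)^2 / row/col products
  expect_equal(res$df, 1)

  expect_error(groupComparison(1:3, rep("a", 3), "continuous"), "2 groups")
  expect_error(groupComparison(matrix(c(5, 5), 2, 1), kind = "categorical"),
               "2 x 2")
})
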