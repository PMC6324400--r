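#' @include reference-model.R
NULL

#' Gaussian-kernel density estimate
#'
#' Smooths a sample of lab values into a probability density on an evenly
#' spaced grid spanning `[min - 3h, max + 3h]` (h = bandwidth), optionally
#' clipped at a support floor (e.g. 0 for non-negative analytes), and
#' renormalized to integrate to 1 on the grid.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @param bandwidthRule `"silverman"` (rule-of-thumb, the default) or
#'   `"sj"` (Sheather-Jones); alternatively a positive number used
#'   directly as the bandwidth.
#' @param gridPoints number of grid points (default 512).
#' @param supportFloor optional lower clip for the grid (values below are
#'   impossible for the analyte); the density is renormalized after
#'   clipping.
#' @return A [DensityEstimate].
#' @examples
#' d <- estimateDensity(rnorm(1000))
#' @export
estimateDensity <- function(values, bandwidthRule = "silverman",
                            gridPoints = 512L, supportFloor = NULL) {
  if (anyNA(values) || !all(is.finite(values)))
    stopf("values must be finite and non-missing")
  if (length(unique(values)) < 2L)
    stopf("need at least 2 distinct values for a density estimate")
  bw <- if (is.numeric(bandwidthRule)) {
    if (bandwidthRule <= 0) stopf("numeric bandwidth must be positive")
    bandwidthRule
  } else switch(bandwidthRule,
    silverman = stats::bw.nrd0(values),
    sj = stats::bw.SJ(values),
    stopf("unknown bandwidth rule '%s'", bandwidthRule))
  from <- min(values) - 3 * bw
  to <- max(values) + 3 * bw
  if (!is.null(supportFloor)) from <- max(from, supportFloor)
  kde <- stats::density(values, bw = bw, kernel = "gaussian",
                        from = from, to = to, n = gridPoints)
  area <- trapezoid(kde$x, kde$y)
  new("DensityEstimate", grid = kde$x, density = kde$y / area,
      bw = bw, n = length(values))
}

#' Trimmed central interval of a sample
#'
#' The central interval obtained by excluding a fixed fraction of the
#' sample from each tail — by default the extreme 2.5% from both ends,
#' i.e. the empirical central 95% used to build ICU-derived reference
#' intervals robust to outliers. Quantiles use linear interpolation over
#' the order statistics (position `1 + p*(n-1)`).
#'
#' @param values non-empty numeric vector (NAs removed).
#' @param trim fraction excluded per tail, default 0.025.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' centralInterval(1:1000)  # c(25.975, 975.025)
#' @export
centralInterval <- function(values, trim = 0.025) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("centralInterval requires a non-empty sample")
  assertFraction(trim, "trim")
  if (trim > 0.5) stopf("trim per tail cannot exceed 0.5")
  q <- quantileLinear(values, c(trim, 1 - trim))
  c(lower = q[1], upper = q[2])
}

# Shared OVL kernel: integrate min(f1, f2) by trapezoid on the union grid,
# each density linearly interpolated and 0 outside its own grid.
ovlFromGrids <- function(g1, f1, g2, f2) {
  grid <- sort(unique(c(g1, g2)))
  y1 <- stats::approx(g1, f1, xout = grid, yleft = 0, yright = 0)$y
  y2 <- stats::approx(g2, f2, xout = grid, yleft = 0, yright = 0)$y
  min(max(trapezoid(grid, pmin(y1, y2)), 0), 1)
}

#' @rdname overlapCoefficient
#' @export
setMethod("overlapCoefficient",
  signature("DensityEstimate", "DensityEstimate"), function(d1, d2) {
    ovlFromGrids(d1@grid, d1@density, d2@grid, d2@density)
  })

#' @rdname overlapCoefficient
#' @export
setMethod("overlapCoefficient",
  signature("DensityEstimate", "ReferenceDistribution"), function(d1, d2) {
    ref <- referenceDensityEstimate(d2, gridPoints = length(d1@grid),
                                    span = range(d1@grid))
    ovlFromGrids(d1@grid, d1@density, ref@grid, ref@density)
  })

#' @rdname overlapCoefficient
#' @export
setMethod("overlapCoefficient",
  signature("ReferenceDistribution", "DensityEstimate"), function(d1, d2) {
    overlapCoefficient(d2, d1)
  })

#' @rdname overlapCoefficient
#' @export
setMethod("overlapCoefficient",
  signature("ReferenceDistribution", "ReferenceDistribution"),
  function(d1, d2) {
    span <- range(referenceQuantile(d1, c(1e-6, 1 - 1e-6)),
                  referenceQuantile(d2, c(1e-6, 1 - 1e-6)))
    a <- referenceDensityEstimate(d1, span = span)
    b <- referenceDensityEstimate(d2, span = span)
    ovlFromGrids(a@grid, a@density, b@grid, b@density)
  })

#' Cohen standardized mean difference between two samples
#'
#' `(mean(x1) - mean(x2)) / s_pooled` with the pooled standard deviation
#' `sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`. By the sign convention
#' used throughout, group 1 is the ICU cohort and group 2 the reference,
#' so a negative SMD means the ICU values run below the reference.
#'
#' @param x1,x2 numeric vectors, each with at least 2 values (NAs
#'   removed).
#' @return A single number, in units of pooled standard deviation.
#' @examples
#' standardizedMeanDifference(c(0, 1, 2), c(2, 3, 4))  # -2
#' @export
standardizedMeanDifference <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stopf("each group needs at least 2 values")
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
               (n1 + n2 - 2))
  if (sp == 0) stopf("pooled standard deviation is zero (degenerate groups)")
  (mean(x1) - mean(x2)) / sp
}

# SMD of a sample against an analytic reference distribution: the
# balanced (equal-weight) pooling limit, since the reference is a
# distribution rather than a finite group.
smdVsReference <- function(x, dist) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stopf("need at least 2 values")
  sp <- sqrt((stats::var(x) + referenceSd(dist)^2) / 2)
  (mean(x) - referenceMean(dist)) / sp
}

#' Classify an SMD into the conventional effect-size bands
#'
#' Bands on the absolute SMD: below 0.2 small, 0.2 to 0.8 moderate,
#' above 0.8 large.
#'
#' @param smd finite numeric vector of standardized mean differences.
#' @return Factor with levels `small`, `moderate`, `large`.
#' @export
classifyEffectSize <- function(smd) {
  if (anyNA(smd) || !all(is.finite(smd))) stopf("smd must be finite")
  a <- abs(smd)
  factor(ifelse(a < 0.2, "small", ifelse(a <= 0.8, "moderate", "large")),
         levels = c("small", "moderate", "large"))
}

#' One-sample Wilcoxon signed-rank test against a reference mean
#'
#' Tests whether the ICU sample is located away from the reference
#' distribution's mean: signed ranks of `x - referenceMean(dist)`, zero
#' differences dropped, mid-ranks for ties, normal approximation with tie
#' correction for n > 25 (exact otherwise), two-sided.
#'
#' @param x numeric vector with at least 6 values (NAs removed).
#' @param dist a [ReferenceDistribution], or a single number taken as the
#'   reference mean.
#' @return Two-sided p-value.
#' @export
locationShiftTest <- function(x, dist) {
  mu <- if (is(dist, "ReferenceDistribution")) referenceMean(dist)
        else if (isScalarNumber(dist)) dist
        else stopf("dist must be a ReferenceDistribution or a number")
  x <- x[!is.na(x)]
  if (length(x) < 6L) stopf("signed-rank test requires n >= 6")
  d <- x - mu
  if (all(d == 0)) {
    warning("all differences from the reference mean are zero; p = 1")
    return(1)
  }
  exact <- length(d[d != 0]) <= 25 && !any(duplicated(abs(d[d != 0])))
  res <- suppressWarnings(
    wilcox.test(x, mu = mu, exact = exact, correct = FALSE))
  unname(res$p.value)
}

#' Omnibus comparison of a variable across outcome groups
#'
#' Kruskal-Wallis rank test (with tie correction) for continuous
#' variables; Pearson chi-square without continuity correction for
#' categorical ones.
#'
#' @param values numeric vector (continuous) or vector/factor of
#'   categories (categorical); alternatively, for `kind = "categorical"`,
#'   a pre-tabulated contingency matrix (then `groups` is ignored).
#' @param groups group labels aligned with `values`.
#' @param kind `"continuous"` or `"categorical"`.
#' @return List with `statistic`, `df` and `p_value`.
#' @examples
#' groupComparison(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
#' @export
groupComparison <- function(values, groups = NULL,
                            kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    keep <- !is.na(values) & !is.na(groups)
    values <- values[keep]
    g <- factor(as.character(groups[keep]))
    if (nlevels(g) < 2L) stopf("need at least 2 groups")
    if (any(table(g) == 0L)) stopf("every group needs at least one value")
    res <- kruskal.test(values, g)
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value))
  } else {
    tab <- if (is.matrix(values) || is.table(values)) as.table(values)
           else {
             keep <- !is.na(values) & !is.na(groups)
             table(factor(as.character(values[keep])),
                   factor(as.character(groups[keep])))
           }
    if (any(dim(tab) < 2L)) stopf("contingency table must be at least 2 x 2")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stopf("every group needs at least one observation")
    res <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value))
  }
}
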