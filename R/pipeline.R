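#' @include divergence-stats.R outcome-profiles.R cohort-builder.R
NULL

# Values of one feature for one comparison population.
featureValues <- function(cohort, feature, which = c("all", "best", "worst")) {
  which <- match.arg(which)
  v <- worstValues(cohort)[feature, ]
  g <- outcomeGroups(cohort)
  v <- switch(which, all = v,
              best = v[g == "Q1_BEST"],
              worst = v[g == "DIED_WORST"])
  v[!is.na(v)]
}

#' Divergence of ICU lab distributions from the hospital reference
#'
#' For every (test, direction) feature of the cohort, compares the worst
#' first-day value distribution of (a) all ICU stays, (b) the best-outcome
#' group and (c) the worst-outcome group against the instantiated hospital
#' reference interval — reporting the overlapping coefficient (OVL,
#' kernel density vs exact reference density), the standardized mean
#' difference (SMD; ICU minus reference, so negative means ICU values run
#' low), its effect-size band, and a one-sample Wilcoxon signed-rank
#' p-value — plus the best-vs-worst contrast (KDE-vs-KDE OVL, two-sample
#' pooled SMD, Kruskal-Wallis p). Features with fewer than `minN`
#' non-missing values in a population get `NA` for that comparison;
#' features with no values at all are dropped with a warning.
#'
#' @param cohort an [IcuCohort].
#' @param gridPoints,bandwidthRule kernel density settings (see
#'   [estimateDensity()]).
#' @param sampledReference if `TRUE`, replace the analytic reference side
#'   by a seeded sample (parity-check mode).
#' @param referenceN sampled-reference size; `NULL` (default) matches the
#'   size of the ICU population being compared, so the two-sample pooled
#'   SMD is comparable with the analytic equal-weight pooling.
#' @param referenceSeed base seed for the reference draws.
#' @param minN minimum non-missing values per population (default 10).
#' @return `data.frame`, one row per feature: sample sizes, and
#'   `ovl_*` / `smd_*` / `band_*` / `p_*` columns for `all`, `best`,
#'   `worst` (vs reference) and `best_worst`; full precision plus
#'   2-decimal `*_disp` display columns for OVL and SMD.
#' @export
divergenceTable <- function(cohort, gridPoints = 512L,
                            bandwidthRule = "silverman",
                            sampledReference = FALSE, referenceN = NULL,
                            referenceSeed = 1L, minN = 10L) {
  stopifnot(is(cohort, "IcuCohort"))
  rd <- SummarizedExperiment::rowData(cohort)
  rows <- list()
  for (feature in rownames(cohort)) {
    spec <- as.list(rd[feature, , drop = FALSE])
    dist <- intervalToDistribution(spec)
    pops <- list(all = featureValues(cohort, feature, "all"),
                 best = featureValues(cohort, feature, "best"),
                 worst = featureValues(cohort, feature, "worst"))
    if (!length(pops$all)) {
      warning(sprintf("feature %s has no non-missing values; dropped",
                      feature))
      next
    }
    floor0 <- if (min(pops$all) >= 0) 0 else NULL
    row <- list(feature = feature, test_id = spec$test_id,
                direction = spec$direction, units = spec$units,
                ref_lower = spec$ref_lower, ref_upper = spec$ref_upper,
                n_all = length(pops$all), n_best = length(pops$best),
                n_worst = length(pops$worst))
    kdes <- list()
    for (p in names(pops)) {
      x <- pops[[p]]
      ok <- length(x) >= minN && length(unique(x)) >= 2L
      if (ok) {
        kdes[[p]] <- estimateDensity(x, bandwidthRule, gridPoints, floor0)
        if (sampledReference) {
          nRef <- if (is.null(referenceN)) length(x) else referenceN
          refSample <- sampleReference(
            dist, nRef,
            seed = deriveSeed(referenceSeed, paste(feature, p)))
          ovl <- overlapCoefficient(
            kdes[[p]],
            estimateDensity(refSample, bandwidthRule, gridPoints, floor0))
          smd <- standardizedMeanDifference(x, refSample)
        } else {
          ovl <- overlapCoefficient(kdes[[p]], dist)
          smd <- smdVsReference(x, dist)
        }
        pv <- if (length(x) >= 6) locationShiftTest(x, dist) else NA_real_
      } else {
        ovl <- smd <- pv <- NA_real_
      }
      row[[paste0("ovl_", p)]] <- ovl
      row[[paste0("smd_", p)]] <- smd
      row[[paste0("band_", p)]] <-
        if (is.na(smd)) NA_character_ else as.character(classifyEffectSize(smd))
      row[[paste0("p_", p)]] <- pv
    }
    if (!is.null(kdes$best) && !is.null(kdes$worst)) {
      row$ovl_best_worst <- overlapCoefficient(kdes$best, kdes$worst)
      row$smd_best_worst <- standardizedMeanDifference(pops$best, pops$worst)
      row$p_best_worst <- groupComparison(
        c(pops$best, pops$worst),
        rep(c("best", "worst"), c(length(pops$best), length(pops$worst))),
        "continuous")$p_value
    } else {
      row$ovl_best_worst <- row$smd_best_worst <- row$p_best_worst <- NA_real_
    }
    rows[[feature]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stopf("no feature had any non-missing values")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (col in grep("^(ovl|smd)_", colnames(out), value = TRUE))
    out[[paste0(col, "_disp")]] <- sprintf("%.2f", out[[col]])
  out
}

#' Density-comparison curves for plotting
#'
#' The data behind an ICU-vs-reference density figure: KDE curves for the
#' full cohort, best- and worst-outcome groups of one feature, the exact
#' reference density, and the reference interval bounds, in long format.
#'
#' @param cohort an [IcuCohort].
#' @param feature a row name of the cohort (e.g. `"lactate_max"`).
#' @param gridPoints,bandwidthRule kernel density settings.
#' @param minN minimum group size for a curve to be emitted.
#' @return `data.frame` with columns `feature`, `curve`
#'   (`all`/`best`/`worst`/`reference`), `value`, `density`,
#'   `ref_lower`, `ref_upper`.
#' @export
densityComparisonTable <- function(cohort, feature, gridPoints = 512L,
                                   bandwidthRule = "silverman", minN = 10L) {
  stopifnot(is(cohort, "IcuCohort"), feature %in% rownames(cohort))
  spec <- as.list(SummarizedExperiment::rowData(cohort)[feature, ,
                                                        drop = FALSE])
  dist <- intervalToDistribution(spec)
  pops <- list(all = featureValues(cohort, feature, "all"),
               best = featureValues(cohort, feature, "best"),
               worst = featureValues(cohort, feature, "worst"))
  floor0 <- if (length(pops$all) && min(pops$all) >= 0) 0 else NULL
  out <- list()
  for (p in names(pops)) {
    x <- pops[[p]]
    if (length(x) >= minN && length(unique(x)) >= 2L) {
      kde <- estimateDensity(x, bandwidthRule, gridPoints, floor0)
      out[[p]] <- data.frame(feature = feature, curve = p,
                             value = densityGrid(kde),
                             density = densityValues(kde),
                             stringsAsFactors = FALSE)
    }
  }
  span <- if (length(out)) range(unlist(lapply(out, `[[`, "value"))) else NULL
  ref <- referenceDensityEstimate(dist, gridPoints, span = span)
  out$reference <- data.frame(feature = feature, curve = "reference",
                              value = densityGrid(ref),
                              density = densityValues(ref),
                              stringsAsFactors = FALSE)
  out <- do.call(rbind, out)
  out$ref_lower <- spec$ref_lower
  out$ref_upper <- spec$ref_upper
  rownames(out) <- NULL
  out
}

fmtMedianIqr <- function(x) {
  q <- quantileLinear(x[!is.na(x)], c(0.5, 0.25, 0.75))
  sprintf("%.2f (%.2f-%.2f)", q[1], q[2], q[3])
}

#' Baseline-characteristics summary of best vs worst outcome groups
#'
#' The cohort-description table: for each covariate and lab feature,
#' median (IQR) per group with a Kruskal-Wallis p-value for continuous
#' variables, count (%) with a chi-square p-value for categorical ones.
#' Columns entirely missing in both groups are flagged (`note`), not
#' fatal.
#'
#' @param cohort an [IcuCohort] containing both `Q1_BEST` and
#'   `DIED_WORST` stays.
#' @param covariates which colData columns to summarize; defaults to
#'   age, LOS and the standard flags when present.
#' @return `data.frame` with columns `variable`, `kind`, `best`, `worst`,
#'   `p_value`, `note`.
#' @export
summarizeBestWorst <- function(cohort, covariates = NULL) {
  stopifnot(is(cohort, "IcuCohort"))
  g <- outcomeGroups(cohort)
  if (!any(g == "Q1_BEST") || !any(g == "DIED_WORST"))
    stopf("cohort must contain both Q1_BEST and DIED_WORST stays")
  sel <- g %in% c("Q1_BEST", "DIED_WORST")
  grp <- droplevels(g[sel])
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))[sel, ,
                                                             drop = FALSE]
  if (is.null(covariates))
    covariates <- intersect(c("age_years", "los_days", "female",
                              "vasopressor", "ventilation", "care_unit"),
                            colnames(cd))
  summarizeOne <- function(name, x) {
    isBest <- grp == "Q1_BEST"
    if (all(is.na(x)))
      return(data.frame(variable = name, kind = "continuous", best = NA,
                        worst = NA, p_value = NA_real_,
                        note = "entirely missing", stringsAsFactors = FALSE))
    if (is.numeric(x)) {
      p <- tryCatch(groupComparison(x, grp, "continuous")$p_value,
                    error = function(e) NA_real_)
      data.frame(variable = name, kind = "continuous",
                 best = fmtMedianIqr(x[isBest]),
                 worst = fmtMedianIqr(x[!isBest]),
                 p_value = p, note = "", stringsAsFactors = FALSE)
    } else {
      x <- as.factor(x)
      p <- tryCatch(groupComparison(x, grp, "categorical")$p_value,
                    error = function(e) NA_real_)
      lv <- levels(x)
      fmt <- function(mask) {
        tab <- table(factor(x[mask], levels = lv))
        sprintf("%d (%.1f)", tab, 100 * tab / max(sum(tab), 1L))
      }
      data.frame(variable = if (length(lv) > 1L && !is.logical(x))
                              paste(name, lv, sep = ": ") else name,
                 kind = "categorical", best = fmt(isBest),
                 worst = fmt(!isBest),
                 p_value = c(p, rep(NA_real_, length(lv) - 1L)),
                 note = "", stringsAsFactors = FALSE)
    }
  }
  rows <- list()
  for (cv in covariates) {
    x <- cd[[cv]]
    if (is.logical(x)) {
      isBest <- grp == "Q1_BEST"
      p <- tryCatch(groupComparison(x, grp, "categorical")$p_value,
                    error = function(e) NA_real_)
      fmt <- function(mask) sprintf("%d (%.1f)", sum(x[mask], na.rm = TRUE),
                                    100 * mean(x[mask], na.rm = TRUE))
      rows[[cv]] <- data.frame(variable = cv, kind = "categorical",
                               best = fmt(isBest), worst = fmt(!isBest),
                               p_value = p, note = "",
                               stringsAsFactors = FALSE)
    } else rows[[cv]] <- summarizeOne(cv, x)
  }
  wv <- worstValues(cohort)[, sel, drop = FALSE]
  for (feature in rownames(wv))
    rows[[feature]] <- summarizeOne(feature, wv[feature, ])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
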