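#' @include panel.R
#' @import data.table
NULL

parseTimes <- function(x, what) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  if (anyNA(out) && !all(is.na(x)))
    stopf("unparseable %s timestamp(s), e.g. '%s'", what,
          x[which(is.na(out) & !is.na(x))[1]])
  out
}

checkStayTable <- function(stays) {
  req <- c("subject_id", "stay_id", "intime", "outtime", "icu_death")
  miss <- setdiff(req, colnames(stays))
  if (length(miss))
    stopf("stay table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(stays$stay_id))
    stopf("duplicate stay_id in stay table: %s",
          paste(head(unique(stays$stay_id[duplicated(stays$stay_id)]), 5),
                collapse = ", "))
  stays$intime <- parseTimes(stays$intime, "intime")
  stays$outtime <- parseTimes(stays$outtime, "outtime")
  if (any(stays$outtime <= stays$intime))
    stopf("every stay must have outtime > intime (offending stay_id: %s)",
          stays$stay_id[which(stays$outtime <= stays$intime)[1]])
  stays$los_days <- as.numeric(difftime(stays$outtime, stays$intime,
                                        units = "days"))
  stays
}

#' Select each subject's first adult ICU stay
#'
#' Keeps exactly one stay per subject — the earliest `intime`, ties broken
#' by smallest `stay_id` — and drops stays of patients younger than
#' `adultAgeMin`. Masked-age deidentification sentinels (age > 300 years)
#' are retained as adults. Restricting to first stays keeps data points
#' independent across patients.
#'
#' @param stays stay table: `subject_id`, `stay_id`, `intime`, `outtime`,
#'   `age_years`, `icu_death` (+ any covariates, carried through).
#' @param adultAgeMin adult age threshold in years (default 18).
#' @return The filtered stay table with a derived `los_days` column.
#' @export
selectFirstStays <- function(stays, adultAgeMin = 18) {
  stays <- checkStayTable(stays)
  if (!"age_years" %in% colnames(stays))
    stopf("stay table lacks column(s): age_years")
  ord <- order(stays$subject_id, stays$intime, stays$stay_id)
  stays <- stays[ord, , drop = FALSE]
  first <- !duplicated(stays$subject_id)
  out <- stays[first, , drop = FALSE]
  adult <- out$age_years >= adultAgeMin | out$age_years > 300
  out <- out[adult, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract worst first-day lab values
#'
#' For every (selected) stay and panel test, scans the lab events falling
#' in the first-day window `[intime, intime + windowHours)` and emits the
#' minimum and/or maximum observed value according to the test's
#' configured worst-value direction(s). Events are matched by `stay_id`;
#' events without a `stay_id` fall back to `subject_id` plus the time
#' window. Stays with no event for a test yield no record — per-test
#' missingness is preserved, so a patient missing only albumin still
#' contributes to every other test's analysis.
#'
#' @param events event table: `subject_id`, optional `stay_id`,
#'   `test_id`, `charttime`, numeric `value`.
#' @param stays stay table (typically from [selectFirstStays()]).
#' @param panel a lab panel (see [labPanel()]).
#' @param windowHours first-day window length in hours, default 24
#'   (half-open, measured from ICU admission).
#' @return `data.frame` with columns `stay_id`, `test_id`, `direction`
#'   (`"min"`/`"max"`) and `value`; at most one row per combination.
#' @export
extractWorstFirstDay <- function(events, stays, panel, windowHours = 24) {
  panel <- validatePanel(panel)
  stays <- checkStayTable(stays)
  if (!isScalarNumber(windowHours) || windowHours <= 0)
    stopf("windowHours must be > 0")
  req <- c("subject_id", "test_id", "charttime", "value")
  miss <- setdiff(req, colnames(events))
  if (length(miss))
    stopf("event table lacks column(s): %s", paste(miss, collapse = ", "))
  emptyRec <- data.frame(stay_id = character(), test_id = character(),
                         direction = character(), value = numeric(),
                         stringsAsFactors = FALSE)
  if (!nrow(events)) return(emptyRec)
  if (!is.numeric(events$value)) {
    suppressWarnings(v <- as.numeric(events$value))
    bad <- which(is.na(v) & !is.na(events$value))
    if (length(bad))
      stopf("non-numeric lab value in event row %d (test %s, value '%s')",
            bad[1], events$test_id[bad[1]], events$value[bad[1]])
    events$value <- v
  }
  bad <- which(!is.finite(events$value))
  if (length(bad))
    stopf("non-finite lab value in event row %d (test %s)",
          bad[1], events$test_id[bad[1]])

  ev <- data.table::as.data.table(
    events[, c("subject_id", "test_id", "charttime", "value",
               intersect("stay_id", colnames(events)))])
  ev <- ev[ev$test_id %in% panel$test_id]
  if (!nrow(ev)) return(emptyRec)
  ev$charttime <- parseTimes(ev$charttime, "charttime")

  st <- data.table::as.data.table(
    stays[, c("subject_id", "stay_id", "intime")])
  st$wend <- st$intime + windowHours * 3600

  if ("stay_id" %in% colnames(ev)) {
    byStay <- ev[!is.na(ev$stay_id)]
    byFall <- ev[is.na(ev$stay_id)]
  } else {
    byStay <- ev[0]
    byFall <- ev
  }
  matched <- NULL
  if (nrow(byStay)) {
    m <- merge(byStay, st, by = "stay_id")
    m <- m[m$charttime >= m$intime & m$charttime < m$wend]
    matched <- m[, c("stay_id", "test_id", "value")]
  }
  if (nrow(byFall)) {
    byFall$stay_id <- NULL
    m <- merge(byFall, st, by = "subject_id", allow.cartesian = TRUE)
    m <- m[m$charttime >= m$intime & m$charttime < m$wend]
    matched <- rbind(matched, m[, c("stay_id", "test_id", "value")])
  }
  if (is.null(matched) || !nrow(matched)) return(emptyRec)

  agg <- matched[, list(vmin = min(value), vmax = max(value)),
                 by = c("stay_id", "test_id")]
  dirs <- setNames(panel$directions, panel$test_id)
  wantMin <- dirs[agg$test_id] %in% c("min", "both")
  wantMax <- dirs[agg$test_id] %in% c("max", "both")
  recs <- rbind(
    data.frame(stay_id = agg$stay_id[wantMin], test_id = agg$test_id[wantMin],
               direction = rep("min", sum(wantMin)),
               value = agg$vmin[wantMin], stringsAsFactors = FALSE),
    data.frame(stay_id = agg$stay_id[wantMax], test_id = agg$test_id[wantMax],
               direction = rep("max", sum(wantMax)),
               value = agg$vmax[wantMax], stringsAsFactors = FALSE))
  recs <- recs[order(recs$stay_id, recs$test_id, recs$direction), ,
               drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Stratify stays into the five outcome groups
#'
#' ICU deaths form the worst-outcome group; survivors are ranked by
#' `(los_days, stay_id)` ascending and rank `r` of `n` is mapped to
#' survivor LOS quartile `ceiling(4 r / n)` — quartile 1, the shortest
#' stays, is the best outcome. The `stay_id` tie-break makes the
#' assignment deterministic under tied LOS and invariant to input row
#' order.
#'
#' @param stays selected stay table with `stay_id`, `icu_death` and
#'   `los_days` (or `intime`/`outtime` from which LOS is derived).
#' @return `data.frame` with `stay_id` and `outcome` (factor with levels
#'   [outcomeLevels()]).
#' @export
assignOutcomeGroups <- function(stays) {
  if (!nrow(stays)) stopf("cannot stratify an empty stay table")
  if (!"los_days" %in% colnames(stays)) stays <- checkStayTable(stays)
  death <- as.logical(stays$icu_death)
  nSurv <- sum(!death)
  if (nSurv > 0 && nSurv < 4)
    stopf(paste("only %d survivor(s): too few for LOS quartiles;",
                "merge groups or enlarge the cohort"), nSurv)
  outcome <- rep(NA_character_, nrow(stays))
  outcome[death] <- "DIED_WORST"
  if (nSurv) {
    surv <- which(!death)
    r <- integer(nSurv)
    r[order(stays$los_days[surv], stays$stay_id[surv])] <- seq_len(nSurv)
    outcome[surv] <- outcomeLevels()[ceiling(4 * r / nSurv)]
  }
  data.frame(stay_id = stays$stay_id,
             outcome = factor(outcome, levels = outcomeLevels()),
             stringsAsFactors = FALSE)
}

#' Assemble the analysis cohort
#'
#' Joins worst-value records, outcome groups and stay-level covariates
#' into an [IcuCohort] (a `SummarizedExperiment`): one column per included
#' stay, one row per (test, direction) feature, `"worst"` assay holding
#' the worst first-day values with `NA` for missing tests.
#'
#' @param records worst-value records from [extractWorstFirstDay()].
#' @param stays the selected stay table (defines the cohort columns).
#' @param panel the lab panel.
#' @param groups optional precomputed output of [assignOutcomeGroups()];
#'   computed from `stays` when `NULL`.
#' @return An [IcuCohort].
#' @export
buildCohort <- function(records, stays, panel, groups = NULL) {
  panel <- validatePanel(panel)
  stays <- checkStayTable(stays)
  if (is.null(groups)) groups <- assignOutcomeGroups(stays)
  if (nrow(records)) {
    unknown <- setdiff(records$stay_id, stays$stay_id)
    if (length(unknown))
      stopf("worst-value record references unknown stay_id: %s",
            paste(head(unknown, 5), collapse = ", "))
  }
  feats <- panelFeatures(panel)
  mat <- matrix(NA_real_, nrow = nrow(feats), ncol = nrow(stays),
                dimnames = list(feats$feature, stays$stay_id))
  if (nrow(records)) {
    f <- paste(records$test_id, records$direction, sep = "_")
    keep <- f %in% feats$feature
    mat[cbind(match(f[keep], feats$feature),
              match(records$stay_id[keep], stays$stay_id))] <-
      records$value[keep]
  }
  cd <- stays
  cd$outcome <- groups$outcome[match(stays$stay_id, groups$stay_id)]
  if (anyNA(cd$outcome))
    stopf("outcome groups do not cover every stay in the cohort")
  rownames(cd) <- stays$stay_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(worst = mat),
    rowData = S4Vectors::DataFrame(feats[, -1, drop = FALSE]),
    colData = S4Vectors::DataFrame(cd))
  new("IcuCohort", se)
}

#' Flatten a cohort to a wide data frame
#'
#' One row per stay: covariates followed by one column per
#' (test, direction) worst value — the conventional wide analysis table.
#'
#' @param cohort an [IcuCohort].
#' @return `data.frame`.
#' @export
asCohortDataFrame <- function(cohort) {
  stopifnot(is(cohort, "IcuCohort"))
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  wide <- as.data.frame(t(worstValues(cohort)))
  cbind(cd, wide[rownames(cd), , drop = FALSE])
}

#' Read stay / event tables from CSV
#'
#' Readers for the relational extract schema written by
#' [writeSyntheticTables()]. Real-database extracts with different column
#' names can be adapted via `columnMap` (a named character vector,
#' `c(schema_name = "file_name")`).
#'
#' @param path CSV file path.
#' @param columnMap optional column renaming map.
#' @return `data.frame` in the package schema.
#' @export
readStays <- function(path, columnMap = NULL) {
  df <- applyColumnMap(read.csv(path, stringsAsFactors = FALSE), columnMap)
  df <- checkStayTable(df)
  if ("icu_death" %in% colnames(df)) df$icu_death <- asLogicalColumn(df$icu_death)
  for (col in intersect(c("female", "vasopressor", "ventilation"), colnames(df)))
    df[[col]] <- asLogicalColumn(df[[col]])
  df
}

#' @rdname readStays
#' @export
readEvents <- function(path, columnMap = NULL) {
  df <- applyColumnMap(read.csv(path, stringsAsFactors = FALSE), columnMap)
  req <- c("subject_id", "test_id", "charttime", "value")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stopf("event file lacks column(s): %s", paste(miss, collapse = ", "))
  df$charttime <- parseTimes(df$charttime, "charttime")
  df
}

applyColumnMap <- function(df, columnMap) {
  if (is.null(columnMap)) return(df)
  for (target in names(columnMap)) {
    src <- columnMap[[target]]
    if (!src %in% colnames(df)) stopf("columnMap source '%s' not found", src)
    colnames(df)[colnames(df) == src] <- target
  }
  df
}

asLogicalColumn <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}
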