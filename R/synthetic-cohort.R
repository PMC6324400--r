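#' @include panel.R
NULL

#' Describe one synthetic analyte
#'
#' Defines the ground-truth value model for one laboratory test in the
#' synthetic cohort: a normal or log-normal baseline and a per-outcome-group
#' location shift expressed in units of the (latent-scale) standard
#' deviation — i.e. the true standardized mean difference of each group
#' against the baseline. For log-normal analytes `location`/`scale` are
#' `meanlog`/`sdlog` and shifts act on the log scale.
#'
#' @param test_id test identifier (should match a panel entry downstream).
#' @param family `"normal"` or `"lognormal"`.
#' @param location,scale baseline parameters; `scale > 0`.
#' @param shifts numeric length-5 vector of per-group shifts in units of
#'   `scale`, ordered best to worst (`Q1_BEST`, `Q2`, `Q3`, `Q4`,
#'   `DIED_WORST`).
#' @param missingness fraction of patients with no measurement of this
#'   test.
#' @param severityMonotone if `TRUE` (default), require
#'   `|shift[DIED_WORST]| >= |shift[Q1_BEST]|` — the death group diverges
#'   from baseline at least as far as the best survivors.
#' @return A list of class `SyntheticAnalyte`.
#' @export
syntheticAnalyte <- function(test_id, family = c("normal", "lognormal"),
                             location, scale, shifts = numeric(5),
                             missingness = 0, severityMonotone = TRUE) {
  family <- match.arg(family)
  if (!isScalarNumber(location) || !isScalarNumber(scale) || scale <= 0)
    stopf("analyte '%s': location must be finite and scale > 0", test_id)
  if (length(shifts) != 5L || anyNA(shifts) || !all(is.finite(shifts)))
    stopf("analyte '%s': shifts must be 5 finite numbers", test_id)
  assertFraction(missingness, sprintf("analyte '%s' missingness", test_id))
  if (severityMonotone && abs(shifts[5]) < abs(shifts[1]))
    stopf("analyte '%s': severity-monotone requires |death shift| >= |best shift|",
          test_id)
  structure(list(test_id = as.character(test_id), family = family,
                 location = location, scale = scale,
                 shifts = setNames(as.numeric(shifts), outcomeLevels()),
                 missingness = missingness,
                 severityMonotone = severityMonotone),
            class = "SyntheticAnalyte")
}

#' Default synthetic analyte panel
#'
#' Five analytes whose group shifts mimic the qualitative patterns seen in
#' ICU cohorts: albumin and hemoglobin fall with worsening outcome,
#' lactate and creatinine rise (log-normal, right-skewed), sodium barely
#' moves. Missingness mirrors ordering practice: albumin ordered for a
#' minority of patients (59% missing), ionized-calcium-like gaps for
#' lactate (40% missing), the rest nearly complete.
#'
#' @return List of [syntheticAnalyte()] objects.
#' @export
syntheticAnalytes <- function() {
  list(
    syntheticAnalyte("albumin", "normal", location = 3.1, scale = 0.6,
                     shifts = c(0.5, 0.2, 0.0, -0.3, -0.9),
                     missingness = 0.59),
    syntheticAnalyte("hemoglobin", "normal", location = 10.5, scale = 1.9,
                     shifts = c(0.2, 0.05, 0.0, -0.15, -0.5),
                     missingness = 0.10),
    syntheticAnalyte("lactate", "lognormal", location = log(2.0),
                     scale = 0.55,
                     shifts = c(-0.45, -0.15, 0.05, 0.25, 0.95),
                     missingness = 0.40),
    syntheticAnalyte("creatinine", "lognormal", location = log(1.0),
                     scale = 0.5,
                     shifts = c(-0.3, -0.1, 0.0, 0.2, 0.7),
                     missingness = 0.05),
    syntheticAnalyte("sodium", "normal", location = 137.5, scale = 4.5,
                     shifts = c(-0.1, 0.0, 0.0, 0.05, 0.2),
                     missingness = 0.05,
                     severityMonotone = FALSE))
}

#' Configure the synthetic MIMIC-like cohort generator
#'
#' The generator emulates the structural features of a critical-care
#' relational extract that the downstream pipeline must survive:
#' per-patient multiple ICU stays (decoy later stays whose events must be
#' ignored), several same-day measurements per test, per-test missingness,
#' group-conditional location shifts between survivors and non-survivors,
#' and right-skewed length of stay. Defaults state the emulated world:
#' ICU death probability 0.08, survivor LOS log-normal with median 2 days
#' (death group median 2.5 days, same family), 25% of survivors with a
#' later decoy stay, ages uniform 18-89 (optionally masked to a >300-year
#' sentinel, a deidentification artifact readers must tolerate).
#'
#' @param nPatients number of patients (>= 0).
#' @param seed integer master seed; per-analyte substreams are derived
#'   from `(seed, test_id)` so adding an analyte never perturbs another's
#'   draws.
#' @param deathProbability probability a first stay ends in ICU death.
#' @param losMeanlog,losSdlog survivor LOS log-normal parameters (days).
#' @param losDeathMeanlog,losDeathSdlog death-group LOS parameters.
#' @param panel list of [syntheticAnalyte()] objects.
#' @param eventsPerFirstDay mean number of first-day measurements per
#'   measured test (>= 1; count is `1 + Poisson(mean - 1)`).
#' @param multiStayFraction fraction of surviving patients given a decoy
#'   later ICU stay.
#' @param maskedAgeFraction fraction of patients whose age is recoded to
#'   the 308-year masking sentinel.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nPatients, seed = 1L, deathProbability = 0.08,
                            losMeanlog = log(2), losSdlog = 1.0,
                            losDeathMeanlog = log(2.5), losDeathSdlog = 1.0,
                            panel = syntheticAnalytes(),
                            eventsPerFirstDay = 3,
                            multiStayFraction = 0.25,
                            maskedAgeFraction = 0) {
  if (!isScalarNumber(nPatients) || nPatients < 0 ||
      nPatients != floor(nPatients))
    stopf("nPatients must be a non-negative integer")
  assertFraction(deathProbability, "deathProbability")
  assertFraction(multiStayFraction, "multiStayFraction")
  assertFraction(maskedAgeFraction, "maskedAgeFraction")
  for (p in c(losSdlog, losDeathSdlog))
    if (!isScalarNumber(p) || p <= 0) stopf("LOS scale parameters must be > 0")
  if (!isScalarNumber(losMeanlog) || !isScalarNumber(losDeathMeanlog))
    stopf("LOS location parameters must be finite")
  if (!isScalarNumber(eventsPerFirstDay) || eventsPerFirstDay < 1)
    stopf("eventsPerFirstDay must be >= 1")
  if (!length(panel) || !all(vapply(panel, inherits, TRUE, "SyntheticAnalyte")))
    stopf("panel must be a non-empty list of syntheticAnalyte objects")
  ids <- vapply(panel, `[[`, "", "test_id")
  if (anyDuplicated(ids)) stopf("duplicate analyte test_id in panel")
  structure(list(nPatients = as.integer(nPatients), seed = as.integer(seed),
                 deathProbability = deathProbability,
                 losMeanlog = losMeanlog, losSdlog = losSdlog,
                 losDeathMeanlog = losDeathMeanlog,
                 losDeathSdlog = losDeathSdlog, panel = panel,
                 eventsPerFirstDay = eventsPerFirstDay,
                 multiStayFraction = multiStayFraction,
                 maskedAgeFraction = maskedAgeFraction),
            class = "SyntheticConfig")
}

emptyStays <- function() data.frame(
  subject_id = character(), stay_id = character(),
  intime = as.POSIXct(character(), tz = "UTC"),
  outtime = as.POSIXct(character(), tz = "UTC"),
  age_years = numeric(), icu_death = logical(),
  care_unit = character(), female = logical(),
  vasopressor = logical(), ventilation = logical(),
  stringsAsFactors = FALSE)

emptyEvents <- function() data.frame(
  subject_id = character(), stay_id = character(), test_id = character(),
  charttime = as.POSIXct(character(), tz = "UTC"), value = numeric(),
  stringsAsFactors = FALSE)

#' Generate a synthetic ICU cohort
#'
#' Draws a stay table, a lab-event table and a ground-truth record from a
#' [syntheticConfig()]. Identical `(config, seed)` produce identical
#' tables. First-day events of each patient's first stay come from that
#' patient's outcome-group-conditional distribution (the outcome group is
#' determined inside the generator with the same survivor-LOS-quartile
#' rule the pipeline uses); decoy later stays receive baseline-distributed
#' events that a correct pipeline must ignore.
#'
#' @param config a `SyntheticConfig`.
#' @return A list with elements `stays` (one row per ICU stay), `events`
#'   (one row per lab measurement) and `truth` (one row per analyte and
#'   outcome group: true latent location/scale and the true SMD vs
#'   baseline in units of `scale`).
#' @examples
#' sim <- generateCohort(syntheticConfig(200, seed = 7))
#' head(sim$stays)
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stopf("config must come from syntheticConfig()")
  n <- config$nPatients
  truth <- do.call(rbind, lapply(config$panel, function(a) data.frame(
    test_id = a$test_id, group = outcomeLevels(), family = a$family,
    location = a$location + a$shifts * a$scale, scale = a$scale,
    true_smd = unname(a$shifts), missingness = a$missingness,
    stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  if (n == 0L)
    return(list(stays = emptyStays(), events = emptyEvents(),
                truth = truth[0, , drop = FALSE]))

  origin <- as.POSIXct("2001-01-01 00:00:00", tz = "UTC")
  pat <- withSeed(deriveSeed(config$seed, "patients"), {
    subject_id <- sprintf("S%06d", seq_len(n))
    age <- runif(n, 18, 89)
    if (config$maskedAgeFraction > 0) {
      masked <- runif(n) < config$maskedAgeFraction
      age[masked] <- 308  # deidentification sentinel, > 300 years
    }
    female <- runif(n) < 0.435
    death <- runif(n) < config$deathProbability
    los <- ifelse(death,
                  rlnorm(n, config$losDeathMeanlog, config$losDeathSdlog),
                  rlnorm(n, config$losMeanlog, config$losSdlog))
    intime <- origin + round(runif(n, 0, 4322 * 86400))
    care_unit <- sample(c("CCU", "CSRU", "MICU", "SICU"), n, replace = TRUE,
                        prob = c(0.15, 0.15, 0.40, 0.30))
    vaso <- runif(n) < ifelse(death, 0.687, 0.162)
    vent <- runif(n) < ifelse(death, 0.872, 0.271)
    decoy <- !death & runif(n) < config$multiStayFraction
    decoyGap <- runif(n, 1, 30)        # days after first discharge
    decoyLos <- rlnorm(n, config$losMeanlog, config$losSdlog)
    list(subject_id = subject_id, age = age, female = female,
         death = death, los = los, intime = intime, care_unit = care_unit,
         vaso = vaso, vent = vent, decoy = decoy, decoyGap = decoyGap,
         decoyLos = decoyLos)
  })

  group <- rep(NA_character_, n)
  group[pat$death] <- "DIED_WORST"
  surv <- which(!pat$death)
  if (length(surv)) {
    r <- integer(length(surv))
    r[order(pat$los[surv], pat$subject_id[surv])] <- seq_along(surv)
    q <- pmin(pmax(ceiling(4 * r / length(surv)), 1L), 4L)
    group[surv] <- outcomeLevels()[q]
  }
  group <- factor(group, levels = outcomeLevels())

  firstStay <- data.frame(
    subject_id = pat$subject_id,
    stay_id = paste0(pat$subject_id, "-1"),
    intime = pat$intime,
    outtime = pat$intime + round(pat$los * 86400),
    age_years = pat$age, icu_death = pat$death, care_unit = pat$care_unit,
    female = pat$female, vasopressor = pat$vaso, ventilation = pat$vent,
    stringsAsFactors = FALSE)
  stays <- firstStay
  dec <- which(pat$decoy)
  if (length(dec)) {
    decoyStay <- data.frame(
      subject_id = pat$subject_id[dec],
      stay_id = paste0(pat$subject_id[dec], "-2"),
      intime = firstStay$outtime[dec] + round(pat$decoyGap[dec] * 86400),
      outtime = firstStay$outtime[dec] +
        round((pat$decoyGap[dec] + pat$decoyLos[dec]) * 86400),
      age_years = pat$age[dec], icu_death = FALSE,
      care_unit = pat$care_unit[dec], female = pat$female[dec],
      vasopressor = FALSE, ventilation = FALSE, stringsAsFactors = FALSE)
    stays <- rbind(stays, decoyStay)
  }
  stays <- stays[order(stays$stay_id), , drop = FALSE]
  rownames(stays) <- NULL

  # grp is already expanded to one entry per event
  drawValues <- function(a, grp) {
    shift <- unname(a$shifts[as.integer(grp)])
    v <- rnorm(length(shift), a$location + shift * a$scale, a$scale)
    if (a$family == "lognormal") exp(v) else v
  }
  events <- lapply(config$panel, function(a) {
    withSeed(deriveSeed(config$seed, a$test_id), {
      measured <- which(runif(n) >= a$missingness)
      out <- NULL
      if (length(measured)) {
        k <- 1L + rpois(length(measured), config$eventsPerFirstDay - 1)
        idx <- rep(measured, k)
        out <- data.frame(
          subject_id = pat$subject_id[idx],
          stay_id = paste0(pat$subject_id[idx], "-1"),
          test_id = a$test_id,
          charttime = pat$intime[idx] + round(runif(sum(k), 0, 86400 - 1)),
          value = drawValues(a, group[idx]),
          stringsAsFactors = FALSE)
      }
      decMeasured <- intersect(dec, measured)
      if (length(decMeasured)) {
        k2 <- 1L + rpois(length(decMeasured), config$eventsPerFirstDay - 1)
        idx2 <- rep(decMeasured, k2)
        baseGrp <- factor(rep("Q3", length(idx2)), levels = outcomeLevels())
        din <- firstStay$outtime[idx2] + round(pat$decoyGap[idx2] * 86400)
        out <- rbind(out, data.frame(
          subject_id = pat$subject_id[idx2],
          stay_id = paste0(pat$subject_id[idx2], "-2"),
          test_id = a$test_id,
          charttime = din + round(runif(sum(k2), 0, 86400 - 1)),
          value = drawValues(a, baseGrp),
          stringsAsFactors = FALSE))
      }
      out
    })
  })
  events <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
  if (is.null(events)) events <- emptyEvents()
  rownames(events) <- NULL
  list(stays = stays, events = events, truth = truth)
}

#' Exact overlap of two equal-variance normal densities
#'
#' Closed-form overlapping coefficient for `N(mu1, sigma)` vs
#' `N(mu2, sigma)`: `2 * pnorm(-|mu1 - mu2| / (2 * sigma))`. Serves as the
#' analytic oracle against which the kernel-density OVL path is validated.
#'
#' @param mu1,mu2 the two means.
#' @param sigma common standard deviation, `> 0`.
#' @return Overlap in `[0, 1]`.
#' @examples
#' analyticNormalOvl(0, 1, 1)  # 0.6171
#' @export
analyticNormalOvl <- function(mu1, mu2, sigma) {
  if (!isScalarNumber(sigma) || sigma <= 0) stopf("sigma must be > 0")
  if (!all(is.finite(c(mu1, mu2)))) stopf("means must be finite")
  2 * pnorm(-abs(mu1 - mu2) / (2 * sigma))
}

#' Write synthetic tables as CSV
#'
#' Writes `stays.csv`, `events.csv` and `truth.csv` (RFC 4180, ISO-8601
#' UTC timestamps) in the schema read back by [readStays()] /
#' [readEvents()].
#'
#' @param sim result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSyntheticTables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- sim$stays
  st$intime <- format(st$intime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  st$outtime <- format(st$outtime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ev <- sim$events
  ev$charttime <- format(ev$charttime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  paths <- file.path(dir, c("stays.csv", "events.csv", "truth.csv"))
  write.csv(st, paths[1], row.names = FALSE)
  write.csv(ev, paths[2], row.names = FALSE)
  write.csv(sim$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
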