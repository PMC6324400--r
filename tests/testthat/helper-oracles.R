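# Independent oracles and small fixture builders shared across tests.

# Linear-interpolation quantile at position 1 + p*(n-1), written from the
# definition (independent of stats::quantile).
oracleQuantile <- function(x, p) {
  s <- sort(x)
  pos <- 1 + p * (length(s) - 1)
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# Brute-force worst-value scan: per stay, per panel test, loop over every
# event and keep min/max of those inside [intime, intime + window).
oracleWorst <- function(events, stays, panel, windowHours = 24) {
  out <- list()
  for (i in seq_len(nrow(stays))) {
    st <- stays[i, ]
    for (j in seq_len(nrow(panel))) {
      tid <- panel$test_id[j]
      vals <- c()
      for (k in seq_len(nrow(events))) {
        ev <- events[k, ]
        if (ev$test_id != tid) next
        matches <- if (!is.null(events$stay_id) && !is.na(ev$stay_id))
          ev$stay_id == st$stay_id else ev$subject_id == st$subject_id
        if (!matches) next
        dt <- as.numeric(difftime(ev$charttime, st$intime, units = "hours"))
        if (dt >= 0 && dt < windowHours) vals <- c(vals, ev$value)
      }
      if (!length(vals)) next
      dirs <- switch(panel$directions[j], min = "min", max = "max",
                     both = c("min", "max"))
      for (d in dirs)
        out[[length(out) + 1L]] <- data.frame(
          stay_id = st$stay_id, test_id = tid, direction = d,
          value = if (d == "min") min(vals) else max(vals),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(stay_id = character(), test_id = character(),
                      direction = character(), value = numeric()))
  out <- do.call(rbind, out)
  out <- out[order(out$stay_id, out$test_id, out$direction), ]
  rownames(out) <- NULL
  out
}

# Rank-based outcome assignment written independently: deaths worst,
# survivors sorted by (los, stay_id), rank r of n -> ceiling(4r/n).
oracleGroups <- function(stay_id, los, death) {
  out <- rep(NA_character_, length(stay_id))
  out[death] <- "DIED_WORST"
  sv <- which(!death)
  o <- sv[order(los[sv], stay_id[sv])]
  for (i in seq_along(o))
    out[o[i]] <- c("Q1_BEST", "Q2", "Q3", "Q4")[ceiling(4 * i / length(o))]
  factor(out, levels = outcomeLevels())
}

# Minimal stay-table builder.
makeStays <- function(n, losDays = NULL, death = NULL, age = NULL,
                      prefix = "P") {
  origin <- as.POSIXct("2010-01-01", tz = "UTC")
  if (is.null(losDays)) losDays <- rep(2, n)
  if (is.null(death)) death <- rep(FALSE, n)
  if (is.null(age)) age <- rep(50, n)
  data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
             stay_id = sprintf("%s%03d-1", prefix, seq_len(n)),
             intime = origin + (seq_len(n) - 1) * 86400 * 40,
             outtime = origin + (seq_len(n) - 1) * 86400 * 40 +
               losDays * 86400,
             age_years = age, icu_death = death, los_days = losDays,
             stringsAsFactors = FALSE)
}

# Random event/stay fixture with multi-stay decoys and out-of-window events.
makeRandomFixture <- function(nStays = 20, nEvents = 200, tests = c("a", "b"),
                              multiStay = TRUE) {
  stays <- makeStays(nStays, losDays = runif(nStays, 0.5, 10),
                     death = runif(nStays) < 0.2)
  if (multiStay) {
    extra <- stays[seq_len(floor(nStays / 3)), ]
    extra$stay_id <- sub("-1$", "-2", extra$stay_id)
    extra$intime <- extra$outtime + 86400 * 3
    extra$outtime <- extra$intime + 86400 * 2
    stays2 <- rbind(stays, extra)
  } else stays2 <- stays
  pick <- sample(nrow(stays2), nEvents, replace = TRUE)
  events <- data.frame(
    subject_id = stays2$subject_id[pick],
    stay_id = ifelse(runif(nEvents) < 0.8, stays2$stay_id[pick], NA),
    test_id = sample(tests, nEvents, replace = TRUE),
    charttime = stays2$intime[pick] +
      round(runif(nEvents, -12, 60) * 3600),   # some out of window
    value = round(runif(nEvents, 0, 100), 1), stringsAsFactors = FALSE)
  panel <- labPanel(tests, units = "u",
                    directions = rep(c("min", "both"), length.out =
                                       length(tests)),
                    ref_lower = 10, ref_upper = 90)
  list(stays = stays2, firstStays = stays, events = events, panel = panel)
}
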