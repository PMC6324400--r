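#' @include AllClasses.R
NULL

#' Construct and validate a lab panel
#'
#' A lab panel is a plain `data.frame` with one row per laboratory test,
#' carrying the test identity, display name, units, the worst-value
#' direction(s) to extract (`"min"`, `"max"` or `"both"`), the hospital
#' reference interval, and the distribution family used to instantiate
#' that interval (see [intervalToDistribution()]). Units are carried
#' verbatim and must match the units of the event values; no unit
#' conversion is attempted.
#'
#' @param test_id character vector of test identifiers.
#' @param name display names (defaults to `test_id`).
#' @param units character vector of unit strings.
#' @param directions one of `"min"`, `"max"`, `"both"` per test.
#' @param ref_lower,ref_upper hospital reference interval bounds.
#' @param ref_family `"normal"` (default) or `"lognormal"` per test.
#' @return A validated panel `data.frame`.
#' @examples
#' labPanel("lactate", units = "mmol/L", directions = "max",
#'          ref_lower = 0.5, ref_upper = 2.0)
#' @export
labPanel <- function(test_id, name = test_id, units, directions,
                     ref_lower, ref_upper, ref_family = "normal") {
  panel <- data.frame(
    test_id = as.character(test_id), name = as.character(name),
    units = as.character(units), directions = as.character(directions),
    ref_lower = as.numeric(ref_lower), ref_upper = as.numeric(ref_upper),
    ref_family = as.character(ref_family), stringsAsFactors = FALSE)
  validatePanel(panel)
}

#' @rdname labPanel
#' @param panel a panel `data.frame` to validate.
#' @export
validatePanel <- function(panel) {
  req <- c("test_id", "units", "directions", "ref_lower", "ref_upper")
  miss <- setdiff(req, colnames(panel))
  if (length(miss))
    stopf("panel lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"name" %in% colnames(panel)) panel$name <- panel$test_id
  if (!"ref_family" %in% colnames(panel)) panel$ref_family <- "normal"
  if (anyDuplicated(panel$test_id))
    stopf("duplicate test_id in panel: %s",
          paste(unique(panel$test_id[duplicated(panel$test_id)]), collapse = ", "))
  bad <- !panel$directions %in% c("min", "max", "both")
  if (any(bad))
    stopf("directions must be 'min', 'max' or 'both' (offending: %s)",
          paste(panel$test_id[bad], collapse = ", "))
  bad <- !is.finite(panel$ref_lower) | !is.finite(panel$ref_upper) |
    panel$ref_lower >= panel$ref_upper
  if (any(bad))
    stopf("reference interval must have finite lower < upper (offending: %s)",
          paste(panel$test_id[bad], collapse = ", "))
  if (any(!panel$ref_family %in% c("normal", "lognormal")))
    stopf("ref_family must be 'normal' or 'lognormal'")
  panel
}

#' The default routine ICU lab panel
#'
#' The routinely ordered panel with its worst-value directions: minimum
#' only for albumin, ionized calcium, hemoglobin and platelets; maximum
#' only for lactate and bilirubin; both directions for bicarbonate, blood
#' urea nitrogen, creatinine, calcium, magnesium, phosphate, potassium,
#' sodium, glucose and white blood cell count. The lactate reference
#' interval is 0.5-2.0 mmol/L; the remaining intervals are standard adult
#' clinical-chemistry reference ranges. The panel is configuration, not
#' code: pass your institution's intervals via [labPanel()] or
#' [readPanel()].
#'
#' @return A panel `data.frame` (see [labPanel()]).
#' @export
defaultPanel <- function() {
  labPanel(
    test_id = c("albumin", "bicarbonate", "bilirubin", "bun", "creatinine",
                "calcium", "ionized_calcium", "glucose", "hemoglobin",
                "lactate", "magnesium", "phosphate", "platelets",
                "potassium", "sodium", "wbc"),
    name = c("Albumin", "Bicarbonate", "Bilirubin", "Blood urea nitrogen",
             "Creatinine", "Calcium", "Ionized calcium", "Glucose",
             "Hemoglobin", "Lactate", "Magnesium", "Phosphate",
             "Platelet count", "Potassium", "Sodium",
             "White blood cell count"),
    units = c("g/dL", "mEq/L", "mg/dL", "mg/dL", "mg/dL", "mg/dL",
              "mmol/L", "mg/dL", "g/dL", "mmol/L", "mEq/L", "mg/dL",
              "x10^3/uL", "mEq/L", "mEq/L", "x10^3/uL"),
    directions = c("min", "both", "max", "both", "both", "both", "min",
                   "both", "min", "max", "both", "both", "min", "both",
                   "both", "both"),
    ref_lower = c(3.5, 22, 0.1, 6, 0.5, 8.4, 1.14, 70, 12.0, 0.5,
                  1.3, 2.7, 150, 3.4, 135, 4.5),
    ref_upper = c(5.5, 32, 1.2, 20, 1.2, 10.3, 1.30, 105, 16.0, 2.0,
                  2.1, 4.5, 400, 4.8, 145, 11.0))
}

#' Read / write a panel configuration file
#'
#' Panels (tests, directions, units and hospital reference intervals)
#' round-trip through a single JSON file so that every analysis default
#' is auditable configuration.
#'
#' @param path file path.
#' @return `readPanel` returns a validated panel `data.frame`.
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  validatePanel(jsonlite::fromJSON(path))
}

#' @rdname readPanel
#' @param panel a panel `data.frame`.
#' @export
writePanel <- function(panel, path) {
  panel <- validatePanel(panel)
  jsonlite::write_json(panel, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Expand a panel into one row per (test, direction) feature.
panelFeatures <- function(panel) {
  panel <- validatePanel(panel)
  dirList <- lapply(panel$directions, function(d)
    switch(d, min = "min", max = "max", both = c("min", "max")))
  idx <- rep(seq_len(nrow(panel)), lengths(dirList))
  out <- panel[idx, , drop = FALSE]
  out$direction <- unlist(dirList)
  out$feature <- paste(out$test_id, out$direction, sep = "_")
  rownames(out) <- out$feature
  out[, c("feature", "test_id", "direction", "name", "units",
          "ref_lower", "ref_upper", "ref_family")]
}
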