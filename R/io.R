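#' Cohort CSV schema
#'
#' The long-format cohort table: one row per timestamped observation.
#' Mandatory columns are `woman_id`, `timestamp` (hours since admission),
#' the nine vital-sign columns (`resp_rate`, `spo2`, `o2_supplement`,
#' `temperature`, `sbp`, `dbp`, `heart_rate`, `avpu`, `vas_pain`) and the
#' per-woman `morbidity` label. Booleans are written as 0/1, AVPU as
#' letters, missing values as empty cells. Covariate columns (as produced
#' by [sample_covariates()]) are carried through when present.
#'
#' @return Character vector of mandatory column names.
#' @export
cohort_schema <- function() {
  c("woman_id", "timestamp", VITAL_PARAMETERS, "morbidity")
}

schema_error <- function(msg) {
  stop(structure(class = c("ewstriage_schema_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

degenerate_error <- function(msg) {
  stop(structure(class = c("ewstriage_degenerate_error", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a cohort table from CSV
#'
#' Validates the schema (mandatory columns, one morbidity value per woman,
#' non-decreasing timestamps within a stay) and runs
#' [validate_observation()] range checks on every row; issues are collected
#' with their file line numbers (header = line 1) and attached as the
#' `"validation"` attribute rather than discarded, so a chart-review
#' pipeline can report and proceed.
#'
#' @param path CSV file in the [cohort_schema()] layout.
#' @return A `cohort_table` data frame with a `"validation"` attribute
#'   (data frame with columns `line`, `parameter`, `kind`, `message`).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) schema_error(paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_schema(), names(raw))
  if (length(missing_cols))
    schema_error(paste("missing mandatory columns:",
                       paste(missing_cols, collapse = ", ")))
  raw$o2_supplement <- as.logical(raw$o2_supplement)
  raw$morbidity <- as.logical(raw$morbidity)
  if (anyNA(raw$morbidity))
    schema_error("morbidity must be 0/1 for every row")
  conflicts <- tapply(raw$morbidity, raw$woman_id,
                      function(m) length(unique(m)) > 1)
  if (any(conflicts))
    schema_error(paste("conflicting morbidity labels for:",
                       paste(names(conflicts)[conflicts], collapse = ", ")))

  unsorted <- tapply(raw$timestamp, raw$woman_id, is.unsorted)
  if (any(unsorted))
    schema_error(paste("timestamps not non-decreasing for:",
                       paste(names(unsorted)[unsorted], collapse = ", ")))

  issues <- validate_cohort(raw)
  attr(raw, "validation") <- issues
  class(raw) <- c("cohort_table", "data.frame")
  raw
}

# Row-by-row range/type validation with CSV line numbers (header is line 1).
validate_cohort <- function(data, system = NULL) {
  out <- lapply(seq_len(nrow(data)), function(i) {
    iss <- validate_observation(data[i, ], system)
    if (nrow(iss)) cbind(line = i + 1L, iss) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(line = integer(), parameter = character(),
                      kind = character(), message = character())
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: booleans as 0/1, missing as empty cells.
#'
#' @param data A `cohort_table` (or compatible data frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- as.data.frame(data)
  for (col in intersect(c("o2_supplement", "morbidity", "nulliparity",
                          "twin_pregnancy", "red_override"), names(out)))
    out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the accuracy comparison as CSV and/or JSON
#'
#' Both files carry the raw (unrounded) and formatted values for the six
#' test definitions plus prevalence.
#'
#' @param comparison A `dx_comparison` from [evaluate_cohort()].
#' @param csv,json Output paths (either may be `NULL`).
#' @return Invisibly, the raw report data frame.
#' @export
write_report <- function(comparison, csv = NULL, json = NULL) {
  raw <- as.data.frame(comparison)
  fmt <- as.data.frame(comparison, formatted = TRUE)
  names(fmt)[-1] <- paste0(names(fmt)[-1], "_formatted")
  tab <- cbind(raw, fmt[-1])
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(n = comparison$n, n_morbid = comparison$n_morbid,
           prevalence = comparison$prevalence$point,
           prevalence_formatted = fmt_percent_1dp(comparison$prevalence$point),
           tests = tab),
      json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(tab)
}

# Tiny stable FNV-1a hash so pipeline logs can identify a configuration
# without a heavyweight dependency.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run the full pipeline: ingest or simulate, score, triage, evaluate
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param config A [cohort_config()] used when simulating.
#' @param seed Seed for simulation.
#' @param out_dir Directory for outputs: `report.csv`, `report.json`,
#'   `assessments.csv`, and the echoed `cohort.csv` when simulating.
#' @param quiet Suppress the log (written to `stderr`).
#' @return The `dx_comparison`, invisibly.
#' @export
run_pipeline <- function(input = NULL, config = cohort_config(),
                         seed = NULL, out_dir = ".", quiet = FALSE) {
  log <- function(...) if (!quiet) message("[ewstriage] ", sprintf(...))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(input)) {
    log("simulating cohort: n=%d, seed=%s, config=%s", config$n_women,
        as.character(seed %||% "NULL"),
        fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)))
    cohort <- generate_cohort(config, seed = seed)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  } else {
    log("reading cohort from %s", input)
    cohort <- read_cohort(input)
    issues <- attr(cohort, "validation")
    if (nrow(issues)) {
      log("%d validation issue(s); first: line %d: %s", nrow(issues),
          issues$line[1], issues$message[1])
    }
  }
  log("scoring %d observations from %d women", nrow(cohort),
      length(unique(cohort$woman_id)))
  assessments <- assess_cohort(cohort)
  n_morbid <- sum(assessments$morbidity)
  if (n_morbid == 0 || n_morbid == nrow(assessments))
    degenerate_error(sprintf(
      "degenerate cohort: %d of %d women morbid; accuracy undefined",
      n_morbid, nrow(assessments)))
  comparison <- evaluate_cohort(assessments)
  utils::write.csv(as.data.frame(assessments),
                   file.path(out_dir, "assessments.csv"), row.names = FALSE)
  write_report(comparison, csv = file.path(out_dir, "report.csv"),
               json = file.path(out_dir, "report.json"))
  log("report written to %s", out_dir)
  invisible(comparison)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
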