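# Cohort file format: delimited text, one row per dog.

#' Read a dog-level cohort file
#'
#' Reads a delimited cohort file (comma- or tab-separated by extension,
#' overridable with `sep`). Required columns: `id`, `neuter_status`,
#' `age_years`, `breed`. Clinical-sign columns (`polydipsia`, `vomiting`,
#' `potbelly_hepatomegaly`, `alopecia`, `pruritus`) take `yes`/`no`; empty
#' cells resolve to `"no"` (a sign not mentioned in the record is
#' considered absent) and the number of such defaults is reported per
#' column in the attached coercion log. Empty `usg`/`alp` cells resolve to
#' `"not_recorded"`. Optional columns: `outcome` (`case`/`noncase` or
#' 0/1), `tool_score`, `uccr_day1..3`, `alive_*` flags, comorbidity
#' columns. Unknown columns are preserved and ignored.
#'
#' @param path path to the cohort file.
#' @param sep field separator; defaults to `","` unless the extension is
#'   `.tsv`/`.txt` (then tab).
#' @return cohort data frame with attribute `coercion_log`, a named count
#'   of defaults applied per column.
#' @export
read_cohort <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = TRUE)
  required <- c("id", "neuter_status", "age_years", "breed")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  log <- c()
  age <- suppressWarnings(as.numeric(raw$age_years))
  bad <- which(is.na(age) | age < 0)
  if (length(bad)) {
    stop("unparseable or negative age_years at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw$age_years <- age
  for (sign in SIGN_FIELDS) {
    if (!sign %in% names(raw)) next
    v <- raw[[sign]]
    n_default <- sum(is.na(v) | v == "")
    if (n_default) {
      log[sign] <- n_default
      message(n_default, " empty ", sign, " cell(s) resolved to \"no\"")
    }
  }
  for (lab in c("usg", "alp")) {
    if (!lab %in% names(raw)) next
    n_default <- sum(is.na(raw[[lab]]) | raw[[lab]] == "")
    if (n_default) {
      log[lab] <- n_default
      message(n_default, " empty ", lab, " cell(s) resolved to \"not_recorded\"")
    }
  }
  out <- resolve_profiles(raw)
  if ("outcome" %in% names(out)) {
    oc <- out$outcome
    if (all(oc %in% c("case", "noncase"))) {
      out$outcome <- as.integer(oc == "case")
    } else if (all(oc %in% c("0", "1"))) {
      out$outcome <- as.integer(oc)
    } else {
      stop("outcome column must be case/noncase or 0/1", call. = FALSE)
    }
  }
  for (num in c("tool_score", "uccr_day1", "uccr_day2", "uccr_day3")) {
    if (num %in% names(out)) out[[num]] <- suppressWarnings(as.numeric(out[[num]]))
  }
  for (fl in grep("^alive_", names(out), value = TRUE)) {
    out[[fl]] <- tolower(out[[fl]]) %in% c("true", "yes", "1")
  }
  attr(out, "coercion_log") <- log
  out
}

#' Write a cohort data frame to a delimited file
#'
#' Logical sign columns are written as `yes`/`no`; a 0/1 outcome is written
#' as `case`/`noncase`, so a written cohort round-trips through
#' [read_cohort()].
#'
#' @param cohort cohort data frame.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (sign in intersect(SIGN_FIELDS, names(out))) {
    if (is.logical(out[[sign]])) out[[sign]] <- ifelse(out[[sign]], "yes", "no")
  }
  if ("outcome" %in% names(out) && is.numeric(out$outcome)) {
    out$outcome <- ifelse(out$outcome == 1, "case", "noncase")
  }
  drop <- intersect(c("breed_score", "breed_model", "age_band2", "age_band3"), names(out))
  out <- out[, setdiff(names(out), drop), drop = FALSE]
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
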