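# Patient cohorts: validated clinical records plus the eight-variable
# median summaries used for model matching.

# canonical column order for a cohort data.frame
COHORT_COLS <- c("case_id", "age", "preop_psa", "gleason_primary",
                 "gleason_secondary", "stage_ord", "margin_positive", "svi",
                 "ln_positive", "ece", "surgery_year", "pfs_time", "event")

# the eight matching variables of the weighted-distance step, in fixed order
MATCH_VARS <- c("age", "margin_positive", "stage_ord", "gleason_primary",
                "gleason_secondary", "preop_psa", "svi", "ln_positive")
MATCH_CONTINUOUS <- c("age", "stage_ord", "gleason_primary",
                      "gleason_secondary", "preop_psa")
MATCH_BINARY <- setdiff(MATCH_VARS, MATCH_CONTINUOUS)

#' Matching variables
#'
#' The eight clinical variables used for cohort matching, in the fixed order
#' in which median vectors and weight vectors are laid out: age, margin
#' status, pathologic tumor stage (ordinal), Gleason primary score, Gleason
#' secondary score, pre-operative PSA, seminal vesicle invasion, lymph node
#' status.
#'
#' @return Character vector of length 8.
#' @export
match_vars <- function() MATCH_VARS

#' Construct a validated patient cohort
#'
#' A cohort is a data.frame of post-prostatectomy cases, one row per patient,
#' carrying the clinical covariates used for matching, the covariates carried
#' but not matched on (extraprostatic extension, surgery year), and the
#' observed follow-up (`pfs_time` in years from surgery, `event` = 1 if
#' progression was observed, 0 if censored).
#'
#' @param patients data.frame with columns `case_id`, `age`, `preop_psa`,
#'   `gleason_primary`, `gleason_secondary`, `stage_ord` (2 = pT2, 3 = pT3,
#'   4 = pT4), `margin_positive`, `svi`, `ln_positive`, `ece` (all 0/1),
#'   `surgery_year`, `pfs_time` (> 0, years), `event` (0/1).
#' @param label Cohort label used in provenance blocks.
#' @return A `cohort` object (a data.frame with attribute `label`).
#' @export
cohort <- function(patients, label = "cohort") {
  if (!is.data.frame(patients)) stop("`patients` must be a data.frame")
  missing_cols <- setdiff(COHORT_COLS, names(patients))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  patients <- patients[, COHORT_COLS]
  patients$case_id <- as.character(patients$case_id)
  if (nrow(patients) == 0L) stop("cohort must contain at least one patient")
  if (anyDuplicated(patients$case_id)) {
    stop("duplicated case_id: ",
         paste(unique(patients$case_id[duplicated(patients$case_id)]),
               collapse = ", "))
  }
  problems <- validate_patient_rows(patients)
  if (length(problems) > 0L) {
    stop("invalid patient row(s):\n  ", paste(problems, collapse = "\n  "))
  }
  rownames(patients) <- NULL
  structure(patients, label = label, class = c("cohort", "data.frame"))
}

# returns character vector of row-level problems, "" case_id tagged
validate_patient_rows <- function(df) {
  msgs <- character(0)
  chk <- function(bad, what) {
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      idx <- which(bad | is.na(bad))
      msgs <<- c(msgs, sprintf("case_id %s: %s", df$case_id[idx], what))
    }
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  chk(!(num(df$age) > 0), "age must be a positive number")
  chk(!(num(df$preop_psa) > 0), "preop_psa must be > 0")
  chk(!(num(df$gleason_primary) %in% 2:5), "gleason_primary must be in 2..5")
  chk(!(num(df$gleason_secondary) %in% 2:5), "gleason_secondary must be in 2..5")
  chk(!(num(df$stage_ord) %in% 2:4), "stage_ord must be 2 (pT2), 3 (pT3) or 4 (pT4)")
  for (v in c("margin_positive", "svi", "ln_positive", "ece", "event")) {
    chk(!(num(df[[v]]) %in% c(0, 1)), paste0(v, " must be 0 or 1"))
  }
  chk(!(num(df$pfs_time) > 0), "pfs_time must be > 0")
  chk(!is.finite(num(df$surgery_year)), "surgery_year must be numeric")
  msgs
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  attr(x, "label") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Patient cohort '%s': %d cases, %d progression events (%.0f%% censored)\n",
              attr(x, "label"), nrow(x), sum(x$event),
              100 * mean(x$event == 0)))
  cat(sprintf("  median age %.1f, median pre-op PSA %.2f ng/mL, median follow-up %.2f y\n",
              median(x$age), median(x$preop_psa), median(x$pfs_time)))
  invisible(x)
}

#' Read a patient cohort from CSV
#'
#' Reads one row per case. Rows violating the record invariants (Gleason
#' grades outside 2–5, non-positive PSA or follow-up time, non-binary flags)
#' are rejected with row-level diagnostics naming the case; a missing column
#' is a schema error. Rows with missing matching variables are rejected, not
#' imputed.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping canonical column names (see
#'   [cohort()]) to the file's header names; defaults to identity.
#' @param label Cohort label.
#' @param drop_invalid If `TRUE`, invalid rows are dropped with a warning
#'   listing each offending case; if `FALSE` (default) any invalid row is an
#'   error.
#' @return A `cohort`.
#' @export
read_cohort <- function(path, schema = NULL, label = NULL,
                        drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0L) {
      stop("schema names column(s) absent from file: ",
           paste(missing_src, collapse = ", "))
    }
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(COHORT_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw$case_id <- as.character(raw$case_id)
  if (drop_invalid) {
    problems <- validate_patient_rows(raw)
    if (length(problems) > 0L) {
      bad_ids <- sub("^case_id (\\S+):.*$", "\\1", problems)
      warning("dropping ", length(unique(bad_ids)), " invalid row(s):\n  ",
              paste(problems, collapse = "\n  "), call. = FALSE)
      raw <- raw[!(raw$case_id %in% bad_ids), , drop = FALSE]
    }
  }
  cohort(raw, label = if (is.null(label)) basename(path) else label)
}

#' Write a cohort to CSV (round-trip safe)
#'
#' @param x A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x)[, COHORT_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Clinical median vector of a cohort
#'
#' Entrywise median of the eight matching variables, in the fixed
#' [match_vars()] order. Medians are ordinary sample medians throughout (for
#' an even number of cases, the mean of the two central order statistics), so
#' binary variables can yield 0, 0.5 or 1.
#'
#' @param x A `cohort` (or data.frame with the matching columns).
#' @return Named numeric vector of length 8.
#' @export
cohort_medians <- function(x) {
  if (nrow(x) == 0L) stop("cannot summarise an empty cohort")
  vapply(MATCH_VARS, function(v) stats::median(as.numeric(x[[v]])),
         numeric(1))
}
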