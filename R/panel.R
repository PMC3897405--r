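# Nomogram probability panels: per-patient PFS probabilities at the fixed
# horizons 0, 2, 5, 7 years. The nomogram itself is external; its output
# tables are first-class inputs here.

PANEL_HORIZONS <- c(0, 2, 5, 7)

#' Construct a nomogram probability panel
#'
#' A panel holds, for each case, the nomogram-predicted probabilities of
#' progression-free survival at years 2, 5 and 7 after prostatectomy. The
#' probability at year 0 is 1 by definition and is stored explicitly.
#'
#' @param tables data.frame with columns `case_id`, `p2`, `p5`, `p7`
#'   (probabilities in \[0, 1\]); an optional `p0` column must equal 1.
#' @return A `probability_panel` (data.frame `case_id`, `p0`, `p2`, `p5`, `p7`).
#' @export
probability_panel <- function(tables) {
  if (!is.data.frame(tables)) stop("`tables` must be a data.frame")
  need <- c("case_id", "p2", "p5", "p7")
  missing_cols <- setdiff(need, names(tables))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(case_id = as.character(tables$case_id),
                    p0 = if ("p0" %in% names(tables)) as.numeric(tables$p0) else 1,
                    p2 = as.numeric(tables$p2),
                    p5 = as.numeric(tables$p5),
                    p7 = as.numeric(tables$p7),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("panel must contain at least one case")
  if (anyDuplicated(out$case_id)) stop("duplicated case_id in panel")
  bad <- !stats::complete.cases(out[, c("p2", "p5", "p7")]) |
    out$p2 < 0 | out$p2 > 1 | out$p5 < 0 | out$p5 > 1 |
    out$p7 < 0 | out$p7 > 1
  if (any(bad)) {
    stop("probabilities outside [0, 1] for case_id: ",
         paste(out$case_id[bad], collapse = ", "))
  }
  if (any(out$p0 != 1)) {
    stop("probability at year 0 must equal 1 for case_id: ",
         paste(out$case_id[out$p0 != 1], collapse = ", "))
  }
  rownames(out) <- NULL
  class(out) <- c("probability_panel", "data.frame")
  out
}

#' @export
as.data.frame.probability_panel <- function(x, ...) {
  class(x) <- "data.frame"
  x
}

#' @export
print.probability_panel <- function(x, ...) {
  cat(sprintf("Nomogram probability panel: %d cases at years %s\n",
              nrow(x), paste(PANEL_HORIZONS, collapse = "/")))
  cat(sprintf("  median P(PFS): %.2f at 2y, %.2f at 5y, %.2f at 7y\n",
              median(x$p2), median(x$p5), median(x$p7)))
  invisible(x)
}

#' Read a probability panel from CSV
#'
#' Expects columns `case_id`, `p2`, `p5`, `p7`; the year-0 probability is
#' implied and set to 1. Rows with probabilities outside \[0, 1\] are errors.
#'
#' @param path CSV file path.
#' @return A `probability_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  probability_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a probability panel to CSV (round-trip safe)
#'
#' @param x A `probability_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "probability_panel"))
  utils::write.csv(as.data.frame(x)[, c("case_id", "p2", "p5", "p7")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Repair non-monotone probability tables
#'
#' A survival function is non-increasing; rounding of nomogram output can
#' produce tables that are not. This repairs each table by antitonic
#' pool-adjacent-violators regression on its four points (equal weights),
#' which pools each violating block to its mean and leaves already-monotone
#' tables unchanged. Idempotent.
#'
#' @param x A `probability_panel`, or a numeric vector of four probabilities
#'   at years 0/2/5/7.
#' @return Object of the same type with non-increasing probabilities.
#' @export
enforce_monotone <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 4L)
    return(pav_antitonic(x))
  }
  stopifnot(inherits(x, "probability_panel"))
  for (i in seq_len(nrow(x))) {
    p <- pav_antitonic(as.numeric(x[i, c("p0", "p2", "p5", "p7")]))
    x$p0[i] <- p[1]; x$p2[i] <- p[2]; x$p5[i] <- p[3]; x$p7[i] <- p[4]
  }
  x
}

# antitonic PAV = isotonic regression on the reversed sequence
pav_antitonic <- function(p) {
  if (all(diff(p) <= 0)) return(p)
  rev(stats::isoreg(seq_along(p), rev(p))$yf)
}
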