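# Reference case sets: for each of the eight models, the prefix of ranked
# training cases whose observed PFS agrees best (minimum logrank chi-square)
# with the model's virtual PFS times. The eight sets together form a
# reference library that later tells which model fits which kind of cohort.

#' Scan order of training cases for one model
#'
#' Class-1 models (q <= 0.75) fit moderate-risk patients: their scan starts
#' from the long-PFS end, so cases are ranked by descending observed PFS.
#' Class-2 models (q >= 0.80) fit high-risk patients: cases are ranked by
#' ascending observed PFS. Ties are broken by case_id (lexicographic).
#'
#' @param x A `cohort`.
#' @param q Model threshold in [model_grid()].
#' @return Character vector of case ids in scan order.
#' @export
scan_order <- function(x, q) {
  stopifnot(inherits(x, "cohort"))
  cls <- model_class(q)
  ord <- if (cls == 1L) {
    order(-x$pfs_time, x$case_id, method = "radix")
  } else {
    order(x$pfs_time, x$case_id, method = "radix")
  }
  x$case_id[ord]
}

#' Build the reference case set for one model
#'
#' Ranks the training cases per [scan_order()], computes each case's virtual
#' PFS time once, then scans prefixes from `seed_size` cases up to the whole
#' cohort. For each prefix the logrank chi-square between the observed and
#' the virtual survival samples is recorded; the prefix attaining the minimum
#' chi-square (the earliest such prefix on ties) becomes the reference set.
#' Prefixes in which either sample has no events (undefined or degenerate
#' statistic) are skipped and flagged in the scan trace.
#'
#' @param x Training `cohort`.
#' @param panel Aligned `probability_panel`.
#' @param q Model threshold in [model_grid()].
#' @param seed_size Starting prefix size (default 30).
#' @param method,horizon_cap Curve-fit settings, see [fit_curve()].
#' @return A `reference_set`: list with `q`, `model_class`, `member_ids`,
#'   `medians` (eight matching-variable medians over members),
#'   `min_chi_square`, and `scan_trace` (data.frame `size`, `chi_square`,
#'   `skipped`).
#' @export
build_reference_set <- function(x, panel, q, seed_size = 30,
                                method = "monotone-cubic", horizon_cap = 15) {
  stopifnot(inherits(x, "cohort"))
  q <- check_model_q(q)
  check_alignment(x, panel)
  n <- nrow(x)
  if (n < seed_size) {
    stop("cohort size (", n, ") is below seed_size (", seed_size, ")")
  }
  ids <- scan_order(x, q)
  virt <- virtualize_cohort(panel, q, method = method,
                            horizon_cap = horizon_cap)
  vt <- virt$time[match(ids, virt$case_id)]
  vo <- virt$observed[match(ids, virt$case_id)]
  ot <- x$pfs_time[match(ids, x$case_id)]
  oe <- x$event[match(ids, x$case_id)]

  sizes <- seq.int(seed_size, n)
  chis <- rep(NA_real_, length(sizes))
  skipped <- logical(length(sizes))
  for (k in seq_along(sizes)) {
    j <- sizes[k]
    if (sum(oe[1:j]) == 0L || sum(vo[1:j]) == 0L) {
      skipped[k] <- TRUE
      next
    }
    chis[k] <- logrank_test(surv_sample(ot[1:j], oe[1:j]),
                            surv_sample(vt[1:j], vo[1:j]))$chi_square
  }
  if (all(skipped)) {
    stop("all prefixes skipped for model q = ", q,
         ": no events in observed or virtual samples")
  }
  best <- which.min(replace(chis, skipped, Inf))  # earliest minimum
  members <- ids[seq_len(sizes[best])]
  structure(list(q = q,
                 model_class = model_class(q),
                 member_ids = members,
                 medians = cohort_medians(x[match(members, x$case_id), ]),
                 min_chi_square = chis[best],
                 scan_trace = data.frame(size = sizes, chi_square = chis,
                                         skipped = skipped)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set for model.%02.0f (class %d): %d members, min chi-square %.4g\n",
              100 * x$q, x$model_class, length(x$member_ids),
              x$min_chi_square))
  invisible(x)
}

#' Train the reference library: eight reference sets, one per model
#'
#' Builds [build_reference_set()] for every q in [model_grid()] and records,
#' alongside the sets, the training-pool min/max range of each matching
#' variable (used later to normalise scales in the distance step) and a
#' provenance block. Deterministic given its inputs.
#'
#' @inheritParams build_reference_set
#' @return A `reference_library`: list with `models` (named by
#'   `sprintf("%.2f", q)`), `ranges`, `provenance`.
#' @export
build_reference_library <- function(x, panel, seed_size = 30,
                                    method = "monotone-cubic",
                                    horizon_cap = 15) {
  stopifnot(inherits(x, "cohort"))
  check_alignment(x, panel)
  models <- lapply(MODEL_GRID, function(q) {
    tryCatch(build_reference_set(x, panel, q, seed_size = seed_size,
                                 method = method, horizon_cap = horizon_cap),
             error = function(e) stop("model q = ", q, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(models) <- sprintf("%.2f", MODEL_GRID)
  ranges <- lapply(setNames(MATCH_VARS, MATCH_VARS), function(v) {
    range(as.numeric(x[[v]]))
  })
  structure(list(models = models,
                 ranges = ranges,
                 provenance = list(training_label = attr(x, "label"),
                                   n_training = nrow(x),
                                   method = method,
                                   horizon_cap = horizon_cap,
                                   seed_size = seed_size)),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("Reference library trained on '%s' (n = %d; %s, cap %g y, seed %d)\n",
              x$provenance$training_label, x$provenance$n_training,
              x$provenance$method, x$provenance$horizon_cap,
              x$provenance$seed_size))
  for (m in x$models) {
    cat(sprintf("  model.%02.0f: %3d members, min chi-square %8.4g\n",
                100 * m$q, length(m$member_ids), m$min_chi_square))
  }
  invisible(x)
}

#' Serialise a reference library to JSON
#'
#' @param library A `reference_library`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "reference_library"))
  payload <- list(
    provenance = library$provenance,
    ranges = library$ranges,
    models = lapply(unname(library$models), function(m) {
      list(q = m$q, model_class = m$model_class,
           member_ids = m$member_ids,
           medians = as.list(m$medians),
           min_chi_square = m$min_chi_square,
           scan_trace = list(size = m$scan_trace$size,
                             chi_square = m$scan_trace$chi_square,
                             skipped = m$scan_trace$skipped))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a reference library from JSON
#'
#' @param path JSON file written by [write_library()].
#' @return A `reference_library`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_len(nrow(raw$models)), function(i) {
    m <- raw$models[i, ]
    st <- m$scan_trace
    structure(list(q = m$q, model_class = as.integer(m$model_class),
                   member_ids = m$member_ids[[1]],
                   medians = unlist(m$medians[1, , drop = TRUE])[MATCH_VARS],
                   min_chi_square = m$min_chi_square,
                   scan_trace = data.frame(
                     size = st$size[[1]],
                     chi_square = as.numeric(st$chi_square[[1]]),
                     skipped = st$skipped[[1]])),
              class = "reference_set")
  })
  names(models) <- sprintf("%.2f", vapply(models, `[[`, numeric(1), "q"))
  if (!identical(names(models), sprintf("%.2f", MODEL_GRID))) {
    stop("reference library must contain exactly the 8 models q = ",
         paste(sprintf("%.2f", MODEL_GRID), collapse = ", "))
  }
  ranges <- lapply(raw$ranges, as.numeric)[MATCH_VARS]
  structure(list(models = models, ranges = ranges,
                 provenance = as.list(raw$provenance)),
            class = "reference_library")
}

# cohort and panel must cover exactly the same case ids
check_alignment <- function(x, panel) {
  stopifnot(inherits(panel, "probability_panel"))
  orphans_p <- setdiff(panel$case_id, x$case_id)
  orphans_c <- setdiff(x$case_id, panel$case_id)
  if (length(orphans_p) || length(orphans_c)) {
    stop("cohort and probability panel are misaligned; orphan case ids: ",
         paste(c(orphans_p, orphans_c), collapse = ", "))
  }
  invisible(TRUE)
}
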