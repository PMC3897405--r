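# Model selection for a trial cohort: weighted Euclidean distance between
# the trial's clinical-median vector and each reference set's median vector.

#' Default matching weights
#'
#' Continuous variables carry more weight than binary ones: 17% each for age,
#' tumor stage, Gleason primary, Gleason secondary and pre-op PSA; 5% each
#' for margin status, seminal vesicle invasion and lymph node status (in
#' [match_vars()] order: 17, 5, 17, 17, 17, 17, 5, 5).
#'
#' @return Named numeric vector of length 8 summing to 1.
#' @export
default_weights <- function() {
  setNames(c(0.17, 0.05, 0.17, 0.17, 0.17, 0.17, 0.05, 0.05), MATCH_VARS)
}

check_weights <- function(w) {
  if (length(w) != 8L) stop("weight vector must have exactly 8 entries")
  if (is.null(names(w))) names(w) <- MATCH_VARS
  if (!setequal(names(w), MATCH_VARS)) {
    stop("weights must be named by the matching variables: ",
         paste(MATCH_VARS, collapse = ", "))
  }
  w <- w[MATCH_VARS]
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  w
}

#' Normalise a clinical median vector to training-pool scale
#'
#' Continuous variables (age, stage, Gleason primary/secondary, PSA) are
#' min-max scaled by the training-pool ranges and clipped to \[0, 1\];
#' binary variables pass through unchanged (their medians already lie in
#' \[0, 1\]). A degenerate range (max = min) passes that variable through
#' with a warning.
#'
#' @param medians Named 8-vector from [cohort_medians()].
#' @param ranges Named list of `c(min, max)` per variable (as stored in a
#'   [build_reference_library()] result).
#' @return Named numeric 8-vector in \[0, 1\] (continuous entries).
#' @export
normalize_medians <- function(medians, ranges) {
  out <- medians[MATCH_VARS]
  for (v in MATCH_CONTINUOUS) {
    r <- as.numeric(ranges[[v]])
    if (length(r) != 2L || !all(is.finite(r))) {
      stop("invalid range for variable ", v)
    }
    if (r[2] <= r[1]) {
      warning("degenerate training range for ", v,
              "; passing it through unscaled", call. = FALSE)
      next
    }
    out[v] <- min(1, max(0, (out[v] - r[1]) / (r[2] - r[1])))
  }
  out
}

#' Weighted Euclidean distance between two clinical median vectors
#'
#' D = sqrt( sum_i w_i (T_i - R_i)^2 ) over the eight matching variables,
#' where T is the trial median vector and R a reference set's.
#'
#' @param trial,ref Aligned numeric 8-vectors.
#' @param w Weight vector (default [default_weights()]).
#' @return Non-negative scalar.
#' @export
weighted_distance <- function(trial, ref, w = default_weights()) {
  if (length(trial) != 8L || length(ref) != 8L) {
    stop("median vectors must have exactly 8 entries")
  }
  w <- check_weights(w)
  if (!is.null(names(trial))) trial <- trial[MATCH_VARS]
  if (!is.null(names(ref))) ref <- ref[MATCH_VARS]
  sqrt(sum(w * (as.numeric(trial) - as.numeric(ref))^2))
}

#' Select the model for a trial cohort
#'
#' Computes the weighted Euclidean distance between the trial cohort's
#' clinical medians and each of the eight reference sets' medians (both
#' normalised to the training-pool scale unless `normalize = FALSE`) and
#' selects the model at minimum distance; exact ties resolve toward the
#' smaller q (the more lenient model, whose longer virtual times are the
#' conservative choice when declaring a therapy benefit).
#'
#' @param x Trial `cohort`.
#' @param library A `reference_library`.
#' @param w Weight vector (default [default_weights()]).
#' @param normalize Min-max scale continuous variables by the training-pool
#'   ranges before the distance (default `TRUE`); disable for raw-scale
#'   replication.
#' @return A `distance_profile`: list with `distances` (data.frame `q`,
#'   `distance`), `selected_q`, `weights`, `normalized`, `trial_medians`.
#' @export
select_model <- function(x, library, w = default_weights(),
                         normalize = TRUE) {
  stopifnot(inherits(x, "cohort"), inherits(library, "reference_library"))
  w <- check_weights(w)
  trial_med <- cohort_medians(x)
  trial_vec <- if (normalize) normalize_medians(trial_med, library$ranges)
               else trial_med
  dists <- vapply(library$models, function(m) {
    ref_vec <- if (normalize) normalize_medians(m$medians, library$ranges)
               else m$medians
    weighted_distance(trial_vec, ref_vec, w)
  }, numeric(1))
  qs <- vapply(library$models, `[[`, numeric(1), "q")
  sel <- qs[which.min(dists)]  # qs ascending, so first minimum = smallest q
  structure(list(distances = data.frame(q = unname(qs),
                                        distance = unname(dists)),
                 selected_q = unname(sel),
                 weights = w,
                 normalized = normalize,
                 trial_medians = trial_med),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("Model selection (weighted Euclidean distance, %s scales):\n",
              if (x$normalized) "normalised" else "raw"))
  for (i in seq_len(nrow(x$distances))) {
    cat(sprintf("  model.%02.0f  D = %.4f%s\n", 100 * x$distances$q[i],
                x$distances$distance[i],
                if (x$distances$q[i] == x$selected_q) "  <- selected" else ""))
  }
  invisible(x)
}
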