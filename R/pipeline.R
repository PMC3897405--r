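# End-to-end orchestration: train the reference library, select the model
# for a trial cohort, generate its virtual control arm, and compare observed
# with virtual PFS by the logrank test.

#' Evaluate a single-arm trial against its virtual control arm
#'
#' Selects the model for the trial cohort by weighted distance against the
#' reference library, converts each patient's probability table to a virtual
#' PFS time under the selected model (using the library's curve-fit
#' settings), and compares the observed with the virtual survival sample by
#' the logrank test. Virtual observations whose curve never reaches the
#' threshold are censored at the horizon cap. A Rubinstein power block is
#' included only when explicit survival proportions are supplied via
#' `power_surv` (they are read off Kaplan-Meier curves by the analyst, not
#' inferred).
#'
#' @param x Trial `cohort`.
#' @param panel Aligned `probability_panel`.
#' @param library A `reference_library`.
#' @param w Matching weights (default [default_weights()]).
#' @param normalize Normalise scales in the distance step (default `TRUE`).
#' @param power_surv Optional `c(surv_observed, surv_virtual)` proportions at
#'   `power_tau` years for the power block.
#' @param power_tau,power_alpha Power-block horizon (years) and two-sided
#'   alpha.
#' @return A `trial_report`: list with `profile` (distance profile),
#'   `selected_q`, `virtual_arm`, `observed_arm`, `km_observed`,
#'   `km_virtual`, `logrank`, `power` (or `NULL`), `provenance`.
#' @export
evaluate_trial <- function(x, panel, library, w = default_weights(),
                           normalize = TRUE, power_surv = NULL,
                           power_tau = 10, power_alpha = 0.05) {
  stopifnot(inherits(x, "cohort"), inherits(library, "reference_library"))
  check_alignment(x, panel)
  profile <- select_model(x, library, w = w, normalize = normalize)
  q <- profile$selected_q
  prov <- library$provenance
  virt <- virtualize_cohort(panel, q, method = prov$method,
                            horizon_cap = prov$horizon_cap)
  observed <- surv_sample(x$pfs_time, x$event)
  virtual <- surv_sample(virt$time, virt$observed)
  lr <- logrank_test(observed, virtual)
  power <- NULL
  if (!is.null(power_surv)) {
    stopifnot(length(power_surv) == 2L)
    power <- list(surv_observed = power_surv[1], surv_virtual = power_surv[2],
                  n_observed = nrow(x), n_virtual = nrow(virt),
                  tau = power_tau, alpha = power_alpha,
                  power = rubinstein_power(power_surv[1], power_surv[2],
                                           nrow(x), nrow(virt),
                                           alpha = power_alpha,
                                           tau = power_tau))
  }
  structure(list(trial_label = attr(x, "label"),
                 profile = profile,
                 selected_q = q,
                 observed_arm = data.frame(case_id = x$case_id,
                                           time = x$pfs_time,
                                           event = x$event,
                                           stringsAsFactors = FALSE),
                 virtual_arm = virt,
                 km_observed = km_estimate(observed),
                 km_virtual = km_estimate(virtual),
                 logrank = lr,
                 power = power,
                 provenance = prov),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("Single-arm trial '%s' vs virtual control arm (n = %d)\n",
              x$trial_label, nrow(x$observed_arm)))
  cat(sprintf("  selected model.%02.0f (weighted distance %.4f)\n",
              100 * x$selected_q,
              min(x$profile$distances$distance)))
  print(x$logrank)
  if (!is.null(x$power)) {
    cat(sprintf("  Rubinstein power: %.1f%% (S_obs = %.2f vs S_virt = %.2f at %g y, alpha = %g)\n",
                100 * x$power$power, x$power$surv_observed,
                x$power$surv_virtual, x$power$tau, x$power$alpha))
  }
  invisible(x)
}

#' Train a reference library from CSV inputs and write it to JSON
#'
#' @param patients_csv Training patients CSV (see [read_cohort()]).
#' @param probs_csv Training probability-panel CSV (see [read_panel()]).
#' @param out Output JSON path for the library.
#' @param schema,label Passed to [read_cohort()].
#' @param seed_size,method,horizon_cap Passed to
#'   [build_reference_library()].
#' @return The `reference_library`, invisibly; the JSON file is the primary
#'   output.
#' @export
run_training <- function(patients_csv, probs_csv, out, schema = NULL,
                         label = NULL, seed_size = 30,
                         method = "monotone-cubic", horizon_cap = 15) {
  coh <- read_cohort(patients_csv, schema = schema, label = label)
  panel <- read_panel(probs_csv)
  lib <- build_reference_library(coh, panel, seed_size = seed_size,
                                 method = method, horizon_cap = horizon_cap)
  write_library(lib, out)
  invisible(lib)
}

#' Run a single-arm trial comparison from CSV inputs and write the report
#'
#' Writes the trial report as JSON (`<out_prefix>_report.json`) and the two
#' Kaplan-Meier curves as CSV (`<out_prefix>_km_observed.csv`,
#' `<out_prefix>_km_virtual.csv`).
#'
#' @param patients_csv,probs_csv Trial cohort inputs.
#' @param library_file Reference-library JSON from [run_training()].
#' @param out_prefix Path prefix for the outputs.
#' @param schema,label Passed to [read_cohort()].
#' @param w,normalize,power_surv,power_tau,power_alpha Passed to
#'   [evaluate_trial()].
#' @return The `trial_report`, invisibly.
#' @export
run_trial <- function(patients_csv, probs_csv, library_file, out_prefix,
                      schema = NULL, label = NULL, w = default_weights(),
                      normalize = TRUE, power_surv = NULL, power_tau = 10,
                      power_alpha = 0.05) {
  coh <- read_cohort(patients_csv, schema = schema, label = label)
  panel <- read_panel(probs_csv)
  lib <- read_library(library_file)
  report <- evaluate_trial(coh, panel, lib, w = w, normalize = normalize,
                           power_surv = power_surv, power_tau = power_tau,
                           power_alpha = power_alpha)
  write_trial_report(report, paste0(out_prefix, "_report.json"))
  write_km_curve(report$km_observed, paste0(out_prefix, "_km_observed.csv"))
  write_km_curve(report$km_virtual, paste0(out_prefix, "_km_virtual.csv"))
  invisible(report)
}

#' Serialise a trial report to JSON
#'
#' Both survival arms are stored in full, so the logrank result can be
#' recomputed from the file.
#'
#' @param report A `trial_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_trial_report <- function(report, path) {
  stopifnot(inherits(report, "trial_report"))
  payload <- list(
    trial_label = report$trial_label,
    selected_q = report$selected_q,
    distances = list(q = report$profile$distances$q,
                     distance = report$profile$distances$distance),
    weights = as.list(report$profile$weights),
    normalized = report$profile$normalized,
    trial_medians = as.list(report$profile$trial_medians),
    observed_arm = list(case_id = report$observed_arm$case_id,
                        time = report$observed_arm$time,
                        event = report$observed_arm$event),
    virtual_arm = list(case_id = report$virtual_arm$case_id,
                       time = report$virtual_arm$time,
                       observed = report$virtual_arm$observed),
    logrank = list(chi_square = report$logrank$chi_square,
                   p_value = report$logrank$p_value,
                   df = report$logrank$df,
                   significant = report$logrank$significant),
    power = report$power,
    provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a trial report from JSON
#'
#' Restores the stored arms and recomputes the Kaplan-Meier curves and the
#' logrank result from them (the stored logrank block is kept alongside for
#' comparison).
#'
#' @param path JSON file written by [write_trial_report()].
#' @return A `trial_report`.
#' @export
read_trial_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  observed <- data.frame(case_id = raw$observed_arm$case_id,
                         time = raw$observed_arm$time,
                         event = as.integer(raw$observed_arm$event),
                         stringsAsFactors = FALSE)
  virtual <- data.frame(case_id = raw$virtual_arm$case_id,
                        model_q = raw$selected_q,
                        time = raw$virtual_arm$time,
                        observed = as.integer(raw$virtual_arm$observed),
                        stringsAsFactors = FALSE)
  obs_s <- surv_sample(observed$time, observed$event)
  vir_s <- surv_sample(virtual$time, virtual$observed)
  profile <- structure(list(distances = data.frame(q = raw$distances$q,
                                                   distance = raw$distances$distance),
                            selected_q = raw$selected_q,
                            weights = unlist(raw$weights)[MATCH_VARS],
                            normalized = raw$normalized,
                            trial_medians = unlist(raw$trial_medians)[MATCH_VARS]),
                       class = "distance_profile")
  structure(list(trial_label = raw$trial_label,
                 profile = profile,
                 selected_q = raw$selected_q,
                 observed_arm = observed,
                 virtual_arm = virtual,
                 km_observed = km_estimate(obs_s),
                 km_virtual = km_estimate(vir_s),
                 logrank = logrank_test(obs_s, vir_s),
                 stored_logrank = raw$logrank,
                 power = raw$power,
                 provenance = as.list(raw$provenance)),
            class = "trial_report")
}
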