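# Survival comparison machinery: Kaplan-Meier summaries, the two-sample
# logrank (Mantel-Haenszel) test that drives every decision in the method,
# the Wilcoxon rank-sum fallback for censoring-free data, and the simplified
# Rubinstein power formula.

#' Construct a survival sample
#'
#' @param time Positive times in years.
#' @param event 0/1 event indicators aligned with `time` (1 = progression
#'   observed, 0 = censored).
#' @return A `surv_sample` data.frame.
#' @export
surv_sample <- function(time, event) {
  if (length(time) == 0L) stop("survival sample must be non-empty")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            class = c("surv_sample", "data.frame"))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate with ties handled by simultaneous decrement;
#' censored observations at an event time are counted at risk at that time
#' and leave the risk set after it.
#'
#' @param sample A `surv_sample` (or anything coercible via [surv_sample()]).
#' @return A `km_curve`: data.frame `time`, `at_risk`, `n_event`, `surv` over
#'   the distinct observed times.
#' @export
km_estimate <- function(sample) {
  sample <- as_surv_sample(sample)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sample,
                           conf.type = "none")
  structure(data.frame(time = fit$time, at_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            n = nrow(sample), class = c("km_curve", "data.frame"))
}

as_surv_sample <- function(x) {
  if (inherits(x, "surv_sample")) return(x)
  if (is.data.frame(x) && all(c("time", "event") %in% names(x))) {
    return(surv_sample(x$time, x$event))
  }
  stop("expected a surv_sample or a data.frame with columns time, event")
}

#' @export
print.km_curve <- function(x, ...) {
  ev <- x[x$n_event > 0, , drop = FALSE]
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, S(last event) = %.3f\n",
              attr(x, "n"), nrow(ev),
              if (nrow(ev)) ev$surv[nrow(ev)] else 1))
  invisible(x)
}

#' Write a Kaplan-Meier curve to CSV
#'
#' @param x A `km_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(x, path) {
  stopifnot(inherits(x, "km_curve"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-sample logrank (Mantel-Haenszel) test
#'
#' Over the distinct event times, accumulates observed minus expected events
#' in the first group with the hypergeometric variance;
#' chi-square = (sum O - sum E)^2 / sum V on 1 degree of freedom, with the
#' two-sided p-value from the upper chi-square tail. A chi-square above the
#' 95th percentile of chi-square(1) — 3.84 — flags significant disagreement
#' between the two survival curves.
#'
#' @param a,b `surv_sample`s (or data.frames with `time`, `event`).
#' @return A `logrank_result`: list with `chi_square`, `p_value`, `df` (1),
#'   `significant` (chi_square above the 3.84 cutoff).
#' @export
logrank_test <- function(a, b) {
  a <- as_surv_sample(a); b <- as_surv_sample(b)
  if (sum(a$event) + sum(b$event) == 0L) {
    stop("logrank statistic undefined: no events in either group")
  }
  dat <- data.frame(time = c(a$time, b$time), event = c(a$event, b$event),
                    group = rep(c("a", "b"), c(nrow(a), nrow(b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat,
                           rho = 0)
  chi <- unname(sd$chisq)
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 df = 1L,
                 significant = chi > CHISQ_CUTOFF),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Logrank test: chi-square = %.4g (df = 1), p = %.4g -> %s\n",
              x$chi_square, x$p_value,
              if (x$significant) "curves differ (chi-square > 3.84)"
              else "no significant difference (chi-square <= 3.84)"))
  invisible(x)
}

#' Wilcoxon rank-sum test for censoring-free survival samples
#'
#' When no observation is censored the survival comparison reduces to a
#' two-sample location test on the raw times; any censored observation is an
#' error directing the caller to [logrank_test()]. Exact p-values are used
#' when both groups have at most 10 observations (and no ties), the normal
#' approximation otherwise.
#'
#' @param a,b `surv_sample`s with all events observed.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to group `a`.
#' @return List with `rank_sum` (rank sum of group a), `u_stat`
#'   (Mann-Whitney U of group a) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  a <- as_surv_sample(a); b <- as_surv_sample(b)
  if (any(a$event == 0L) || any(b$event == 0L)) {
    stop("censored observations present; use logrank_test() instead")
  }
  exact <- nrow(a) <= 10L && nrow(b) <= 10L
  wt <- suppressWarnings(
    stats::wilcox.test(a$time, b$time, alternative = alternative,
                       exact = exact))
  ranks <- rank(c(a$time, b$time))
  list(rank_sum = sum(ranks[seq_len(nrow(a))]),
       u_stat = unname(wt$statistic),
       p_value = wt$p.value)
}

#' Simplified Rubinstein power for a logrank comparison
#'
#' Closed-form power for detecting a survival difference given the survival
#' proportions in the two arms at the horizon of interest: the hazard ratio
#' under proportional hazards is HR = log(surv_b) / log(surv_a), the expected
#' number of events under complete follow-up is
#' d = n_a (1 - surv_a) + n_b (1 - surv_b), and
#' power = Phi(sqrt(d) |log HR| / 2 - z_{1 - alpha/2}).
#'
#' @param surv_a,surv_b Survival proportions in (0, 1) at the horizon.
#' @param n_a,n_b Arm sizes.
#' @param alpha Two-sided significance level (default 0.05).
#' @param tau Horizon in years at which `surv_a`, `surv_b` are read
#'   (descriptive; under complete follow-up it does not enter the formula).
#' @param d Optional override of the expected event count.
#' @return Power in \[0, 1\].
#' @export
rubinstein_power <- function(surv_a, surv_b, n_a, n_b, alpha = 0.05,
                             tau = 10, d = NULL) {
  stopifnot(n_a >= 1, n_b >= 1, alpha > 0, alpha < 1)
  if (surv_a <= 0 || surv_a >= 1 || surv_b <= 0 || surv_b >= 1) {
    stop("survival proportions must lie strictly inside (0, 1)")
  }
  hr <- log(surv_b) / log(surv_a)
  if (is.null(d)) d <- n_a * (1 - surv_a) + n_b * (1 - surv_b)
  stats::pnorm(sqrt(d) * abs(log(hr)) / 2 - stats::qnorm(1 - alpha / 2))
}
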