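# Per-patient survival curve fitting and threshold inversion: the
# probability-to-time conversion at the core of the virtual-control method.
# A fitted curve S(t) passes through (or smooths) the four nomogram points
# at years 0/2/5/7 and is inverted to "time to q% chance of PFS".

CURVE_METHODS <- c("monotone-cubic", "linear", "loess")

#' Fit a monotone survival curve through a 4-point probability table
#'
#' Fits S(t) through the nomogram probabilities at years 0, 2, 5 and 7.
#' `"monotone-cubic"` (default) is monotone piecewise-cubic Hermite
#' interpolation (Fritsch–Carlson tangents); `"linear"` is piecewise-linear
#' interpolation, which doubles as a closed-form oracle; `"loess"` is a
#' locally-weighted linear smoother evaluated on a fine grid and then
#' projected onto the monotone cone (clamped to \[0, 1\], S(0) forced to 1),
#' so it smooths rather than interpolates. Beyond year 7 every method
#' extrapolates at the constant exponential hazard implied by the last
#' segment, h = log(S(5)/S(7))/2, up to `horizon_cap`.
#'
#' @param probs Numeric vector of four non-increasing probabilities at years
#'   0/2/5/7 (apply [enforce_monotone()] first if needed), with `probs[1] == 1`.
#' @param method One of `"monotone-cubic"`, `"linear"`, `"loess"`.
#' @param horizon_cap Maximum extrapolation time in years (>= 7); crossings
#'   beyond it are censored at the cap.
#' @param case_id Optional case label carried on the curve.
#' @return A `survival_curve`: evaluate it with [curve_eval()], invert it
#'   with [time_to_threshold()].
#' @export
fit_curve <- function(probs, method = CURVE_METHODS, horizon_cap = 15,
                      case_id = NA_character_) {
  method <- match.arg(method)
  stopifnot(is.numeric(probs), length(probs) == 4L)
  if (horizon_cap < 7) stop("horizon_cap must be >= 7 years")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(probs[1] - 1) > 1e-12) stop("probability at year 0 must equal 1")
  if (any(diff(probs) > 1e-12)) {
    stop("probability table is not non-increasing; apply enforce_monotone() first")
  }
  knots <- data.frame(time = PANEL_HORIZONS, prob = probs)
  core <- switch(method,
    "linear" = stats::approxfun(knots$time, knots$prob, method = "linear",
                                rule = 2),
    "monotone-cubic" = stats::splinefun(knots$time, knots$prob,
                                        method = "monoH.FC"),
    "loess" = loess_monotone(knots)
  )
  # tail probabilities used for the exponential extrapolation
  s5 <- core(5); s7 <- core(7)
  tail_rate <- if (s5 <= 0 || s7 <= 0) Inf else max(0, log(s5 / s7) / 2)
  structure(list(case_id = case_id, method = method, knots = knots,
                 horizon_cap = horizon_cap, core = core, s7 = s7,
                 tail_rate = tail_rate),
            class = "survival_curve")
}

# loess on 4 points is a weighted linear smoother; evaluate on a 0.01-year
# grid, pin S(0) = 1, clamp to [0,1] and take the running minimum so the
# result is a valid survival function.
loess_monotone <- function(knots) {
  fit <- stats::loess(prob ~ time, data = knots, span = 1, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(0, 7, by = 0.01)
  vals <- pmin(1, pmax(0, stats::predict(fit, newdata = data.frame(time = grid))))
  vals[1] <- 1
  vals <- cummin(vals)
  stats::approxfun(grid, vals, method = "linear", rule = 2)
}

#' Evaluate a fitted survival curve
#'
#' @param curve A `survival_curve` from [fit_curve()].
#' @param t Times in years (>= 0); values beyond the horizon cap evaluate on
#'   the same extrapolation.
#' @return S(t), clamped to \[0, 1\] and non-increasing.
#' @export
curve_eval <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"), all(t >= 0))
  out <- numeric(length(t))
  inside <- t <= 7
  if (any(inside)) out[inside] <- pmin(1, pmax(0, curve$core(t[inside])))
  if (any(!inside)) {
    out[!inside] <- if (is.infinite(curve$tail_rate)) 0 else
      curve$s7 * exp(-curve$tail_rate * (t[!inside] - 7))
  }
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Fitted survival curve%s (%s): S(2)=%.3f S(5)=%.3f S(7)=%.3f, cap %g y\n",
              if (is.na(x$case_id)) "" else paste0(" for ", x$case_id),
              x$method, curve_eval(x, 2), curve_eval(x, 5), curve_eval(x, 7),
              x$horizon_cap))
  invisible(x)
}

#' Invert a survival curve: time to q% chance of PFS
#'
#' Finds the earliest time t with S(t) <= q by bisection (survival-scale
#' tolerance 1e-8 where S is strictly decreasing; flat segments at exactly q
#' resolve to their earliest time). If the curve never falls to q before the
#' horizon cap, the virtual observation is censored at the cap.
#'
#' @param curve A `survival_curve`.
#' @param q Survival threshold in [model_grid()].
#' @return One-row data.frame `case_id`, `model_q`, `time`, `observed`
#'   (`observed` = 0 means censored at the horizon cap).
#' @export
time_to_threshold <- function(curve, q) {
  stopifnot(inherits(curve, "survival_curve"))
  q <- check_model_q(q)
  stopifnot(length(q) == 1L)
  cap <- curve$horizon_cap
  if (curve_eval(curve, cap) > q) {
    return(data.frame(case_id = curve$case_id, model_q = q, time = cap,
                      observed = 0L, stringsAsFactors = FALSE))
  }
  lo <- 0; hi <- cap
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (curve_eval(curve, mid) <= q) hi <- mid else lo <- mid
  }
  data.frame(case_id = curve$case_id, model_q = q, time = hi, observed = 1L,
             stringsAsFactors = FALSE)
}

#' Virtual PFS times for a whole cohort under one model
#'
#' Repairs each table with [enforce_monotone()], fits a curve and inverts it
#' at threshold q. Deterministic given its inputs.
#'
#' @param panel A `probability_panel`.
#' @param q Model threshold in [model_grid()].
#' @param method Curve-fit method, see [fit_curve()].
#' @param horizon_cap Extrapolation cap in years.
#' @return data.frame `case_id`, `model_q`, `time`, `observed`, one row per
#'   case in panel order.
#' @export
virtualize_cohort <- function(panel, q, method = "monotone-cubic",
                              horizon_cap = 15) {
  stopifnot(inherits(panel, "probability_panel"))
  q <- check_model_q(q)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    probs <- pav_antitonic(as.numeric(panel[i, c("p0", "p2", "p5", "p7")]))
    crv <- tryCatch(
      fit_curve(probs, method = method, horizon_cap = horizon_cap,
                case_id = panel$case_id[i]),
      error = function(e) stop("case ", panel$case_id[i], ": ",
                               conditionMessage(e), call. = FALSE))
    time_to_threshold(crv, q)
  })
  do.call(rbind, rows)
}

#' Write virtual times to CSV
#'
#' @param x Output of [virtualize_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_virtual_times <- function(x, path) {
  utils::write.csv(
    data.frame(case_id = x$case_id, model_q = x$model_q,
               virtual_time_years = x$time, observed_flag = x$observed),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
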