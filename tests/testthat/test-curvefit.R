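test_that("interpolating fits reproduce knots and stay monotone in [0,1]", {
  probs <- c(1.0, 0.9, 0.8, 0.7)
  for (m in c("linear", "monotone-cubic")) {
    crv <- fit_curve(probs, method = m)
    expect_equal(curve_eval(crv, c(0, 2, 5, 7)), probs, tolerance = 1e-9)
    grid <- seq(0, 15, by = 0.01)
    vals <- curve_eval(crv, grid)
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(all(vals >= 0 & vals <= 1))
  }
  # constant table stays at 1 inside the observed window
  flat <- fit_curve(c(1, 1, 1, 1))
  expect_equal(curve_eval(flat, c(0, 3, 7)), c(1, 1, 1))
})

test_that("fit_curve validates its inputs", {
  expect_error(fit_curve(c(1, 0.9, 0.8, 0.7), method = "quadratic"))
  expect_error(fit_curve(c(1, 0.9, 0.8, 0.7), horizon_cap = 5), ">= 7")
  expect_error(fit_curve(c(1, 0.8, 0.9, 0.7)), "enforce_monotone")
  expect_error(fit_curve(c(0.99, 0.9, 0.8, 0.7)), "year 0")
})

test_that("loess smoothing yields a valid survival function", {
  crv <- fit_curve(c(1.0, 0.9, 0.8, 0.7), method = "loess")
  grid <- seq(0, 15, by = 0.01)
  vals <- curve_eval(crv, grid)
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("threshold inversion matches closed-form piecewise-linear crossings", {
  crv <- fit_curve(c(1.0, 0.9, 0.8, 0.7), method = "linear", case_id = "A")
  hit75 <- time_to_threshold(crv, 0.75)
  expect_equal(hit75$time, 6.0, tolerance = 1e-6)   # 5 + 2*(0.8-0.75)/0.1
  expect_equal(hit75$observed, 1L)
  hit95 <- time_to_threshold(crv, 0.95)
  expect_equal(hit95$time, 1.0, tolerance = 1e-6)   # 0.95 on S(t) = 1 - 0.05 t
  expect_equal(hit95$case_id, "A")

  flat <- fit_curve(c(1, 1, 1, 1), horizon_cap = 15)
  miss <- time_to_threshold(flat, 0.95)
  expect_equal(miss$time, 15)
  expect_equal(miss$observed, 0L)
})

test_that("random linear curves invert to the segment-algebra oracle", {
  set.seed(97)
  for (i in 1:300) {
    probs <- random_monotone_table()
    crv <- fit_curve(probs, method = "linear")
    for (q in sample(model_grid(), 3)) {
      expected <- linear_inversion_oracle(probs, q)
      got <- time_to_threshold(crv, q)
      if (is.na(expected)) {
        # not crossed by year 7: either the exponential tail reaches q before
        # the cap (observed, time > 7) or the draw is censored at the cap
        expect_true(got$time > 7 - 1e-9)
      } else {
        expect_equal(got$time, expected, tolerance = 1e-6)
        expect_equal(got$observed, 1L)
        # inversion residual at a strict crossing
        if (probs[which(c(0, 2, 5, 7) >= expected)[1] - 1] -
              probs[which(c(0, 2, 5, 7) >= expected)[1]] > 1e-6) {
          expect_lt(abs(curve_eval(crv, got$time) - q), 1e-6)
        }
      }
    }
  }
})

test_that("time to threshold is non-increasing in q (stringency monotonicity)", {
  set.seed(131)
  for (i in 1:1000) {
    probs <- random_monotone_table()
    crv <- fit_curve(probs, method = sample(c("linear", "monotone-cubic"), 1))
    times <- vapply(model_grid(),
                    function(q) time_to_threshold(crv, q)$time, numeric(1))
    expect_true(all(diff(times) <= 1e-9))  # q ascending => times non-increasing
  }
})

test_that("linear and monotone-cubic stay within each inter-knot range", {
  set.seed(61)
  knots_t <- c(0, 2, 5, 7)
  for (i in 1:50) {
    probs <- random_monotone_table()
    lin <- fit_curve(probs, method = "linear")
    cub <- fit_curve(probs, method = "monotone-cubic")
    expect_equal(curve_eval(cub, knots_t), curve_eval(lin, knots_t),
                 tolerance = 1e-9)
    for (seg in 1:3) {
      tt <- seq(knots_t[seg], knots_t[seg + 1], length.out = 25)
      for (vals in list(curve_eval(lin, tt), curve_eval(cub, tt))) {
        expect_true(all(vals <= probs[seg] + 1e-9 &
                          vals >= probs[seg + 1] - 1e-9))
      }
    }
  }
})

test_that("virtualize_cohort composes per-case fits deterministically", {
  panel <- probability_panel(data.frame(case_id = "A", p2 = 0.9, p5 = 0.8,
                                        p7 = 0.7))
  single <- virtualize_cohort(panel, 0.75, method = "linear")
  crv <- fit_curve(c(1, 0.9, 0.8, 0.7), method = "linear", case_id = "A")
  expect_equal(single, time_to_threshold(crv, 0.75))

  # non-monotone tables are repaired before fitting
  panel2 <- probability_panel(data.frame(case_id = "B", p2 = 0.8, p5 = 0.9,
                                         p7 = 0.7))
  expect_equal(virtualize_cohort(panel2, 0.75, method = "linear")$time,
               time_to_threshold(fit_curve(c(1, 0.85, 0.85, 0.7),
                                           method = "linear"), 0.75)$time)

  # more stringent thresholds are reached earlier, per case
  sim <- simulate_cohort(sim_config(n = 15, seed = 3))
  v60 <- virtualize_cohort(sim$panel, 0.60)
  v95 <- virtualize_cohort(sim$panel, 0.95)
  expect_true(all(v95$time <= v60$time + 1e-9))
})

test_that("4-point tables of an exponential law invert near the true quantile", {
  S <- function(t) exp(-0.1 * t)
  panel <- probability_panel(data.frame(case_id = "E", p2 = S(2), p5 = S(5),
                                        p7 = S(7)))
  got <- virtualize_cohort(panel, 0.60, method = "monotone-cubic")
  expect_equal(got$time, log(1 / 0.6) / 0.1, tolerance = 0.15)
  expect_equal(got$observed, 1L)
})
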