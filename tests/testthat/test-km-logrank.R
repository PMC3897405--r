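test_that("Kaplan-Meier matches product-limit hand calculations", {
  km <- km_estimate(surv_sample(1:4, rep(1, 4)))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))   # 1 - k/n without censoring
  expect_equal(km$at_risk, 4:1)

  km2 <- km_estimate(surv_sample(1:3, c(1, 0, 1)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)       # (2/3) * (1 - 1/1)

  km3 <- km_estimate(surv_sample(c(2, 4, 6), c(0, 0, 0)))
  expect_true(all(km3$surv == 1))
  expect_true(all(km3$n_event == 0))

  expect_error(km_estimate(surv_sample(numeric(0), integer(0))), "non-empty")
})

test_that("tied events decrement simultaneously; tied censorings stay at risk", {
  km <- km_estimate(surv_sample(c(1, 1, 2, 2, 2), c(1, 1, 1, 0, 0)))
  expect_equal(km$surv[km$time == 1], 3 / 5)
  expect_equal(km$surv[km$time == 2], 3 / 5 * 2 / 3)  # censored at 2 count at risk
})

test_that("logrank chi-square matches the hand-computed O/E/V fixture", {
  a <- surv_sample(c(1, 2), c(1, 1))
  b <- surv_sample(c(3, 4), c(1, 1))
  lr <- logrank_test(a, b)
  expect_equal(lr$chi_square, 49 / 17, tolerance = 1e-9)  # O=2, E=5/6, V=17/36
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
  expect_false(lr$significant)

  # label symmetry and the identical-sample null
  expect_equal(logrank_test(b, a)$chi_square, lr$chi_square)
  expect_equal(logrank_test(a, a)$chi_square, 0, tolerance = 1e-12)

  expect_error(logrank_test(surv_sample(1:2, c(0, 0)),
                            surv_sample(3:4, c(0, 0))), "no events")
})

test_that("logrank agrees with the independent O/E/V oracle on censored data", {
  set.seed(19)
  for (i in 1:25) {
    a <- surv_sample(round(rexp(7, 0.3), 2) + 0.01, rbinom(7, 1, 0.7))
    b <- surv_sample(round(rexp(8, 0.5), 2) + 0.01, rbinom(8, 1, 0.7))
    if (sum(a$event) + sum(b$event) == 0) next
    expect_equal(logrank_test(a, b)$chi_square,
                 oracle_logrank_chi(a$time, a$event, b$time, b$event),
                 tolerance = 1e-9)
  }
})

test_that("the 3.84 cutoff is the 5% point of chi-square with 1 df", {
  expect_equal(round(qchisq(0.95, 1), 2), 3.84)
  lr <- logrank_test(surv_sample(c(1, 2), c(1, 1)), surv_sample(c(3, 4), c(1, 1)))
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
})

test_that("chi-square p-value tracks the permutation null on small samples", {
  # tolerance covers Monte-Carlo error (3 se ~ 0.015 at B = 2000) plus the
  # df-1 asymptotic error of the logrank statistic at 6-8 cases per group
  set.seed(23)
  a <- surv_sample(c(1.1, 2.3, 3.2, 4.8, 6.1, 7.9), rep(1, 6))
  b <- surv_sample(c(2.0, 3.5, 4.1, 5.6, 8.2, 9.9), rep(1, 6))
  expect_lt(abs(logrank_test(a, b)$p_value - perm_logrank_p(a, b, B = 2000)),
            0.05)

  a8 <- surv_sample(c(0.8, 1.5, 2.2, 2.9, 3.7, 4.4, 5.2, 6.0), rep(1, 8))
  b8 <- surv_sample(c(1.2, 2.5, 3.3, 4.6, 5.8, 7.1, 8.4, 9.7), rep(1, 8))
  expect_lt(abs(logrank_test(a8, b8)$p_value -
                  perm_logrank_p(a8, b8, B = 2000)), 0.05)
})

test_that("Wilcoxon rank-sum fallback handles censoring-free samples only", {
  a <- surv_sample(c(1, 2), c(1, 1))
  b <- surv_sample(c(3, 4), c(1, 1))
  w <- wilcoxon_rank_sum(a, b, alternative = "less")
  expect_equal(w$rank_sum, 3)
  expect_equal(w$p_value, 1 / 6)   # 1 of the 6 equally likely assignments

  expect_equal(wilcoxon_rank_sum(a, a)$p_value, 1.0)
  expect_error(wilcoxon_rank_sum(surv_sample(c(1, 2), c(1, 0)), b),
               "logrank")
})

test_that("Rubinstein power follows its closed form and monotonicities", {
  # null limit: HR = 1 leaves only the alpha/2 tail
  expect_equal(rubinstein_power(0.5, 0.5, 20, 20), pnorm(qnorm(0.025)),
               tolerance = 1e-12)
  # normal-CDF oracle at d = 16, |log HR| = log(0.2)/log(0.8)
  hr <- log(0.2) / log(0.8)
  expect_equal(rubinstein_power(0.8, 0.2, 20, 20, d = 16),
               pnorm(sqrt(16) * abs(log(hr)) / 2 - qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(pnorm(1.993), 0.977, tolerance = 1e-3)

  expect_error(rubinstein_power(1, 0.5, 10, 10), "inside")
  expect_error(rubinstein_power(0.5, 0, 10, 10), "inside")

  # non-decreasing in the event count and in the effect size
  p_d <- vapply(c(5, 10, 20, 40), function(d)
    rubinstein_power(0.8, 0.4, 20, 20, d = d), numeric(1))
  expect_true(all(diff(p_d) >= 0))
  p_e <- vapply(c(0.7, 0.5, 0.3, 0.2), function(s)
    rubinstein_power(0.8, s, 20, 20), numeric(1))
  expect_true(all(diff(p_e) >= 0))
})
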