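# Shared fixtures and independent oracles, built in code at test time.

# small hand-written cohort (3 cases) for IO and median tests
toy_cohort_df <- function() {
  data.frame(
    case_id = c("A", "B", "C"),
    age = c(60, 70, 65),
    preop_psa = c(4, 20, 10),
    gleason_primary = c(3, 4, 3),
    gleason_secondary = c(4, 5, 3),
    stage_ord = c(2, 3, 3),
    margin_positive = c(0, 1, 1),
    svi = c(0, 1, 0),
    ln_positive = c(0, 1, 0),
    ece = c(0, 1, 1),
    surgery_year = c(1995, 2001, 1998),
    pfs_time = c(8.2, 1.4, 5.0),
    event = c(0, 1, 1),
    stringsAsFactors = FALSE
  )
}

# earliest time with S(t) <= q for the piecewise-linear curve through the
# 0/2/5/7 knots; closed-form segment algebra, independent of the package's
# bisection. NA if not crossed by year 7.
linear_inversion_oracle <- function(probs, q) {
  t <- c(0, 2, 5, 7)
  for (i in 1:3) {
    if (probs[i + 1] <= q) {
      return(t[i] + (t[i + 1] - t[i]) *
               (probs[i] - q) / (probs[i] - probs[i + 1]))
    }
  }
  NA_real_
}

# random valid monotone probability table (p0 = 1, non-increasing)
random_monotone_table <- function() {
  c(1, sort(stats::runif(3), decreasing = TRUE))
}

# independent logrank chi-square: direct observed/expected/hypergeometric
# accumulation over event times (censored at t are at risk at t)
oracle_logrank_chi <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(c(1L, 2L), c(length(ta), length(tb)))
  O <- E <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & grp == 1L)
    d <- sum(time == tt & event == 1)
    O <- O + sum(time == tt & event == 1 & grp == 1L)
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# permutation tail probability of the package's logrank statistic
perm_logrank_p <- function(a, b, B = 10000) {
  time <- c(a$time, b$time); event <- c(a$event, b$event)
  na <- nrow(a)
  obs <- logrank_test(a, b)$chi_square
  hits <- 0L
  for (i in seq_len(B)) {
    idx <- sample.int(length(time), na)
    chi <- logrank_test(surv_sample(time[idx], event[idx]),
                        surv_sample(time[-idx], event[-idx]))$chi_square
    if (chi >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# hand-built reference library (toy medians) for matching tests
toy_library <- function(medians_by_q, ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- list(age = c(50, 80), margin_positive = c(0, 1),
                   stage_ord = c(2, 4), gleason_primary = c(2, 5),
                   gleason_secondary = c(2, 5), preop_psa = c(1, 100),
                   svi = c(0, 1), ln_positive = c(0, 1))
  }
  models <- lapply(model_grid(), function(q) {
    structure(list(q = q, model_class = model_class(q),
                   member_ids = paste0("m", q),
                   medians = medians_by_q[[sprintf("%.2f", q)]],
                   min_chi_square = 0,
                   scan_trace = data.frame(size = 30L, chi_square = 0,
                                           skipped = FALSE)),
              class = "reference_set")
  })
  names(models) <- sprintf("%.2f", model_grid())
  structure(list(models = models, ranges = ranges,
                 provenance = list(training_label = "toy", n_training = 30L,
                                   method = "monotone-cubic",
                                   horizon_cap = 15, seed_size = 30L)),
            class = "reference_library")
}
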