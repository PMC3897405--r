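test_that("scan order runs long-to-short for class 1 and short-to-long for class 2", {
  df <- toy_cohort_df()           # times A=8.2, B=1.4, C=5.0
  coh <- cohort(df, "toy")
  expect_equal(scan_order(coh, 0.60), c("A", "C", "B"))
  expect_equal(scan_order(coh, 0.90), c("B", "C", "A"))

  df$pfs_time <- c(5, 5, 1)       # ties break by case_id
  coh2 <- cohort(df, "ties")
  expect_equal(scan_order(coh2, 0.60), c("A", "B", "C"))
  expect_equal(scan_order(coh2, 0.90), c("C", "A", "B"))
})

test_that("model classes split the grid at q = 0.75", {
  expect_equal(model_class(c(0.60, 0.65, 0.70, 0.75)), rep(1L, 4))
  expect_equal(model_class(c(0.80, 0.85, 0.90, 0.95)), rep(2L, 4))
  expect_error(model_class(0.50), "grid")
})

test_that("prefix scan equals exhaustive recomputation for all 8 models (N = 40)", {
  sim <- simulate_cohort(sim_config(n = 40, seed = 21), "train40")
  coh <- sim$cohort; panel <- sim$panel
  for (q in model_grid()) {
    rs <- build_reference_set(coh, panel, q, seed_size = 30)
    expect_equal(nrow(rs$scan_trace), 40 - 30 + 1)   # 11 evaluated prefixes

    # independent brute force: own ordering, per-prefix logrank, argmin
    cls <- if (q <= 0.75) 1L else 2L
    ord <- if (cls == 1L) order(-coh$pfs_time, coh$case_id) else
      order(coh$pfs_time, coh$case_id)
    ids <- coh$case_id[ord]
    virt <- virtualize_cohort(panel, q)
    chis <- sapply(30:40, function(j) {
      sel <- ids[1:j]
      o <- coh[match(sel, coh$case_id), ]
      v <- virt[match(sel, virt$case_id), ]
      if (sum(o$event) == 0 || sum(v$observed) == 0) return(NA_real_)
      logrank_test(surv_sample(o$pfs_time, o$event),
                   surv_sample(v$time, v$observed))$chi_square
    })
    expect_equal(rs$scan_trace$chi_square, unname(chis))
    best <- which.min(replace(chis, is.na(chis), Inf))
    expect_equal(rs$min_chi_square, chis[best])
    expect_equal(length(rs$member_ids), (30:40)[best])
    expect_equal(rs$member_ids, ids[seq_len((30:40)[best])])  # always a prefix
    expect_true(all(rs$min_chi_square <=
                      rs$scan_trace$chi_square[!rs$scan_trace$skipped] + 1e-12))
    expect_equal(rs$medians,
                 cohort_medians(coh[match(rs$member_ids, coh$case_id), ]))
  }
})

test_that("observed times equal to virtual times give chi-square 0 at the seed prefix", {
  sim <- simulate_cohort(sim_config(n = 35, seed = 8))
  virt <- virtualize_cohort(sim$panel, 0.80)
  df <- as.data.frame(sim$cohort)
  df$pfs_time <- virt$time[match(df$case_id, virt$case_id)]
  df$event <- virt$observed[match(df$case_id, virt$case_id)]
  coh <- cohort(df, "selfmatch")
  rs <- build_reference_set(coh, sim$panel, 0.80, seed_size = 30)
  expect_equal(rs$min_chi_square, 0, tolerance = 1e-12)
  expect_equal(length(rs$member_ids), 30L)   # earliest minimum wins ties
})

test_that("library holds the 8 models, serialises and round-trips", {
  sim <- simulate_cohort(sim_config(n = 45, seed = 13), "train45")
  lib <- build_reference_library(sim$cohort, sim$panel, seed_size = 30)
  expect_named(lib$models, sprintf("%.2f", model_grid()))
  expect_equal(vapply(lib$models, `[[`, numeric(1), "q"),
               setNames(model_grid(), sprintf("%.2f", model_grid())))
  expect_equal(lib$provenance$seed_size, 30)
  expect_named(lib$ranges, match_vars())

  path <- withr::local_tempfile(fileext = ".json")
  write_library(lib, path)
  back <- read_library(path)
  expect_equal(back$provenance$training_label, "train45")
  for (m in names(lib$models)) {
    expect_equal(back$models[[m]]$member_ids, lib$models[[m]]$member_ids)
    expect_equal(back$models[[m]]$medians, lib$models[[m]]$medians)
    expect_equal(back$models[[m]]$min_chi_square,
                 lib$models[[m]]$min_chi_square)
    expect_equal(back$models[[m]]$scan_trace, lib$models[[m]]$scan_trace)
  }
  expect_equal(back$ranges, lib$ranges)

  # determinism: identical inputs give byte-identical serialisations
  lib2 <- build_reference_library(sim$cohort, sim$panel, seed_size = 30)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_library(lib2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("misaligned cohort/panel and undersized cohorts are errors", {
  sim <- simulate_cohort(sim_config(n = 32, seed = 2))
  panel_bad <- sim$panel[-1, ]
  class(panel_bad) <- class(sim$panel)
  expect_error(build_reference_set(sim$cohort, panel_bad, 0.8),
               "orphan.*case001")
  expect_error(build_reference_set(sim$cohort, sim$panel, 0.8, seed_size = 40),
               "below seed_size")
})
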