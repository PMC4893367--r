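# a deliberately small configuration: the structural behaviour of the runner
# does not depend on the full design sizes
small_config <- function(...) {
  study_config(n_total = 250, n_items = 6, clinical_fractions = 0.5,
               theta_grid = seq(-2, 2, by = 1), n_per_point = 25,
               master_seed = 77,
               fit_control = list(tol = 1e-3, max_iter = 200), ...)
}

test_that("run_study produces one row per scenario x fraction x approach", {
  res <- suppressWarnings(run_study(small_config()))
  expect_s3_class(res, "study_result")
  expect_equal(nrow(res), 4L) # 2 scenarios x 1 fraction x 2 approaches
  expect_setequal(res$approach, c("improper", "proper"))
  expect_true(all(vapply(res$fit, inherits, TRUE, "grm_fit")))
  # proper scenario-1 fit is multi-group, proper scenario-2 fit is weighted
  p1 <- res$fit[[which(res$scenario == 1 & res$approach == "proper")]]
  expect_equal(sort(names(p1$group_means)), c("clinical", "general"))
  p2 <- res$fit[[which(res$scenario == 2 & res$approach == "proper")]]
  expect_true(p2$weighted)
})

test_that("invalid fractions are rejected before any computation", {
  expect_error(study_config(clinical_fractions = c(0.5, 1.2)),
               "between 0 and 1")
  expect_error(study_config(clinical_fractions = 0), "between 0 and 1")
})

test_that("study tables have the recovery-table structure and render deterministically", {
  res <- suppressWarnings(run_study(small_config()))
  it <- item_recovery_table(res)
  # per scenario: 5 parameters x 1 fraction x 2 approaches
  expect_equal(nrow(dplyr::filter(it, scenario == 1)), 10L)
  expect_named(it, c("rep", "scenario", "clinical_fraction", "approach",
                     "parameter", "cor", "mean_diff"))
  pt <- person_recovery_table(res)
  expect_equal(nrow(pt), 4L)
  expect_true(all(c("cor", "mean_diff", "mean_se") %in% names(pt)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study_tables(res, d1)
  write_study_tables(res, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_error(item_recovery_table(tibble::tibble()), "study_result")
})

test_that("replications branch seeds independently", {
  res <- suppressWarnings(run_study(small_config(replications = 2)))
  expect_equal(nrow(res), 8L)
  a1 <- res$fit[[which(res$rep == 1 & res$scenario == 1 &
                         res$approach == "improper")]]$bank$a
  a2 <- res$fit[[which(res$rep == 2 & res$scenario == 1 &
                         res$approach == "improper")]]$bank$a
  expect_false(isTRUE(all.equal(a1, a2)))
})

test_that("the same configuration reproduces the same study bit for bit", {
  r1 <- suppressWarnings(run_study(small_config()))
  r2 <- suppressWarnings(run_study(small_config()))
  expect_equal(item_recovery_table(r1), item_recovery_table(r2))
  expect_equal(person_recovery_table(r1), person_recovery_table(r2))
})

test_that("bias-curve plotting layers on the emitted table only", {
  res <- suppressWarnings(run_study(small_config()))
  tab <- bias_curve_table(res)
  expect_true(all(c("true_theta", "mean_theta_hat") %in% names(tab)))
  p1 <- plot_bias_curves(res)
  p2 <- plot_bias_curves(tab)
  expect_s3_class(p1, "ggplot")
  expect_equal(p1$data, p2$data)
})
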