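test_that("critical value is the upper-tail normal quantile of prevalence", {
  expect_equal(round(critical_value(0.10), 2), 1.28)
  expect_equal(critical_value(0.50), 0)
  expect_equal(critical_value(0.25), qnorm(0.75))
  expect_error(critical_value(0), "between 0 and 1")
  expect_error(critical_value(1.2), "between 0 and 1")
})

test_that("sampling weights are the inverse oversampling ratios", {
  w <- sampling_weights(0.10, 0.50)
  expect_equal(unname(w), c(1.8, 0.2))
  # oversampling ratio for clinical respondents: 5x more likely to be sampled
  expect_equal(1 / w[["clinical"]], 5)
  expect_equal(unname(sampling_weights(0.3, 0.3)), c(1, 1))
  expect_error(sampling_weights(0, 0.5), "between 0 and 1")
  expect_error(sampling_weights(0.1, 1), "between 0 and 1")
})

test_that("expected counts under random sampling follow prevalence", {
  ec <- expected_counts(0.10, 1500)
  expect_equal(ec$n_expected[ec$group == "general"], 1350)
  expect_equal(ec$n_expected[ec$group == "clinical"], 150)
  expect_equal(expected_counts(0.5, 100)$n_expected, c(50, 50))
  expect_equal(expected_counts(1e-9, 1000)$n_expected, c(1000, 0),
               tolerance = 1e-5)
})

test_that("scenario-1 samples have exact group counts and unit weights", {
  s <- sample_latent(sampling_design(1, 1500, 0.50), seed = 1)
  expect_equal(unname(table(s$group)), c(750L, 750L), ignore_attr = TRUE)
  expect_true(all(s$weight == 1))
  expect_equal(sum(s$weight), 1500)
  s2 <- sample_latent(sampling_design(1, 1500, 0.50), seed = 1)
  expect_equal(s$theta, s2$theta)
  # near-1 clinical fraction: everyone clinical
  s3 <- sample_latent(sampling_design(1, 10, 0.96), seed = 2)
  expect_equal(sum(s3$group == "clinical"), 10L)
})

test_that("scenario-1 group draws come from the stated populations", {
  s <- sample_latent(sampling_design(1, 2e5, 0.50), seed = 3)
  m_clin <- mean(s$theta[s$group == "clinical"])
  m_gen <- mean(s$theta[s$group == "general"])
  expect_lt(abs(m_clin - 0), 3 / sqrt(1e5))
  expect_lt(abs(m_gen - (-2)), 3 / sqrt(1e5))
})

test_that("scenario-2 samples truncate at the critical value and carry weights", {
  s <- sample_latent(sampling_design(2, 1500, 0.50, prevalence = 0.10), seed = 4)
  cv <- critical_value(0.10)
  expect_true(all(s$theta[s$group == "clinical"] > cv))
  expect_true(all(s$theta[s$group == "general"] <= cv))
  expect_equal(unique(s$weight[s$group == "clinical"]), 0.2)
  expect_equal(unique(s$weight[s$group == "general"]), 1.8)
  expect_equal(sum(s$weight), 1500)
})

test_that("weighted scenario-2 samples recover the untruncated standard normal", {
  # at clinical_fraction == prevalence the sampling is effectively random
  s0 <- sample_latent(sampling_design(2, 1e5, 0.10, prevalence = 0.10), seed = 5)
  expect_true(all(s0$weight == 1))
  expect_lt(weighted_ks_normal(s0$theta, s0$weight), 0.01)
  # heavily enriched sample: raw draws are far from normal, weights restore it
  s1 <- sample_latent(sampling_design(2, 1e5, 0.50, prevalence = 0.10), seed = 6)
  expect_gt(weighted_ks_normal(s1$theta, rep(1, 1e5)), 0.2)
  expect_lt(weighted_ks_normal(s1$theta, s1$weight), 0.01)
})
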