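test_that("marginal log-likelihood matches a tiny closed form", {
  bank <- tiny_bank()[1, ]
  x <- matrix(2L, 1, 1)
  grid <- tibble::tibble(node = c(-1, 1), weight = c(0.5, 0.5))
  got <- marginal_loglik(bank, x, grid = grid)
  p_at <- function(th) {
    P <- 1 / (1 + exp(-bank$a * (th - c(bank$b1, bank$b2, bank$b3, bank$b4))))
    P[2] - P[3]
  }
  expect_equal(got, log(0.5 * p_at(-1) + 0.5 * p_at(1)))
})

test_that("omitted case weights equal unit case weights", {
  bank <- tiny_bank()
  set.seed(2)
  x <- matrix(sample(0:4, 15, TRUE), 5, 3)
  expect_identical(marginal_loglik(bank, x),
                   marginal_loglik(bank, x, weights = rep(1, 5)))
})

test_that("marginal log-likelihood matches an independent brute-force sum", {
  bank <- tiny_bank()
  set.seed(3)
  x <- matrix(sample(0:4, 15, TRUE), 5, 3)
  grid <- quadrature_grid(11, c(-4, 4))
  w <- c(1, 0.2, 1.8, 1, 0.5)
  expect_equal(marginal_loglik(bank, x, grid = grid, weights = w),
               brute_marginal_loglik(bank, x, grid$node, grid$weight, w),
               tolerance = 1e-10)
})

test_that("EM increases the likelihood monotonically and respects invariants", {
  bank <- tiny_bank()
  s <- tibble::tibble(person = 1:400, theta = withr::with_seed(4, rnorm(400)))
  r <- simulate_responses(s, bank, seed = 5)
  fit <- fit_grm(r)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(fit$converged)
  b <- as.matrix(fit$bank[, c("b1", "b2", "b3", "b4")])
  expect_true(all(apply(b, 1, function(row) all(diff(row) > 0))))
  expect_true(all(fit$bank$a > 0))
})

test_that("a weighted fit with unit weights equals the unweighted fit exactly", {
  bank <- tiny_bank()
  s <- tibble::tibble(person = 1:300, theta = withr::with_seed(6, rnorm(300)))
  r <- simulate_responses(s, bank, seed = 7)
  f1 <- fit_grm(r)
  f2 <- fit_grm(r, weights = rep(1, 300))
  expect_identical(f1$bank$a, f2$bank$a)
  expect_identical(f1$bank$b4, f2$bank$b4)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("EM estimates agree with direct maximization of the marginal likelihood", {
  bank <- tiny_bank()
  s <- tibble::tibble(person = 1:250, theta = withr::with_seed(8, rnorm(250)))
  r <- simulate_responses(s, bank, seed = 9)
  fit <- fit_grm(r)
  x <- probank:::response_matrix(r)
  grid <- quadrature_grid()
  # independent route: general-purpose optimizer on the same marginal
  # likelihood, items parameterized by (log a, b1, log gaps)
  unpack <- function(par) {
    m <- matrix(par, ncol = 5, byrow = TRUE)
    as_item_bank(tibble::tibble(
      a = exp(m[, 1]), b1 = m[, 2],
      b2 = m[, 2] + exp(m[, 3]),
      b3 = m[, 2] + exp(m[, 3]) + exp(m[, 4]),
      b4 = m[, 2] + exp(m[, 3]) + exp(m[, 4]) + exp(m[, 5])))
  }
  start <- rep(c(log(1), -1, log(1), log(1), log(1)), nrow(bank))
  neg <- function(par) -marginal_loglik(unpack(par), x, grid = grid)
  opt <- nlminb(start, neg, control = list(iter.max = 500))
  direct <- unpack(opt$par)
  for (col in c("a", "b1", "b2", "b3", "b4")) {
    expect_true(all(abs(fit$bank[[col]] - direct[[col]]) < 0.05),
                info = col)
  }
})

test_that("multi-group fit recovers a shifted free group mean", {
  bank <- tiny_bank()
  design <- sampling_design(1, 800, 0.5, general_mean = -1.5)
  s <- sample_latent(design, seed = 10)
  r <- simulate_responses(s, bank, seed = 11)
  fit <- fit_grm(r, groups = s$group,
                 group_means = c(general = NA, clinical = 0))
  expect_true(fit$fixed_means[["clinical"]])
  expect_equal(fit$group_means[["clinical"]], 0)
  expect_lt(abs(fit$group_means[["general"]] - (-1.5)), 0.3)
})

test_that("standardize_fit is the identity in replication mode and a proper relinking otherwise", {
  bank <- tiny_bank()
  s <- tibble::tibble(person = 1:200, theta = withr::with_seed(12, rnorm(200)))
  r <- simulate_responses(s, bank, seed = 13)
  fit <- fit_grm(r)
  expect_identical(standardize_fit(fit), fit)
  m <- 0.7; sdv <- 1.3
  relinked <- standardize_fit(fit, mean = m, sd = sdv)
  # category probabilities invariant at matched latent values
  theta <- c(-1, 0.3, 2)
  for (j in 1:3) {
    p0 <- grm_category_probs(theta, fit$bank$a[j],
                             unlist(fit$bank[j, c("b1", "b2", "b3", "b4")]))
    p1 <- grm_category_probs(m + sdv * theta, relinked$bank$a[j],
                             unlist(relinked$bank[j, c("b1", "b2", "b3", "b4")]))
    expect_equal(p1, p0, tolerance = 1e-12)
  }
})

test_that("degenerate inputs fail or warn as promised", {
  bank <- tiny_bank()
  x <- matrix(0L, 200, 3) # every item single-category
  expect_error(fit_grm(x), "fewer than 2 observed categories")
  s <- tibble::tibble(person = 1:150, theta = withr::with_seed(14, rnorm(150)))
  r <- simulate_responses(s, bank, seed = 15)
  expect_warning(fit_grm(r, max_iter = 2), "did not converge")
  expect_warning(fit_grm(r[1:50, ]), "persons")
})
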