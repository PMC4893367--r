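test_that("generated banks match the quasi-trait summary targets", {
  bank <- generate_item_bank(n_items = 40, seed = 7)
  expect_s3_class(bank, "item_bank")
  expect_equal(nrow(bank), 40L)
  sm <- bank_summary(bank)
  tg <- quasi_trait_profile()
  for (col in c("min", "mean", "max")) {
    expect_true(all(abs(sm[[col]] - tg[[col]]) <= 0.15),
                info = paste("summary column", col))
  }
  # strict threshold ordering on every item
  b <- as.matrix(bank[, c("b1", "b2", "b3", "b4")])
  expect_true(all(apply(b, 1, function(r) all(diff(r) > 0))))
})

test_that("bank generation is reproducible and seed-sensitive", {
  b1 <- generate_item_bank(seed = 3)
  b2 <- generate_item_bank(seed = 3)
  b3 <- generate_item_bank(seed = 4)
  expect_equal(tibble::as_tibble(b1), tibble::as_tibble(b2))
  expect_false(isTRUE(all.equal(b1$a, b3$a)))
})

test_that("degenerate targets with min = mean = max reproduce the targets exactly", {
  tg <- tibble::tibble(parameter = c("a", "b1", "b2", "b3", "b4"),
                       min = c(1.5, -1, 0, 1, 2),
                       mean = c(1.5, -1, 0, 1, 2),
                       max = c(1.5, -1, 0, 1, 2))
  bank <- generate_item_bank(n_items = 2, seed = 1, targets = tg)
  expect_equal(bank$a, c(1.5, 1.5))
  expect_equal(bank$b4, c(2, 2))
})

test_that("infeasible targets fail loudly", {
  tg <- quasi_trait_profile()
  tg$mean[1] <- 5 # outside [min, max] for a
  expect_error(generate_item_bank(seed = 1, targets = tg), "min <= mean <= max")
})

test_that("bank_summary does exact hand arithmetic and is permutation invariant", {
  bank <- as_item_bank(tibble::tibble(
    a = c(1, 3), b1 = c(-1, 0), b2 = c(0, 1), b3 = c(1, 2), b4 = c(2, 3)))
  sm <- bank_summary(bank)
  expect_equal(unlist(sm[sm$parameter == "a", c("min", "mean", "max")],
                      use.names = FALSE), c(1, 2, 3))
  single <- bank_summary(bank[1, ])
  expect_equal(single$min, single$mean)
  expect_equal(single$mean, single$max)
  shuffled <- bank[c(2, 1), ]
  expect_equal(bank_summary(shuffled), sm)
})

test_that("every generated item has positive category probabilities across the scale", {
  bank <- generate_item_bank(seed = 12)
  theta <- seq(-6, 6, by = 0.5)
  for (j in seq_len(nrow(bank))) {
    p <- grm_category_probs(theta, bank$a[j],
                            unlist(bank[j, c("b1", "b2", "b3", "b4")]))
    expect_true(all(p > 0))
    expect_equal(rowSums(p), rep(1, length(theta)), tolerance = 1e-12)
  }
})

test_that("bank serialization round-trips losslessly in CSV and JSON", {
  bank <- generate_item_bank(seed = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_bank(bank, csv)
  write_bank(bank, json)
  for (path in c(csv, json)) {
    back <- read_bank(path)
    for (col in c("item", "a", "b1", "b2", "b3", "b4")) {
      expect_identical(as.numeric(back[[col]]), as.numeric(bank[[col]]),
                       info = paste(path, col))
    }
  }
})

test_that("loading a bank with unordered thresholds names the offending item", {
  bank <- tibble::as_tibble(generate_item_bank(n_items = 3, seed = 2))
  bank$b2[2] <- bank$b1[2] - 1
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bank, path)
  expect_error(read_bank(path), "Item 2")
})

test_that("rank coupling changes the joint layout but not the marginals", {
  b0 <- generate_item_bank(seed = 9, rho_ab = 0)
  b1 <- generate_item_bank(seed = 9, rho_ab = 0.6)
  expect_equal(sort(b1$a), sort(b0$a) , tolerance = 1e-9)
  sm <- bank_summary(b1)
  expect_true(all(sm$min <= sm$mean & sm$mean <= sm$max))
})
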