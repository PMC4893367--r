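#' GRM cumulative and category probabilities
#'
#' `grm_cumulative_prob()` is the two-parameter logistic
#' \eqn{P_k(\theta) = 1 / (1 + e^{-a(\theta - b_k)})}, the probability of
#' responding in category `k` or higher. `grm_category_probs()` differences
#' the four cumulative curves of a 5-category item into the five category
#' probabilities `p0 = 1 - P1`, `pk = Pk - P(k+1)`, `p4 = P4`.
#'
#' @param theta Latent-trait value(s).
#' @param a Discrimination (> 0).
#' @param b Threshold (scalar for `grm_cumulative_prob()`; length-4 strictly
#'   increasing vector for `grm_category_probs()`).
#' @return `grm_cumulative_prob()`: numeric vector in (0, 1).
#'   `grm_category_probs()`: matrix `length(theta)` x 5, rows summing to 1.
#' @export
#' @examples
#' grm_cumulative_prob(0, a = 2, b = 1) # 1 / (1 + exp(2))
#' rowSums(grm_category_probs(0, a = 1.89, b = c(-0.11, 0.90, 1.93, 2.94)))
grm_cumulative_prob <- function(theta, a, b) {
  if (any(a <= 0)) abort("Discrimination `a` must be positive.")
  plogis(a * (theta - b))
}

#' @rdname grm_cumulative_prob
#' @export
grm_category_probs <- function(theta, a, b) {
  if (length(b) != 4L || any(diff(b) <= 0)) {
    abort("`b` must be 4 strictly increasing thresholds.")
  }
  P <- vapply(b, function(bk) grm_cumulative_prob(theta, a, bk),
              numeric(length(theta)))
  P <- matrix(P, nrow = length(theta))
  cbind(1 - P[, 1], P[, 1] - P[, 2], P[, 2] - P[, 3], P[, 3] - P[, 4], P[, 4])
}

# category probabilities for every item of a bank at a vector of theta values:
# returns a list over items of length(theta) x 5 matrices
bank_category_probs <- function(bank, theta) {
  lapply(seq_len(nrow(bank)), function(j) {
    grm_category_probs(theta, bank$a[j],
                       c(bank$b1[j], bank$b2[j], bank$b3[j], bank$b4[j]))
  })
}

#' Simulate GRM item responses
#'
#' For each person and item, the true parameters and the person's latent value
#' give four cumulative probabilities, which are differenced into category
#' probabilities; one category (coded 0..4) is then drawn from the resulting
#' multinomial. A single uniform draw per cell is compared against the
#' cumulative category probabilities, so one RNG stream drives the whole
#' matrix and results are reproducible given the seed.
#'
#' @param sample A latent sample (tibble with `person` and `theta`, e.g. from
#'   [sample_latent()]).
#' @param bank An `item_bank`.
#' @param seed Optional integer seed.
#' @return A tibble with `person` followed by `item1`..`itemJ` integer columns
#'   (codes 0..4); no missing values.
#' @export
#' @examples
#' bank <- generate_item_bank(seed = 1)
#' s <- sample_latent(sampling_design(1, 100, 0.5), seed = 2)
#' r <- simulate_responses(s, bank, seed = 3)
simulate_responses <- function(sample, bank, seed = NULL) {
  validate_item_bank(bank)
  if (nrow(sample) == 0L) abort("`sample` is empty.")
  theta <- sample$theta
  n <- length(theta)
  J <- nrow(bank)
  with_seed_if(seed, {
    u <- matrix(runif(n * J), nrow = n)
    x <- matrix(0L, nrow = n, ncol = J)
    for (j in seq_len(J)) {
      p <- grm_category_probs(theta, bank$a[j],
                              c(bank$b1[j], bank$b2[j], bank$b3[j], bank$b4[j]))
      cum <- p[, 1]
      xj <- integer(n)
      for (k in 1:4) {
        xj <- xj + (u[, j] > cum)
        if (k < 4) cum <- cum + p[, k + 1]
      }
      x[, j] <- xj
    }
    out <- tibble::as_tibble(as.data.frame(x))
    names(out) <- paste0("item", seq_len(J))
    out <- dplyr::bind_cols(tibble::tibble(person = sample$person), out)
    out
  })
}

# Extract the integer person x item matrix from a response tibble (or pass a
# matrix through). Validates the 0..4 coding.
response_matrix <- function(responses, n_categories = 5L) {
  if (is.matrix(responses)) {
    x <- responses
  } else {
    cols <- grep("^item", names(responses), value = TRUE)
    if (!length(cols)) abort("`responses` has no item columns (item1, item2, ...).")
    x <- as.matrix(responses[, cols])
  }
  storage.mode(x) <- "integer"
  if (anyNA(x)) abort("Responses contain missing values; complete data required.")
  if (any(x < 0L | x >= n_categories)) {
    abort(sprintf("Response codes must lie in 0..%d.", n_categories - 1L))
  }
  x
}
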