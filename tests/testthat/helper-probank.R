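# small hand-built bank used across module tests
tiny_bank <- function() {
  as_item_bank(tibble::tibble(
    a  = c(1.2, 2.0, 0.8),
    b1 = c(-1.0, -0.5, 0.0),
    b2 = c(-0.2, 0.4, 0.6),
    b3 = c(0.9, 1.1, 1.4),
    b4 = c(1.8, 2.3, 2.5)), label = "tiny bank")
}

# independent brute-force marginal log-likelihood: plain loops, no shared code
# with the package's vectorized path beyond the logistic formula itself
brute_marginal_loglik <- function(bank, x, nodes, node_weights,
                                  weights = rep(1, nrow(x))) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    s <- 0
    for (q in seq_along(nodes)) {
      lik <- 1
      for (j in seq_len(nrow(bank))) {
        b <- c(bank$b1[j], bank$b2[j], bank$b3[j], bank$b4[j])
        P <- 1 / (1 + exp(-bank$a[j] * (nodes[q] - b)))
        p <- c(1 - P[1], P[1] - P[2], P[2] - P[3], P[3] - P[4], P[4])
        lik <- lik * p[x[i, j] + 1]
      }
      s <- s + node_weights[q] * lik
    }
    total <- total + weights[i] * log(s)
  }
  total
}

# weighted Kolmogorov distance between a weighted sample and the standard
# normal CDF
weighted_ks_normal <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  cdf_hi <- cumsum(w)
  cdf_lo <- c(0, cdf_hi[-length(cdf_hi)])
  ref <- pnorm(theta)
  max(abs(cdf_hi - ref), abs(cdf_lo - ref))
}
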