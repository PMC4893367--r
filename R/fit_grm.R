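#' Rectangular quadrature grid for marginal maximum likelihood
#'
#' Equally spaced nodes with standard-normal density weights renormalized to
#' sum to one — the classic Bock-Aitkin grid. Group-specific latent means are
#' handled by translating the nodes, not the weights.
#'
#' @param n_nodes Number of nodes (default 61).
#' @param node_range Range of the grid on the latent scale (default
#'   `c(-6, 6)`).
#' @return A tibble with columns `node` (strictly increasing) and `weight`
#'   (non-negative, summing to 1).
#' @export
quadrature_grid <- function(n_nodes = 61, node_range = c(-6, 6)) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  if (node_range[2] <= node_range[1]) abort("`node_range` must be increasing.")
  node <- seq(node_range[1], node_range[2], length.out = n_nodes)
  w <- dnorm(node)
  tibble::tibble(node = node, weight = w / sum(w))
}

# log-likelihood matrix: persons x nodes, summing per-item log category
# probabilities of the observed codes. No clipping: a structurally impossible
# response pattern must surface as -Inf so callers can report it.
loglik_matrix <- function(x, a, b, theta) {
  n <- nrow(x)
  L <- matrix(0, n, length(theta))
  for (j in seq_len(ncol(x))) {
    p <- grm_category_probs(theta, a[j], b[j, ])
    lp <- log(t(p))                       # 5 x Q
    L <- L + lp[x[, j] + 1L, , drop = FALSE]
  }
  L
}

# resolve groups/means into a canonical latent specification
resolve_latent_spec <- function(groups, group_means, n) {
  if (is.null(groups)) {
    groups <- factor(rep("all", n))
    group_means <- c(all = 0)
    fixed <- c(all = TRUE)
  } else {
    groups <- as.factor(groups)
    if (length(groups) != n) abort("`groups` must have one entry per person.")
    lev <- levels(groups)
    if (is.null(group_means)) {
      group_means <- setNames(rep(NA_real_, length(lev)), lev)
      if ("clinical" %in% lev) group_means[["clinical"]] <- 0
      else group_means[[lev[1]]] <- 0
    }
    if (!all(lev %in% names(group_means))) {
      abort("`group_means` must be a named vector covering every group level (NA = free).")
    }
    group_means <- group_means[lev]
    fixed <- !is.na(group_means)
    if (!any(fixed)) {
      abort("At least one group mean must be fixed for identification.")
    }
    group_means[!fixed] <- 0   # provisional; starting values set later
  }
  list(groups = groups, means = group_means, fixed = fixed)
}

#' Marginal log-likelihood of a GRM item bank
#'
#' Integrates the latent trait out over a quadrature grid:
#' \deqn{\ell = \sum_i w_i \log \sum_q W_q \prod_j p(x_{ij} \mid \theta_q + \mu_{g(i)})}
#' where \eqn{W_q} are standard-normal quadrature weights and \eqn{\mu_g} the
#' group latent means (a single group with mean 0 by default — the usual MML
#' assumption of a standard-normal population). Case weights `weights` give
#' the pseudo-likelihood used for enriched samples.
#'
#' @param bank An `item_bank` (or data frame with `a`, `b1`..`b4`).
#' @param responses Response tibble or integer matrix (codes 0..4).
#' @param groups Optional factor of group labels, one per person.
#' @param group_means Named vector of group latent means (used as given; no
#'   free means here). Default: single group at 0.
#' @param grid A [quadrature_grid()] tibble.
#' @param weights Optional non-negative case weights, one per person.
#' @return The scalar weighted marginal log-likelihood.
#' @export
marginal_loglik <- function(bank, responses, groups = NULL, group_means = NULL,
                            grid = quadrature_grid(), weights = NULL) {
  validate_item_bank(bank)
  x <- response_matrix(responses)
  n <- nrow(x)
  if (nrow(bank) != ncol(x)) abort("Bank size and response columns disagree.")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    abort("`weights` must be non-negative, one per person.")
  }
  if (is.null(groups)) {
    groups <- factor(rep("all", n))
    group_means <- group_means %||% c(all = 0)
  } else {
    groups <- as.factor(groups)
    if (is.null(group_means) || !all(levels(groups) %in% names(group_means))) {
      abort("Supply `group_means` covering every group level.")
    }
  }
  a <- bank$a
  b <- as.matrix(bank[, c("b1", "b2", "b3", "b4")])
  lw <- log(grid$weight)
  total <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) next
    L <- loglik_matrix(x[idx, , drop = FALSE], a, b, grid$node + group_means[[g]])
    A <- sweep(L, 2L, lw, "+")
    m <- A[cbind(seq_along(idx), max.col(A, ties.method = "first"))]
    ll <- m + log(rowSums(exp(A - m)))
    if (any(!is.finite(ll))) {
      abort(sprintf(
        "Person %d has zero likelihood at every quadrature node under this bank.",
        idx[which(!is.finite(ll))[1]]))
    }
    total <- total + sum(weights[idx] * ll)
  }
  total
}

# ---- M-step machinery -------------------------------------------------------
# Items are optimized in the unconstrained parameterization
# phi = (log a, b1, log(b2-b1), log(b3-b2), log(b4-b3)), which enforces a > 0
# and strict threshold ordering by construction.

phi_from_item <- function(a, b) c(log(a), b[1], log(pmax(diff(b), 1e-8)))

item_from_phi <- function(phi) {
  list(a = exp(phi[1]), b = cumsum(c(phi[2], exp(phi[3:5]))))
}

item_negQ <- function(phi, R, theta) {
  par <- item_from_phi(phi)
  P <- plogis(par$a * outer(theta, par$b, "-"))
  p <- cbind(1 - P[, 1], P[, 1] - P[, 2], P[, 2] - P[, 3], P[, 3] - P[, 4], P[, 4])
  -sum(R * log(pmax(p, 1e-12)))
}

item_negQ_grad <- function(phi, R, theta) {
  par <- item_from_phi(phi)
  a <- par$a; b <- par$b
  D <- outer(theta, b, "-")
  P <- plogis(a * D)
  p <- cbind(1 - P[, 1], P[, 1] - P[, 2], P[, 2] - P[, 3], P[, 3] - P[, 4], P[, 4])
  W <- R / pmax(p, 1e-12)
  GP <- W[, 1:4, drop = FALSE] - W[, 2:5, drop = FALSE]  # df/dP_k
  Qk <- P * (1 - P)
  df_da <- sum(GP * D * Qk)
  df_db <- -a * colSums(GP * Qk)            # length 4
  gaps <- exp(phi[3:5])
  c(a * df_da,
    sum(df_db),
    gaps * rev(cumsum(rev(df_db)))[2:4])
}

# ---- EM ---------------------------------------------------------------------

#' Fit a graded response model by marginal maximum likelihood
#'
#' Bock-Aitkin EM estimation of a 5-category GRM. Three designs are covered by
#' one routine: the default single-group fit assumes a standard-normal latent
#' trait; supplying `groups` fits a multi-group model with shared item
#' parameters and group-specific normal latent distributions (SD fixed at 1;
#' one mean fixed for identification, free means estimated); supplying
#' `weights` fits the case-weighted pseudo-likelihood in which each person's
#' log-likelihood contribution and E-step expected counts are multiplied by
#' their sampling weight.
#'
#' The E step computes each person's posterior over the (group-translated)
#' quadrature nodes; the M step re-maximizes the expected complete-data
#' log-likelihood item by item in an unconstrained parameterization (log
#' slope, first threshold, log threshold gaps), so positivity and threshold
#' ordering hold by construction. Free group means are updated by the EM
#' coordinate update (posterior-weighted mean of the latent trait in that
#' group). The marginal log-likelihood is non-decreasing over iterations;
#' convergence is declared when the largest absolute parameter change
#' (including free means) drops below `tol`.
#'
#' @param responses Response tibble (from [simulate_responses()]) or integer
#'   matrix with codes 0..4.
#' @param groups Optional factor of group labels per person (multi-group fit).
#' @param weights Optional non-negative case weights per person (weighted fit).
#' @param group_means Named numeric over group levels; `NA` marks a free mean.
#'   Default when `groups` is given: `clinical` fixed at 0 (if present,
#'   otherwise the first level), all other means free.
#' @param n_nodes,node_range Quadrature settings (see [quadrature_grid()]).
#' @param tol Convergence tolerance on the maximum absolute parameter change.
#' @param max_iter Maximum EM cycles.
#' @param a_max Upper bound on discriminations (divergence guard; a warning is
#'   recorded when an estimate lands on the bound).
#' @param gap_floor Lower bound on threshold gaps, so an item with an
#'   unobserved category keeps its 5-category structure with a near-tied
#'   threshold pair instead of collapsing.
#' @param m_step_maxit L-BFGS-B iteration cap per item per cycle (a partial
#'   M step still increases the likelihood from a warm start).
#' @return A `grm_fit` object: estimated `bank`, `group_means` (with
#'   `fixed` attribute), `loglik`, `loglik_trace`, `iterations`, `converged`,
#'   `settings`, and any `warnings` recorded during fitting.
#' @export
#' @examples
#' bank <- generate_item_bank(n_items = 5, seed = 1)
#' s <- sample_latent(sampling_design(1, 200, 0.5, general_mean = 0), seed = 2)
#' r <- simulate_responses(s, bank, seed = 3)
#' fit <- fit_grm(r)
#' glance(fit)
fit_grm <- function(responses, groups = NULL, weights = NULL,
                    group_means = NULL, n_nodes = 61, node_range = c(-6, 6),
                    tol = 1e-4, max_iter = 500, a_max = 10, gap_floor = 0.01,
                    m_step_maxit = 30) {
  x <- response_matrix(responses)
  n <- nrow(x); J <- ncol(x)
  msgs <- character()
  if (n < 100) {
    warn(sprintf("Only %d persons; item parameter estimates will be unstable below a few hundred.", n))
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || anyNA(weights)) {
    abort("`weights` must be non-negative, one per person.")
  }
  spec <- resolve_latent_spec(groups, group_means, n)
  groups <- spec$groups; mu <- spec$means; fixed <- spec$fixed
  lev <- levels(groups)
  gidx <- lapply(lev, function(g) which(groups == g))
  names(gidx) <- lev

  grid <- quadrature_grid(n_nodes, node_range)
  z <- grid$node; lw <- log(grid$weight); Q <- length(z)

  # observed (weighted) category counts per item: starting values + checks
  counts <- matrix(0, J, 5)
  for (j in seq_len(J)) {
    counts[j, ] <- vapply(0:4, function(k) sum(weights[x[, j] == k]), 0)
  }
  few <- which(rowSums(counts > 0) < 2L)
  if (length(few)) {
    abort(sprintf("Item %d has fewer than 2 observed categories; cannot be calibrated.", few[1]))
  }
  empty <- which(apply(counts, 1L, function(r) any(r == 0)))
  if (length(empty)) {
    msgs <- c(msgs, sprintf(
      "Items with unobserved categories (thresholds tied at the gap floor): %s",
      paste(empty, collapse = ", ")))
  }

  # starting values: a = 1.5; thresholds at normal quantiles of observed
  # cumulative proportions, clipped to [-4, 4]; free means from standardized
  # group sum-score differences
  a <- rep(1.5, J)
  wsum <- sum(weights)
  b <- t(vapply(seq_len(J), function(j) {
    p_ge <- rev(cumsum(rev(counts[j, ])))[2:5] / wsum  # P(x >= k), k=1..4
    bj <- qnorm(1 - pmin(pmax(p_ge, 1e-4), 1 - 1e-4))
    bj <- pmin(pmax(bj, -4), 4)
    for (k in 2:4) bj[k] <- max(bj[k], bj[k - 1] + 0.05)
    bj
  }, numeric(4)))

  if (any(!fixed)) {
    ss <- rowSums(x)
    ref <- unlist(gidx[lev[fixed]])
    sd_all <- sd(ss); if (!is.finite(sd_all) || sd_all == 0) sd_all <- 1
    ref_mean <- mean(ss[ref])
    base <- mean(mu[fixed])
    for (g in lev[!fixed]) {
      mu[[g]] <- base + (mean(ss[gidx[[g]]]) - ref_mean) / sd_all
    }
  }

  # expected counts are accumulated with rowsum()/rowSums() rather than BLAS
  # products: a threaded BLAS reorders reductions, which would make repeated
  # fits differ in the last bits and break exact reproducibility

  lower <- c(log(0.05), -10, rep(log(gap_floor), 3))
  upper <- c(log(a_max), 10, rep(log(20), 3))

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # ---- E step ----
    theta_all <- numeric(0)
    Racc <- vector("list", length(lev))
    ll <- 0
    mu_new <- mu
    for (gi in seq_along(lev)) {
      g <- lev[gi]; idx <- gidx[[g]]
      if (!length(idx)) { Racc[[gi]] <- NULL; next }
      th <- z + mu[[g]]
      L <- loglik_matrix(x[idx, , drop = FALSE], a, b, th)
      A <- sweep(L, 2L, lw, "+")
      m <- A[cbind(seq_along(idx), max.col(A, ties.method = "first"))]
      E <- exp(A - m)
      S <- rowSums(E)
      lli <- m + log(S)
      if (any(!is.finite(lli))) {
        abort(sprintf("Person %d has zero likelihood at every quadrature node.",
                      idx[which(!is.finite(lli))[1]]))
      }
      post <- E / S
      ll <- ll + sum(weights[idx] * lli)
      postw <- post * weights[idx]
      Racc[[gi]] <- lapply(seq_len(J), function(j) {
        xg <- x[idx, j]
        Rs <- rowsum(postw, xg)                 # observed categories x Q
        R <- matrix(0, Q, 5)
        R[, as.integer(rownames(Rs)) + 1L] <- t(Rs)
        R
      })
      theta_all <- c(theta_all, th)
      if (!fixed[[g]]) {
        wg <- sum(weights[idx])
        Ez <- rowSums(post * rep(z, each = length(idx)))
        mu_new[[g]] <- mu[[g]] + sum(weights[idx] * Ez) / wg
      }
    }
    trace <- c(trace, ll)

    # ---- M step (items) ----
    a_new <- a; b_new <- b
    for (j in seq_len(J)) {
      R <- do.call(rbind, lapply(Racc, `[[`, j))
      phi0 <- phi_from_item(a[j], b[j, ])
      opt <- stats::optim(phi0, item_negQ, item_negQ_grad, R = R,
                          theta = theta_all, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = m_step_maxit))
      if (opt$value <= item_negQ(phi0, R, theta_all)) {
        par <- item_from_phi(opt$par)
        a_new[j] <- par$a
        b_new[j, ] <- par$b
      }
    }

    delta <- max(abs(a_new - a), abs(b_new - b), abs(unlist(mu_new) - unlist(mu)))
    a <- a_new; b <- b_new; mu <- mu_new
    if (delta < tol) { converged <- TRUE; break }
  }

  if (any(a >= a_max - 1e-6)) {
    msgs <- c(msgs, sprintf("Discrimination bounded at a_max = %g for item(s): %s",
                            a_max, paste(which(a >= a_max - 1e-6), collapse = ", ")))
  }
  if (!converged) {
    warn(sprintf("EM did not converge in %d iterations (last max change above %g).",
                 max_iter, tol))
  }
  for (m in msgs) warn(m)

  est <- new_item_bank(
    tibble::tibble(item = seq_len(J), a = a, b1 = b[, 1], b2 = b[, 2],
                   b3 = b[, 3], b4 = b[, 4]),
    label = "estimated bank")
  bank_final <- est
  loglik_final <- marginal_loglik(bank_final, x, groups = if (length(lev) > 1L) groups,
                                  group_means = mu, grid = grid, weights = weights)
  trace <- c(trace, loglik_final)

  structure(list(
    bank = bank_final,
    group_means = unlist(mu),
    fixed_means = fixed,
    loglik = loglik_final,
    loglik_trace = trace,
    iterations = iter,
    converged = converged,
    n_persons = n,
    n_items = J,
    weighted = any(weights != 1),
    settings = list(n_nodes = n_nodes, node_range = node_range, tol = tol,
                    max_iter = max_iter, a_max = a_max, gap_floor = gap_floor,
                    m_step_maxit = m_step_maxit),
    warnings = msgs
  ), class = "grm_fit")
}

#' Apply the replication identification convention to a fitted GRM
#'
#' In the replication design estimates are compared to the generating
#' parameters directly on the scale induced by the fitted latent
#' specification, so the default is the identity. The optional linear
#' relinking maps the estimates onto a latent scale with the given mean and
#' SD: `a -> a / sd`, `b -> mean + sd * b`, which leaves all category
#' probabilities unchanged at matched latent values.
#'
#' @param fit A `grm_fit`.
#' @param mean,sd Target latent mean and SD (defaults 0 and 1: no change).
#' @return A `grm_fit` with transformed bank.
#' @export
standardize_fit <- function(fit, mean = 0, sd = 1) {
  stopifnot(inherits(fit, "grm_fit"))
  if (sd <= 0) abort("`sd` must be positive.")
  if (mean == 0 && sd == 1) return(fit)
  bank <- fit$bank
  bank$a <- bank$a / sd
  for (col in c("b1", "b2", "b3", "b4")) bank[[col]] <- mean + sd * bank[[col]]
  fit$bank <- bank
  fit$group_means <- mean + sd * fit$group_means
  fit
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("GRM fit: %d items, %d persons%s\n", x$n_items, x$n_persons,
              if (x$weighted) " (case-weighted)" else ""))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s = %.3f%s", names(x$group_means), x$group_means,
                            ifelse(x$fixed_means, " (fixed)", "")),
                    collapse = ", ")))
  cat(sprintf("  logLik %.2f after %d EM cycles (%s)\n", x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a fitted GRM
#'
#' @param x A `grm_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per item with the estimated parameters.
#'   `glance()`: a one-row fit summary.
#' @method tidy grm_fit
#' @export
tidy.grm_fit <- function(x, ...) tibble::as_tibble(x$bank)

#' @rdname tidy.grm_fit
#' @method glance grm_fit
#' @export
glance.grm_fit <- function(x, ...) {
  tibble::tibble(n_persons = x$n_persons, n_items = x$n_items,
                 n_groups = length(x$group_means), logLik = x$loglik,
                 iterations = x$iterations, converged = x$converged,
                 weighted = x$weighted)
}
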