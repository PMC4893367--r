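#' Item-parameter recovery summary
#'
#' For each GRM parameter (a, b1..b4), the Pearson correlation between true
#' and estimated values across items and the mean difference
#' `mean(true - estimate)`. The sign convention follows the recovery-table
#' convention: a negative mean difference means the parameter was
#' overestimated.
#'
#' @param true_bank,est_bank Item banks of equal size (the generating truth
#'   and the calibrated estimate).
#' @return A tibble with columns `parameter`, `cor`, `mean_diff`.
#' @export
#' @examples
#' bank <- generate_item_bank(seed = 1)
#' param_recovery(bank, bank) # correlations 1, differences 0
param_recovery <- function(true_bank, est_bank) {
  validate_item_bank(true_bank)
  validate_item_bank(est_bank)
  if (nrow(true_bank) != nrow(est_bank)) {
    abort("Banks must have the same number of items.")
  }
  purrr::map_dfr(bank_par_cols, function(p) {
    tv <- true_bank[[p]]; ev <- est_bank[[p]]
    tibble::tibble(parameter = p,
                   cor = if (sd(tv) == 0 || sd(ev) == 0) NA_real_ else cor(tv, ev),
                   mean_diff = mean(tv - ev))
  })
}

#' Simulate a latent-trait grid dataset for person-parameter recovery
#'
#' Generates `n_per_point` simulees at each grid value of the true latent
#' trait and draws their responses from the true bank. The same grid dataset
#' can be scored under several calibrations so that scoring differences are
#' attributable to calibration alone.
#'
#' @param bank The true (generating) `item_bank`.
#' @param seed Optional integer seed.
#' @param theta_grid True latent values (default 17 points, -4 to 4 by 0.5).
#' @param n_per_point Simulees per grid point (default 500).
#' @return A list with `sample` (tibble `person`, `theta`) and `responses`
#'   (response tibble), class `theta_grid_data`.
#' @export
theta_grid_data <- function(bank, seed = NULL, theta_grid = seq(-4, 4, by = 0.5),
                            n_per_point = 500) {
  validate_item_bank(bank)
  n_per_point <- check_count(n_per_point, "n_per_point")
  sample <- tibble::tibble(
    person = seq_len(length(theta_grid) * n_per_point),
    theta = rep(theta_grid, each = n_per_point))
  responses <- simulate_responses(sample, bank, seed = seed)
  structure(list(sample = sample, responses = responses,
                 theta_grid = theta_grid, n_per_point = n_per_point),
            class = "theta_grid_data")
}

#' Person-parameter recovery on a latent-trait grid
#'
#' Simulees generated from the true bank at fixed true latent values are
#' MAP-scored under an estimated bank. Per grid point the mean estimate and
#' mean standard error are reported; pooling all simulees gives the overall
#' correlation between true and estimated values, the overall mean difference
#' `mean(theta - theta_hat)` (negative = overestimation) and the overall mean
#' standard error.
#'
#' @param true_bank The generating bank.
#' @param est_bank The scoring (calibrated) bank.
#' @param seed Seed for grid-data simulation (ignored when `grid_data` is
#'   supplied).
#' @param theta_grid,n_per_point Grid settings (defaults: 17 points from -4
#'   to 4 step 0.5, 500 simulees each).
#' @param grid_data Optional pre-simulated [theta_grid_data()], shared across
#'   calibrations.
#' @return A `theta_recovery` object; `tidy()` returns the per-point curve,
#'   `glance()` the pooled summary.
#' @export
theta_recovery <- function(true_bank, est_bank, seed = NULL,
                           theta_grid = seq(-4, 4, by = 0.5),
                           n_per_point = 500, grid_data = NULL) {
  if (is.null(grid_data)) {
    grid_data <- theta_grid_data(true_bank, seed = seed,
                                 theta_grid = theta_grid,
                                 n_per_point = n_per_point)
  }
  scored <- score_responses(grid_data$responses, est_bank, method = "map")
  df <- dplyr::mutate(scored, true_theta = grid_data$sample$theta)
  points <- df |>
    dplyr::group_by(.data$true_theta) |>
    dplyr::summarise(mean_theta_hat = mean(.data$theta_hat),
                     mean_se = mean(.data$se), n = dplyr::n(),
                     .groups = "drop")
  overall <- tibble::tibble(
    cor = cor(df$true_theta, df$theta_hat),
    mean_diff = mean(df$true_theta - df$theta_hat),
    mean_se = mean(df$se),
    n = nrow(df))
  structure(list(points = points, overall = overall), class = "theta_recovery")
}

#' @export
print.theta_recovery <- function(x, ...) {
  cat(sprintf("theta recovery over %d simulees: cor %.3f, mean(theta - est) %.3f, mean SE %.3f\n",
              x$overall$n, x$overall$cor, x$overall$mean_diff, x$overall$mean_se))
  invisible(x)
}

#' @rdname theta_recovery
#' @param x A `theta_recovery`.
#' @param ... Unused.
#' @method tidy theta_recovery
#' @export
tidy.theta_recovery <- function(x, ...) x$points

#' @rdname theta_recovery
#' @method glance theta_recovery
#' @export
glance.theta_recovery <- function(x, ...) x$overall

#' @rdname theta_recovery
#' @param object A `theta_recovery`.
#' @method autoplot theta_recovery
#' @export
autoplot.theta_recovery <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$true_theta, y = .data$mean_theta_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression("true " * theta),
                  y = expression("mean estimated " * theta)) +
    ggplot2::theme_minimal()
}

#' Convert latent-trait values to T-scores
#'
#' The usual norm scale with mean 50 and SD 10: `T = 50 + 10 * theta`. A
#' latent value of 2 is a T-score of 70 (about the 98th percentile), a common
#' clinical cut-off.
#'
#' @param theta Latent-trait value(s).
#' @return T-score(s).
#' @export
#' @examples
#' t_score(c(-1, 0, 2)) # 40, 50, 70
t_score <- function(theta) 50 + 10 * theta
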