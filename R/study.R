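#' Configure the oversampling calibration experiment
#'
#' One configuration drives the full experiment: for each scenario and each
#' clinical fraction, a calibration sample is simulated and calibrated twice —
#' improperly (single-group MML that assumes one standard-normal population,
#' ignoring the sampling scheme) and properly (Scenario 1: multi-group GRM
#' with the clinical mean fixed at 0 and the general mean free; Scenario 2:
#' case-weighted MML using the sampling weights). Defaults reproduce the
#' replication design: a 40-item quasi-trait bank, n = 1500 per sample,
#' clinical fractions 25/50/75%, prevalence 10%, and a 17-point recovery grid
#' with 500 simulees per point.
#'
#' @param n_total Calibration sample size per condition.
#' @param clinical_fractions Clinical shares of the calibration sample.
#' @param scenarios Which scenarios to run (subset of `c(1, 2)`).
#' @param prevalence Scenario-2 population clinical share.
#' @param general_mean,general_sd,clinical_mean,clinical_sd Scenario-1
#'   population distributions.
#' @param n_items,bank_targets Bank generation settings (ignored when `bank`
#'   is supplied).
#' @param bank Optional pre-built true `item_bank`.
#' @param theta_grid,n_per_point Person-recovery grid settings.
#' @param master_seed Integer master seed; every stage draws from its own
#'   deterministic branch.
#' @param replications Number of independent replications (default 1, the
#'   replication design).
#' @param fit_control Named list of overrides passed to [fit_grm()]
#'   (e.g. `list(tol = 1e-4)`).
#' @return A `study_config` list.
#' @export
study_config <- function(n_total = 1500,
                         clinical_fractions = c(0.25, 0.50, 0.75),
                         scenarios = c(1, 2),
                         prevalence = 0.10,
                         general_mean = -2, general_sd = 1,
                         clinical_mean = 0, clinical_sd = 1,
                         n_items = 40, bank_targets = quasi_trait_profile(),
                         bank = NULL,
                         theta_grid = seq(-4, 4, by = 0.5), n_per_point = 500,
                         master_seed = 1, replications = 1,
                         fit_control = list()) {
  for (f in clinical_fractions) check_proportion(f, "clinical_fractions")
  if (!all(scenarios %in% c(1, 2))) abort("`scenarios` must be a subset of c(1, 2).")
  check_proportion(prevalence, "prevalence")
  replications <- check_count(replications, "replications")
  structure(list(
    n_total = check_count(n_total, "n_total"),
    clinical_fractions = clinical_fractions,
    scenarios = as.integer(scenarios),
    prevalence = prevalence,
    general_mean = general_mean, general_sd = general_sd,
    clinical_mean = clinical_mean, clinical_sd = clinical_sd,
    n_items = n_items, bank_targets = bank_targets, bank = bank,
    theta_grid = theta_grid, n_per_point = n_per_point,
    master_seed = master_seed, replications = replications,
    fit_control = fit_control
  ), class = "study_config")
}

fit_with_control <- function(args, control) {
  do.call(fit_grm, utils::modifyList(args, control))
}

#' Run the oversampling calibration experiment
#'
#' Executes every scenario x clinical-fraction cell of the configuration. Per
#' cell one calibration sample is drawn and two calibrations are fitted
#' (improper and proper, see [study_config()]); item-parameter recovery is
#' computed against the true bank, and person-parameter recovery scores one
#' shared latent-grid dataset (per replication) under each calibration, so
#' differences between conditions are due to calibration alone. A
#' non-converged fit does not stop the run; it is flagged in the `converged`
#' column.
#'
#' @param config A [study_config()].
#' @return A `study_result` tibble with one row per replication x scenario x
#'   fraction x approach: columns `rep`, `scenario`, `clinical_fraction`,
#'   `approach`, `converged`, `general_mean_est` (multi-group fits), and
#'   list-columns `fit`, `item_recovery`, `person_recovery`. The true bank
#'   and the config are attached as attributes.
#' @export
#' @examples
#' \donttest{
#' cfg <- study_config(n_total = 300, n_items = 10, n_per_point = 50)
#' res <- run_study(cfg)
#' item_recovery_table(res)
#' }
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seed0 <- config$master_seed
  bank <- config$bank %||% generate_item_bank(
    n_items = config$n_items, seed = seed_branch(seed0, 1),
    targets = config$bank_targets, label = "true bank")
  validate_item_bank(bank)

  rows <- list()
  cond_i <- 0L
  for (rep_i in seq_len(config$replications)) {
    grid_data <- theta_grid_data(bank, seed = seed_branch(seed0, 9000 + rep_i),
                                 theta_grid = config$theta_grid,
                                 n_per_point = config$n_per_point)
    for (scenario in config$scenarios) {
      for (fraction in config$clinical_fractions) {
        cond_i <- cond_i + 1L
        design <- sampling_design(
          scenario, n_total = config$n_total, clinical_fraction = fraction,
          general_mean = config$general_mean, general_sd = config$general_sd,
          clinical_mean = config$clinical_mean, clinical_sd = config$clinical_sd,
          prevalence = config$prevalence)
        samp <- sample_latent(design, seed = seed_branch(seed0, 100 + cond_i))
        resp <- simulate_responses(samp, bank,
                                   seed = seed_branch(seed0, 500 + cond_i))
        fits <- list(
          improper = fit_with_control(list(responses = resp), config$fit_control),
          proper = if (scenario == 1L) {
            fit_with_control(list(responses = resp, groups = samp$group,
                                  group_means = c(general = NA, clinical = 0)),
                             config$fit_control)
          } else {
            fit_with_control(list(responses = resp, weights = samp$weight),
                             config$fit_control)
          })
        for (approach in names(fits)) {
          this_fit <- fits[[approach]]
          ir <- param_recovery(bank, this_fit$bank)
          pr <- theta_recovery(bank, this_fit$bank, grid_data = grid_data)
          gm <- if ("general" %in% names(this_fit$group_means) &&
                    !this_fit$fixed_means[["general"]])
            this_fit$group_means[["general"]] else NA_real_
          rows[[length(rows) + 1L]] <- tibble::tibble(
            rep = rep_i, scenario = scenario, clinical_fraction = fraction,
            approach = approach,
            converged = this_fit$converged,
            general_mean_est = gm,
            fit = list(this_fit),
            item_recovery = list(ir),
            person_recovery = list(pr))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "bank") <- bank
  class(out) <- c("study_result", class(out))
  out
}

check_study_result <- function(result) {
  if (!inherits(result, "study_result") || nrow(result) == 0L) {
    abort("Need a non-empty `study_result` from `run_study()`.")
  }
  invisible(result)
}

#' Tidy tables from a study result
#'
#' `item_recovery_table()` unnests per-parameter correlations and mean
#' differences (the item-recovery tables, one block per scenario);
#' `person_recovery_table()` gives the pooled person-recovery summary
#' (correlation, mean difference, mean SE) per condition;
#' `bias_curve_table()` gives the mean estimated latent value per true grid
#' value, the data behind the bias-curve figure.
#'
#' @param result A `study_result`.
#' @return A tibble.
#' @export
item_recovery_table <- function(result) {
  check_study_result(result)
  result |>
    dplyr::select("rep", "scenario", "clinical_fraction", "approach",
                  "item_recovery") |>
    tidyr::unnest("item_recovery")
}

#' @rdname item_recovery_table
#' @export
person_recovery_table <- function(result) {
  check_study_result(result)
  result |>
    dplyr::mutate(summary = purrr::map(.data$person_recovery, glance)) |>
    dplyr::select("rep", "scenario", "clinical_fraction", "approach",
                  "summary") |>
    tidyr::unnest("summary")
}

#' @rdname item_recovery_table
#' @export
bias_curve_table <- function(result) {
  check_study_result(result)
  result |>
    dplyr::mutate(points = purrr::map(.data$person_recovery, tidy)) |>
    dplyr::select("rep", "scenario", "clinical_fraction", "approach",
                  "points") |>
    tidyr::unnest("points")
}

#' Write study tables to CSV files
#'
#' Emits the item-recovery table per scenario, the person-recovery summary,
#' and the bias-curve table. Output is deterministic: rendering the same
#' result twice yields byte-identical files.
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_study_tables <- function(result, dir) {
  check_study_result(result)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  it <- item_recovery_table(result)
  paths <- character()
  for (sc in sort(unique(it$scenario))) {
    p <- file.path(dir, sprintf("item_recovery_scenario%d.csv", sc))
    readr::write_csv(dplyr::filter(it, .data$scenario == sc), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "person_recovery.csv")
  readr::write_csv(person_recovery_table(result), p)
  paths <- c(paths, p)
  p <- file.path(dir, "bias_curves.csv")
  readr::write_csv(bias_curve_table(result), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Plot bias curves: mean estimated vs. true latent value
#'
#' One panel per scenario x calibration approach, one curve per clinical
#' fraction, with the identity line for reference. Accepts a `study_result`
#' or a [bias_curve_table()] tibble directly — the plot is a pure function of
#' the emitted curve table.
#'
#' @param x A `study_result` or bias-curve tibble.
#' @return A ggplot.
#' @export
plot_bias_curves <- function(x) {
  tab <- if (inherits(x, "study_result")) bias_curve_table(x) else tibble::as_tibble(x)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$true_theta,
                                    y = .data$mean_theta_hat,
                                    colour = factor(.data$clinical_fraction))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey55") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ggplot2::vars(.data$scenario),
                        ggplot2::vars(.data$approach),
                        labeller = ggplot2::labeller(
                          scenario = function(v) paste("scenario", v))) +
    ggplot2::labs(x = expression("true " * theta),
                  y = expression("mean estimated " * theta),
                  colour = "clinical fraction") +
    ggplot2::theme_minimal()
}

#' Write bias-curve figures to files
#'
#' @param result A `study_result`.
#' @param dir Output directory.
#' @param device Graphics device extension understood by
#'   [ggplot2::ggsave()] (default `"pdf"`).
#' @return Invisibly, the written path.
#' @export
write_study_figures <- function(result, dir, device = "pdf") {
  check_study_result(result)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0("bias_curves.", device))
  ggplot2::ggsave(path, plot_bias_curves(result), width = 8, height = 6)
  invisible(path)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study result: %d condition fits (%d scenario(s) x %d fraction(s) x 2 approaches x %d rep(s))\n",
              nrow(x), length(unique(x$scenario)),
              length(unique(x$clinical_fraction)), max(x$rep)))
  if (any(!x$converged)) {
    cat(sprintf("  non-converged fits: %d\n", sum(!x$converged)))
  }
  NextMethod()
}
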