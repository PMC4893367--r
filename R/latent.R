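#' Clinical cut-off on the latent scale for a given prevalence
#'
#' Under the single-distribution view, respondents with pathology are those
#' above a critical value on the standard-normal latent trait; the cut-off is
#' the (1 - prevalence) quantile. A prevalence of 10% gives 1.28.
#'
#' @param prevalence Population proportion above the cut-off, in (0, 1).
#' @return The critical value (latent-scale units).
#' @export
#' @examples
#' critical_value(0.10) # 1.28
critical_value <- function(prevalence) {
  check_proportion(prevalence, "prevalence")
  qnorm(1 - prevalence)
}

#' Sampling weights for an enriched calibration sample
#'
#' When a fraction `clinical_fraction` of the calibration sample is drawn from
#' a clinical stratum whose population share is `prevalence`, clinical
#' respondents are oversampled by the factor `clinical_fraction / prevalence`.
#' The pseudo-likelihood weights that restore the target population are the
#' inverse ratios: `w_clinical = prevalence / clinical_fraction` and
#' `w_general = (1 - prevalence) / (1 - clinical_fraction)`. When group counts
#' follow the fractions exactly, the weights sum to the sample size.
#'
#' @param prevalence Population clinical share, in (0, 1).
#' @param clinical_fraction Sample clinical share, in (0, 1).
#' @return Named numeric vector `c(general = ..., clinical = ...)`.
#' @export
#' @examples
#' sampling_weights(0.10, 0.50) # general 1.8, clinical 0.2
sampling_weights <- function(prevalence, clinical_fraction) {
  check_proportion(prevalence, "prevalence")
  check_proportion(clinical_fraction, "clinical_fraction")
  c(general = (1 - prevalence) / (1 - clinical_fraction),
    clinical = prevalence / clinical_fraction)
}

#' Expected group counts under random sampling
#'
#' The group sizes a simple random sample of `n_total` persons would yield
#' given the population prevalence — the benchmark against which an enriched
#' sample's clinical count is inflated.
#'
#' @inheritParams sampling_weights
#' @param n_total Total sample size.
#' @return A tibble with columns `group` and `n_expected`.
#' @export
#' @examples
#' expected_counts(0.10, 1500) # 1350 general, 150 clinical
expected_counts <- function(prevalence, n_total) {
  check_proportion(prevalence, "prevalence")
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total <= 0) {
    abort("`n_total` must be a single positive number.")
  }
  tibble::tibble(group = c("general", "clinical"),
                 n_expected = c(n_total * (1 - prevalence),
                                n_total * prevalence))
}

#' Specify a latent-trait sampling design
#'
#' Captures one cell of the study design: which population scenario generates
#' the latent traits, the sample size, and the clinical share of the sample.
#' Scenario 1 assumes two distinct normal populations (general and clinical);
#' Scenario 2 assumes one standard-normal population split at the clinical
#' cut-off implied by `prevalence`.
#'
#' @param scenario 1 (two distributions) or 2 (one distribution).
#' @param n_total Sample size (the replication design uses 1500).
#' @param clinical_fraction Share of the sample drawn from the clinical
#'   population/region, in (0, 1).
#' @param general_mean,general_sd Scenario-1 general-population distribution
#'   (defaults N(-2, 1)).
#' @param clinical_mean,clinical_sd Scenario-1 clinical-population
#'   distribution (defaults N(0, 1)).
#' @param population_mean,population_sd Scenario-2 single population
#'   (defaults N(0, 1)).
#' @param prevalence Scenario-2 population clinical share (default 0.10,
#'   cut-off 1.28).
#' @return A `sampling_design` list.
#' @export
sampling_design <- function(scenario, n_total = 1500, clinical_fraction = 0.5,
                            general_mean = -2, general_sd = 1,
                            clinical_mean = 0, clinical_sd = 1,
                            population_mean = 0, population_sd = 1,
                            prevalence = 0.10) {
  if (!scenario %in% c(1, 2)) abort("`scenario` must be 1 or 2.")
  n_total <- check_count(n_total, "n_total")
  check_proportion(clinical_fraction, "clinical_fraction")
  check_proportion(prevalence, "prevalence")
  if (general_sd <= 0 || clinical_sd <= 0 || population_sd <= 0) {
    abort("Standard deviations must be positive.")
  }
  structure(
    list(scenario = as.integer(scenario), n_total = n_total,
         clinical_fraction = clinical_fraction,
         general_mean = general_mean, general_sd = general_sd,
         clinical_mean = clinical_mean, clinical_sd = clinical_sd,
         population_mean = population_mean, population_sd = population_sd,
         prevalence = prevalence),
    class = "sampling_design")
}

#' Draw a latent-trait calibration sample
#'
#' Group counts are fixed, not binomial: exactly
#' `round(n_total * clinical_fraction)` persons (half-up) are clinical, the
#' remainder general. Under Scenario 1 each group is drawn from its own normal
#' distribution and all case weights are 1. Under Scenario 2 the general group
#' is drawn from the standard normal truncated at or below the clinical
#' cut-off and the clinical group from the upper tail (both by inverse-CDF, so
#' sampling is exact with no rejection loop), and each person carries the
#' sampling weight of their group, rescaled so the weights sum to `n_total`.
#'
#' @param design A [sampling_design()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `person`, `theta`, `group` (factor
#'   general/clinical), `weight`, and the design stored as attribute
#'   `"design"`.
#' @export
#' @examples
#' s <- sample_latent(sampling_design(2, 1500, 0.5), seed = 1)
#' table(s$group)
sample_latent <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  n_clin <- as.integer(round_half_up(design$n_total * design$clinical_fraction))
  n_gen <- design$n_total - n_clin
  with_seed_if(seed, {
    if (design$scenario == 1L) {
      theta_gen <- stats::rnorm(n_gen, design$general_mean, design$general_sd)
      theta_clin <- stats::rnorm(n_clin, design$clinical_mean, design$clinical_sd)
      w_gen <- rep(1, n_gen); w_clin <- rep(1, n_clin)
    } else {
      cv <- critical_value(design$prevalence)
      p_cut <- pnorm(cv)
      z_gen <- qnorm(runif(n_gen) * p_cut)
      z_clin <- qnorm(p_cut + runif(n_clin) * (1 - p_cut))
      theta_gen <- design$population_mean + design$population_sd * z_gen
      theta_clin <- design$population_mean + design$population_sd * z_clin
      w <- sampling_weights(design$prevalence, design$clinical_fraction)
      w_gen <- rep(w[["general"]], n_gen)
      w_clin <- rep(w[["clinical"]], n_clin)
      # fixed counts can round, so renormalize to keep sum(weights) == n_total
      tot <- sum(w_gen) + sum(w_clin)
      w_gen <- w_gen * design$n_total / tot
      w_clin <- w_clin * design$n_total / tot
    }
    out <- tibble::tibble(
      person = seq_len(design$n_total),
      theta = c(theta_gen, theta_clin),
      group = factor(rep(c("general", "clinical"), c(n_gen, n_clin)),
                     levels = c("general", "clinical")),
      weight = c(w_gen, w_clin))
    attr(out, "design") <- design
    out
  })
}
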