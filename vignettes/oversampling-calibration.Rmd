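---
title: "Clinical oversampling in PRO item-bank calibration: models, design choices and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical oversampling in PRO item-bank calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Item banks for patient-reported outcomes (PROs) are usually calibrated with
item response theory. Many PRO constructs are *quasi-traits*: the items carry
information only at the severe end of the latent continuum, so a general
population sample produces heavily floor-skewed responses and the upper part
of the scale is measured imprecisely. The standard remedy is to enrich the
calibration sample with clinical respondents. That enrichment changes the
latent-trait distribution of the sample, and the default calibration — which
assumes a single standard-normal population — silently absorbs the change
into the item parameters. `probank` implements the machinery to study exactly
what that does to item parameters, latent-trait scores, norm-referenced
T-scores and reported standard errors.

## Models

**Graded response model.** For a 5-category item with discrimination $a > 0$
and ordered thresholds $b_1 < b_2 < b_3 < b_4$, the cumulative probability of
responding in category $k$ or above at latent value $\theta$ is
$P_k(\theta) = \mathrm{logit}^{-1}\{a(\theta - b_k)\}$, and the category
probabilities are the successive differences of the four cumulative curves
(`grm_category_probs()`).

**Calibration.** Item parameters are estimated by marginal maximum
likelihood: the latent trait is integrated out over an assumed population
density on a rectangular quadrature grid (Bock–Aitkin EM, `fit_grm()`).
Three population assumptions are supported:

* *single group* — $\theta \sim N(0,1)$, the default most software applies;
* *multi-group* — shared item parameters, group-specific normal latent
  distributions with SD fixed at 1; the clinical mean is fixed at 0 for
  identification and the general-population mean is estimated;
* *case-weighted* — a pseudo-likelihood in which person $i$'s log-likelihood
  contribution and E-step expected counts are multiplied by a sampling weight
  $w_i$.

**Scoring.** Latent traits are scored by MAP with a standard-normal prior
(`score_responses()`), the estimator of choice for quasi-traits because it
stays finite for all-lowest response patterns. The reported standard error is
the curvature-based one: $\mathrm{SE} = (-\partial^2 \log \text{posterior} /
\partial \theta^2)^{-1/2}$ at the mode, which includes the prior's
information. This is the conventional MAP standard error; software differs
in this definition, so absolute SE levels should be compared with that caveat
in mind. Bounded maximum-likelihood scoring is available as an option
(`method = "ml"`, default range $[-4, 4]$) but is not used in replication
runs.

## The two population scenarios

`sample_latent()` draws calibration samples of fixed (not binomial) group
composition under two views of where clinical respondents come from:

* **Scenario 1 — two distinct distributions.** The general population is
  $N(-2, 1)$ and the clinical population $N(0, 1)$. The *proper* calibration
  is the multi-group model.
* **Scenario 2 — one distribution.** Everyone comes from $N(0, 1)$;
  respondents above the clinical cut-off $c = \Phi^{-1}(1 - \text{prevalence})$
  (1.28 at the default prevalence of 10%) are clinical. Groups are sampled
  exactly from the two truncated regions by inverse-CDF (no rejection steps,
  exact tails). The *proper* calibration uses the sampling weights
  $w_\text{clin} = \text{prevalence}/\text{fraction}$ and
  $w_\text{gen} = (1-\text{prevalence})/(1-\text{fraction})$
  (`sampling_weights()`), which sum to the sample size; with rounding-induced
  group counts the weights are renormalized so that the sum is exact.

The *improper* calibration in both scenarios is the default single-group fit
that ignores the sampling scheme. The study grid is 2 scenarios × clinical
fractions {25%, 50%, 75%} × {proper, improper}, twelve calibrations per
replication (`run_study()`).

## The synthetic item bank

The exact parameters of the severity bank that motivated the design are not
published; only the per-parameter minimum, mean and maximum are
(`quasi_trait_profile()`: e.g. $a$ ranging 1.04–2.66 with mean 1.89, $b_4$
2.20–3.57 with mean 2.94). `generate_item_bank()` therefore draws each
parameter column from a Beta(2, 2) distribution rescaled so the sample
minimum, maximum and mean hit the targets essentially exactly (the mean via a
monotone power transform of the unit-interval values), then enforces
per-item threshold ordering with a minimum gap of 0.05 and rejects the draw
if the repair moved any summary by more than 0.15. The joint distribution
across parameters is left independent by default because nothing about it is
published; a Gaussian-copula rank coupling between $a$ and the thresholds is
available (`rho_ab`) and permutes within columns, so the marginal summaries
are untouched.

Consequences worth keeping in mind: every quantity downstream of the bank is
*statistically*, not numerically, comparable to the original study — the
same profile, not the same 40 items. The generator reproduces marginal
summaries, not inter-item correlation structure, local dependence, or item
content effects; passing tests show the estimators behave correctly for
banks *of this profile*, not that any real data set is this clean (responses
here are complete, unidimensional and locally independent by construction).

## Numerical choices

* **Quadrature**: 61 equally spaced nodes on $[-6, 6]$ with standard-normal
  density weights renormalized to 1. Group means translate the *nodes*, not
  the weights.
* **M step**: each item is maximized in the unconstrained parameterization
  $(\log a,\; b_1,\; \log(b_2-b_1),\; \log(b_3-b_2),\; \log(b_4-b_3))$ with
  analytic gradients under L-BFGS-B, so positivity and strict ordering are
  structural. Slopes are capped at $a_{\max} = 10$ (a divergence guard that
  is logged when hit); threshold gaps are floored at 0.01 so an item with an
  unobserved category keeps the 5-category structure with a near-tied
  threshold pair rather than collapsing.
* **Free group means** are updated by the EM coordinate update — the
  posterior-weighted mean of $\theta$ in the free group — which is the exact
  maximizer of the expected complete-data log-likelihood in that coordinate,
  shares EM's monotonicity guarantee, and costs nothing compared to a line
  search on the marginal likelihood. At a fixed point it satisfies the same
  stationarity condition.
* **Convergence**: largest absolute parameter change (including free means)
  below $10^{-4}$, at most 500 cycles; the marginal log-likelihood trace is
  recorded and checked to be non-decreasing (tolerance $10^{-8}$) in the
  tests.
* **Starting values**: $a = 1.5$ everywhere; thresholds at normal quantiles
  of the observed cumulative category proportions clipped to $[-4, 4]$; free
  means from standardized group sum-score differences. Deterministic, so a
  fit is a pure function of its inputs.
* **Determinism**: E-step accumulations use `rowsum()`/`rowSums()` rather
  than BLAS matrix products; with a threaded BLAS the reduction order (and
  hence the last bits) of repeated runs would otherwise differ.
* **MAP scoring**: damped, safeguarded Newton on the 1-D log posterior,
  vectorized across persons, estimates clamped to $[-8, 8]$, tolerance
  $10^{-6}$, with a golden-section fallback for any pattern whose gradient
  has not vanished; verified against a dense grid search in the tests.

## Scale indeterminacy, in one paragraph

The improper fits are not "wrong numerically" — they maximize their
likelihood perfectly well. They are wrong *referentially*: forcing a
standard-normal latent distribution onto a sample whose latent mixture has
mean $m$ and standard deviation $s$ re-expresses every item parameter on
that implicit scale, $\hat a \approx s\,a$ and $\hat b_k \approx (b_k - m)/s$.
In Scenario 1 at 50% clinical, $s \approx \sqrt 2$, which is exactly the
observed ~41% slope inflation; in Scenario 2 the truncated-and-reweighted
mixture mean grows with the clinical fraction, which is why location bias
grows with enrichment. Because a latent scale shift propagates into scores,
the MAP estimates and the T-score norms inherit the bias — and because
inflated slopes mean inflated test information, the improper calibrations
also report systematically smaller standard errors than the proper ones,
i.e. overstated precision.

## Problem sizes used in the shipped runs

Replication-mode defaults are the full design: 40 items, $n = 1500$ per
calibration sample, and a recovery grid of 17 true-$\theta$ values from $-4$
to $4$ (step 0.5) with 500 simulees each, scored once per calibration from a
single shared grid dataset per replication. The package's own test suite
runs the complete 12-condition study once at these sizes and additionally
exercises the estimator against an independent direct maximization of the
marginal likelihood on a 5-item, 300-person instance; structural tests of
the study runner use deliberately small configurations (6 items, $n = 250$)
because the properties checked there do not depend on size. One replication
of the full design is used, as in the original single-draw design;
condition-level seed branches make any cell re-runnable in isolation, and
`replications > 1` is available for Monte-Carlo summaries.

## Known limitations

* Latent distributions are normal (or truncated normal) by design; skewed or
  unipolar latent traits are out of scope.
* No missing data, response styles, DIF, or CAT administration — the CAT
  implications (early stopping under understated SEs) are an interpretation
  of the SE results, not a simulated process.
* Item-parameter standard errors are not computed (the recovery outcomes do
  not use them).
* The latent SD is fixed at 1 in every group, as in the replication design;
  the multi-group model estimates means only.

## A minimal run

```{r, eval = FALSE}
library(probank)

cfg <- study_config(master_seed = 42)
res <- run_study(cfg)

item_recovery_table(res)    # correlations + mean(true - estimate) per cell
person_recovery_table(res)  # pooled theta recovery and mean SE per cell
plot_bias_curves(res)       # mean estimated vs true theta, per condition
```
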