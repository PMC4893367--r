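#' Target summary profile of a quasi-trait severity bank
#'
#' Per-parameter minimum, mean and maximum used as generation targets by
#' [generate_item_bank()]. The default profile describes a 40-item, 5-category
#' severity bank whose location parameters sit mostly on the upper half of the
#' latent-trait scale, so that a general-population sample endorses low
#' categories almost exclusively — the situation in which calibration samples
#' are typically enriched with clinical respondents.
#'
#' @return A tibble with columns `parameter` (`"a"`, `"b1"`..`"b4"`), `min`,
#'   `mean`, `max`.
#' @export
#' @examples
#' quasi_trait_profile()
quasi_trait_profile <- function() {
  tibble::tibble(
    parameter = c("a", "b1", "b2", "b3", "b4"),
    min  = c(1.04, -0.97, 0.27, 1.20, 2.20),
    mean = c(1.89, -0.11, 0.90, 1.93, 2.94),
    max  = c(2.66,  0.89, 1.52, 2.72, 3.57)
  )
}

bank_par_cols <- c("a", "b1", "b2", "b3", "b4")

new_item_bank <- function(df, label = "item bank") {
  df <- tibble::as_tibble(df)
  structure(df, class = c("item_bank", class(df)), label = label)
}

#' Coerce a data frame to an item bank
#'
#' @param x A data frame with columns `item`, `a`, `b1`, `b2`, `b3`, `b4`
#'   (the `item` column is added if absent).
#' @param label Free-text label carried as an attribute.
#' @return An `item_bank` tibble.
#' @export
as_item_bank <- function(x, label = "item bank") {
  x <- tibble::as_tibble(x)
  if (!"item" %in% names(x)) x <- dplyr::mutate(x, item = dplyr::row_number())
  x <- dplyr::select(x, "item", dplyr::all_of(bank_par_cols))
  bank <- new_item_bank(x, label = label)
  validate_item_bank(bank)
  bank
}

#' Validate GRM item-bank invariants
#'
#' Checks that every discrimination is strictly positive and every item's
#' thresholds are strictly increasing (`b1 < b2 < b3 < b4`), the conditions
#' under which all five category probabilities are positive at every trait
#' value.
#'
#' @param bank An item-bank data frame.
#' @return The bank, invisibly. Errors name the first offending item.
#' @export
validate_item_bank <- function(bank) {
  if (nrow(bank) == 0L) abort("Item bank is empty.")
  miss <- setdiff(c(bank_par_cols), names(bank))
  if (length(miss)) {
    abort(paste0("Item bank is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_a <- which(!is.finite(bank$a) | bank$a <= 0)
  if (length(bad_a)) {
    abort(sprintf("Item %d has non-positive discrimination a = %g.",
                  bad_a[1], bank$a[bad_a[1]]))
  }
  b <- as.matrix(bank[, c("b1", "b2", "b3", "b4")])
  bad_b <- which(apply(b, 1L, function(r) any(!is.finite(r)) || any(diff(r) <= 0)))
  if (length(bad_b)) {
    abort(sprintf(
      "Item %d has thresholds that are not strictly increasing: (%s).",
      bad_b[1], paste(format(b[bad_b[1], ], digits = 4), collapse = ", ")))
  }
  invisible(bank)
}

#' Summarize an item bank
#'
#' Minimum, mean and maximum of each GRM parameter across items.
#'
#' @param bank An item-bank data frame (see [generate_item_bank()]).
#' @return A tibble with columns `parameter`, `min`, `mean`, `max`.
#' @export
#' @examples
#' bank <- generate_item_bank(n_items = 40, seed = 1)
#' bank_summary(bank)
bank_summary <- function(bank) {
  if (nrow(bank) == 0L) abort("Cannot summarize an empty item bank.")
  bank |>
    dplyr::select(dplyr::all_of(bank_par_cols)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(min = min(.data$value), mean = mean(.data$value),
                     max = max(.data$value), .groups = "drop") |>
    dplyr::arrange(match(.data$parameter, bank_par_cols))
}

# Draw n values on [lo, hi] whose sample min, max and mean hit the targets
# (to numerical precision): Beta draws are rescaled to span [0, 1] exactly,
# then a monotone power transform u^gamma fixes the mean, then the unit
# interval is mapped to [lo, hi]. Width zero collapses to a constant column.
draw_column <- function(n, lo, mu, hi) {
  if (mu < lo || mu > hi) {
    abort(sprintf("Infeasible targets: mean %g outside [min, max] = [%g, %g].",
                  mu, lo, hi))
  }
  width <- hi - lo
  if (width < 1e-12) return(rep(lo, n))
  if (mu <= lo + 1e-12 || mu >= hi - 1e-12) {
    abort(sprintf(
      "Infeasible targets: mean %g must lie strictly inside [%g, %g] when min < max.",
      mu, lo, hi))
  }
  target <- (mu - lo) / width
  u <- rbeta(n, 2, 2)
  u <- (u - min(u)) / (max(u) - min(u))
  f <- function(g) mean(u^g) - target
  gamma <- uniroot(f, lower = 0.02, upper = 50, tol = 1e-12)$root
  lo + width * u^gamma
}

#' Generate a quasi-trait GRM item bank
#'
#' Draws a bank of 5-category graded-response items whose per-parameter
#' minimum, mean and maximum match a target summary profile (by default the
#' quasi-trait profile of [quasi_trait_profile()]). Each parameter column is
#' drawn from a scaled Beta distribution and monotonically adjusted so its
#' sample min/mean/max hit the targets; threshold ordering is then enforced
#' per item with a minimum gap, and the draw is rejected and repeated if the
#' ordering repair pushed any summary outside `tol`.
#'
#' @param n_items Number of items (the study design uses 40).
#' @param seed Integer seed; the same seed and targets reproduce the same bank.
#' @param targets Data frame like [quasi_trait_profile()]: one row per
#'   parameter with `min`, `mean`, `max` (requires `min <= mean <= max`).
#' @param tol Maximum absolute deviation of any realized summary statistic
#'   from its target.
#' @param min_gap Minimum enforced threshold spacing `b[k+1] - b[k]`, keeping
#'   every category numerically alive.
#' @param rho_ab Optional Gaussian-copula rank coupling between `a` and the
#'   threshold columns (0 = independent, the default). Coupling permutes
#'   values within columns, so marginal summaries are unaffected.
#' @param max_tries Rejection-sampling attempts before giving up.
#' @param label Free-text label stored on the bank.
#' @return An `item_bank` tibble with columns `item`, `a`, `b1`..`b4` and
#'   attributes `label`, `seed`, `targets`.
#' @export
#' @examples
#' bank <- generate_item_bank(n_items = 40, seed = 7)
#' bank_summary(bank)
generate_item_bank <- function(n_items = 40, seed = NULL,
                               targets = quasi_trait_profile(),
                               tol = 0.15, min_gap = 0.05, rho_ab = 0,
                               max_tries = 100, label = "generated bank") {
  n_items <- check_count(n_items, "n_items", min = 2L)
  targets <- tibble::as_tibble(targets)
  if (!all(bank_par_cols %in% targets$parameter)) {
    abort("`targets` must contain rows for parameters a, b1, b2, b3, b4.")
  }
  if (any(targets$min > targets$mean | targets$mean > targets$max)) {
    abort("Infeasible targets: need min <= mean <= max for every parameter.")
  }
  tg <- function(p, col) targets[[col]][targets$parameter == p]

  with_seed_if(seed, {
    for (try in seq_len(max_tries)) {
      cols <- lapply(bank_par_cols, function(p) {
        draw_column(n_items, tg(p, "min"), tg(p, "mean"), tg(p, "max"))
      })
      names(cols) <- bank_par_cols
      if (rho_ab != 0) {
        z0 <- stats::rnorm(n_items)
        couple <- function(v, rho) {
          w <- rho * z0 + sqrt(1 - rho^2) * stats::rnorm(n_items)
          sort(v)[rank(w, ties.method = "first")]
        }
        cols$a <- couple(cols$a, rho_ab)
        for (p in c("b1", "b2", "b3", "b4")) cols[[p]] <- couple(cols[[p]], 1)
      }
      b <- cbind(cols$b1, cols$b2, cols$b3, cols$b4)
      for (k in 2:4) b[, k] <- pmax(b[, k], b[, k - 1] + min_gap)
      df <- tibble::tibble(item = seq_len(n_items), a = cols$a,
                           b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4])
      sm <- bank_summary(df)
      dev <- abs(as.matrix(sm[, c("min", "mean", "max")]) -
                   as.matrix(targets[match(sm$parameter, targets$parameter),
                                     c("min", "mean", "max")]))
      if (max(dev) <= tol) {
        bank <- new_item_bank(df, label = label)
        attr(bank, "seed") <- seed
        attr(bank, "targets") <- targets
        validate_item_bank(bank)
        return(bank)
      }
    }
  })
  abort(sprintf(
    "Could not generate a bank matching the targets within tol = %g in %d tries.",
    tol, max_tries))
}

#' Read and write item banks
#'
#' Banks are serialized one row per item. Paths ending in `.json` use a JSON
#' document that also carries `n_categories`, the label and the generation
#' seed; any other path is a CSV with header `item,a,b1,b2,b3,b4`. The round
#' trip is lossless to full double precision, and loading re-validates the
#' threshold ordering, naming the first offending item on failure.
#'
#' @param bank An `item_bank`.
#' @param path File path (`.json` for JSON, otherwise CSV).
#' @return `read_bank()` returns an `item_bank`; `write_bank()` returns the
#'   path invisibly.
#' @export
write_bank <- function(bank, path) {
  validate_item_bank(bank)
  df <- tibble::as_tibble(bank)[, c("item", bank_par_cols)]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      label = attr(bank, "label") %||% "item bank",
      n_categories = 5L,
      seed = attr(bank, "seed"),
      items = df
    )
    # I(17) = 17 significant digits: exact round trip for doubles
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  } else {
    # %.17g keeps the round trip exact to the last bit of a double
    out <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.double), ~ sprintf("%.17g", .x)))
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- tibble::as_tibble(payload$items)
    bank <- as_item_bank(df, label = payload$label %||% "item bank")
    attr(bank, "seed") <- payload$seed
    bank
  } else {
    # parse through base strtod (correctly rounded) for an exact round trip
    df <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()))
    df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.numeric),
                        item = as.integer(.data$item))
    as_item_bank(df, label = "item bank")
  }
}

#' Plot an item bank's parameter layout
#'
#' Thresholds per item on the latent scale, colored by threshold index, with
#' point size mapped to the discrimination parameter. Makes the quasi-trait
#' character visible: most thresholds sit above zero.
#'
#' @param object An `item_bank`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot item_bank
#' @export
autoplot.item_bank <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("b1", "b2", "b3", "b4")),
                        names_to = "threshold", values_to = "b")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$b, y = factor(.data$item),
                                     colour = .data$threshold,
                                     size = .data$a)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_size_continuous(range = c(0.5, 2.5)) +
    ggplot2::labs(x = expression(theta), y = "item",
                  title = attr(object, "label") %||% "item bank") +
    ggplot2::theme_minimal()
}
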