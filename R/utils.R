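# round() half-to-even would make group counts depend on parity; the study
# design wants deterministic half-up counts.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic child seeds so every stage/condition has its own RNG branch
# that can be re-run in isolation. Kept below 2^31 - 1.
seed_branch <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) %% 1e6) * 2039 + index * 7919) %% 2147483647L
}

# Run `expr` under `seed` without disturbing the caller's RNG state; a NULL
# seed means "use the current RNG stream".
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number strictly between 0 and 1, got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, min))
  }
  invisible(as.integer(x))
}
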