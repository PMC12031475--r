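# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All package randomness funnels through this so
# that no stage reads global entropy.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed; keeps results in 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 1000003 * as.double(index)) %% 2147483647L)
}

stopf <- function(fmt, ..., class = "semgrip_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be positive", name)
  if (nonneg && x < 0) stopf("`%s` must be non-negative", name)
  invisible(x)
}

is_sorted <- function(x) !is.unsorted(x, strictly = FALSE)
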