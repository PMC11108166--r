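# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
safe_div <- function(num, den) if (den == 0) 0 else num / den

# Deterministic child-seed derivation. Mixes a master seed with a variable
# number of integer indices via modular multiply-add against a Mersenne
# prime; all arithmetic stays below 2^53 so doubles are exact, and the
# result is a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.double(seed) %% 2147483629) + 1
  for (i in idx) {
    h <- (h * 48271 + as.double(i) + 1) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state (the global .Random.seed is saved and restored).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Classed errors so callers and tests can discriminate failure modes.
rncv_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rncv_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
}
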