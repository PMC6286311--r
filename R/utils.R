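## shared internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so seeded functions do not clobber the session RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a component seed from a global seed and a label.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)

is_scalar <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
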