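# Internal helpers: scoped RNG and deterministic seed fan-out.

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic seed splitting: one global seed fans out to per-stage seeds
# keyed by a short text tag, so any stage can be re-run in isolation.
# Constants are from a splitmix-style multiplicative hash, reduced mod 2^31-1
# so the result is always a valid 32-bit R seed.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((h * 48271) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
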