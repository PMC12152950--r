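#' @keywords internal
"_PACKAGE"

## Deterministic 31-bit string hash (polynomial, base 31). Used wherever a
## stable id -> integer mapping is needed (fingerprint bit hashing, per-molecule
## RNG streams). Double arithmetic keeps intermediates < 2^53.
.str_hash <- function(s, mod = 2^31 - 1) {
  codes <- utf8ToInt(s)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% mod
  h
}

.hash_ints <- function(ints, mod = 2^31 - 1) {
  h <- 7
  for (k in ints) h <- (h * 31 + (k %% mod)) %% mod
  h
}

## Evaluate `expr` under a fixed RNG state without disturbing the caller's.
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647), expr)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)
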