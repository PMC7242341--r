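# Internal helpers: seeded evaluation and deterministic seed derivation.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Mix a master seed with stream indices into a 31-bit sub-seed. The
# multiplier keeps products below 2^53 (2^31 * 69069 < 1.5e14) so double
# arithmetic stays exact; two mixing rounds decorrelate nearby indices.
deriveSeed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + (as.numeric(k) %% 1000003) + 1) %% 2147483563
    h <- (h * 69069 + 12345) %% 2147483563
  }
  as.integer(h)
}

# FNV-1a hash of a string, reported as 8 hex digits; used to fingerprint
# run configurations in output files. Arithmetic split into 16-bit halves so
# all intermediates stay exactly representable as doubles.
fnv1aHash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.logMsg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
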