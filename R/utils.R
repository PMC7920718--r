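#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the global RNG seeded to `seed`, restoring the previous
# RNG state afterwards so package functions never clobber the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 9973) %% 2147483629
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# report files with a config fingerprint without a hashing dependency.
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte because b < 256; keeps h exact in doubles
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  # h can exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
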