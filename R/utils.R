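# Internal helpers: deterministic hashing and seed sub-streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash over a character scalar; returns hex string.
# Used for config/rule hashes in output headers (no external digest dependency).
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a double below 2^32
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply split into 16-bit halves to stay exact
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  # format as hex from two 16-bit halves (h may exceed .Machine$integer.max)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a reproducible integer sub-seed from a master seed and a stream name.
# Adding a new named stream never perturbs draws of existing streams.
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- strtoi(substr(fnv1a(as.character(name)), 1, 7), base = 16L)
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  if (!is.null(seed)) set.seed(substream_seed(seed, name))
  force(expr)
}

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

pkg_version_string <- function() {
  as.character(utils::packageVersion("gmshap"))
}
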