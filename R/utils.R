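#' @keywords internal
"_PACKAGE"

# The 20 standard one-letter amino-acid codes, alphabetical.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

K_NUMBER_REGEX <- "^K[0-9]{5}$"

is_k_number <- function(x) grepl(K_NUMBER_REGEX, x)

# 32-bit modular multiply and xor on doubles (exact below 2^53), used by
# the string hash below.
mul32 <- function(h, p) {
  hi <- h %/% 65536
  lo <- h %% 65536
  (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
}

xor32 <- function(a, b) {
  ahi <- a %/% 65536; alo <- a %% 65536
  bhi <- b %/% 65536; blo <- b %% 65536
  bitwXor(as.integer(ahi), as.integer(bhi)) * 65536 +
    bitwXor(as.integer(alo), as.integer(blo))
}

#' 32-bit string hash (FNV-1a with an avalanche finalizer)
#'
#' Stable, platform-independent string hash used to derive deterministic
#' per-operation RNG seeds and the mock embedder's k-mer directions. Pure
#' arithmetic on doubles (exact below 2^53), so the value is identical on
#' every platform. The murmur-style finalizer breaks the affine structure
#' plain FNV-1a leaves between keys sharing a prefix or suffix, which
#' matters for the statistical independence of hash-derived directions.
#'
#' @param s A single character string.
#' @return A double in `[0, 2^32)`.
#' @keywords internal
fnv1a32 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256L))
    h <- mul32(h, 16777619)
  }
  # murmur3 fmix32 finalizer
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)
  h <- xor32(h, h %/% 8192)
  h <- mul32(h, 3266489909)
  xor32(h, h %/% 65536)
}

# Deterministic per-operation seed derived from a user seed and an operation
# tag, so each operation draws from its own named PRNG stream.
op_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) + fnv1a32(tag)) %% 2147483647)
}

# Uniform deviate in (0, 1) from a string key (never exactly 0 or 1).
hash_unif <- function(key) (fnv1a32(key) + 0.5) / 4294967296

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
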