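#' Derive a per-subject RNG seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream index so every subject
#' (or fixture) gets an independent, reproducible RNG stream.  The result is
#' kept inside the 32-bit signed integer range accepted by [set.seed()].
#'
#' @param seed master seed (single integer-valued number).
#' @param index stream index (non-negative integer; e.g. subject number).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  # multiplicative mixing modulo a Mersenne prime keeps streams decorrelated
  m <- 2147483647
  s <- (abs(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + (index + 1) * 69621) %% m
  as.integer(s)
}

# FNV-1a over a character scalar; used for config hashes in run manifests.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fd4d <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_fd4d("%s must be a numeric matrix", what)
  if (anyNA(x) || any(!is.finite(x)))
    stop_fd4d("%s contains non-finite entries", what)
  invisible(x)
}
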