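#' @keywords internal
#' @useDynLib cbptsdscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal helpers shared across modules. All randomness in the package flows
# through `with_seed()` so that the caller's RNG stream is never disturbed and
# every operation is reproducible from one explicitly passed integer seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `expr`, and restores the previous RNG state on exit.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded sub-seed for a pipeline stage of a repeat. Keeps derived
# seeds well inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

#' FNV-1a 32-bit hash of a character string
#'
#' Used for content-addressed embedding-cache keys and to seed the offline
#' deterministic embedder. Operates on UTF-8 bytes; returns a non-negative
#' double below 2^32 (R has no native unsigned 32-bit integer).
#'
#' @param text character scalar.
#' @return non-negative numeric hash value.
#' @keywords internal
fnv1a32 <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(text)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# XOR for doubles holding 32-bit values (bitwXor() needs integers).
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  xhi <- bitwXor(as.integer(hi_a), as.integer(hi_b))
  xlo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  as.numeric(xhi) * 65536 + as.numeric(xlo)
}

hash_hex <- function(text) {
  h <- fnv1a32(text)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

count_words <- function(text) {
  # Whitespace-delimited tokens; punctuation stays attached.
  n <- lengths(regmatches(text, gregexpr("\\S+", text)))
  n[is.na(text) | text == ""] <- 0L
  as.integer(n)
}
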