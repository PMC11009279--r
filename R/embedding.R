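# Embedding backends: a uniform contract turning narratives into
# fixed-dimension numeric vectors, an offline deterministic embedder for
# tests, and a content-addressed single-file cache.
#
# An embedder is a list with class "embedder":
#   name         character tag (cache key component)
#   dimension    positive integer output length
#   deterministic TRUE if identical text always yields identical vectors
#   embed_fn     function(texts) -> numeric matrix (length(texts) x dimension)

# Token budget mirroring the 16k-context chat model: longer inputs error
# rather than silently truncating.
DEFAULT_TOKEN_BUDGET <- 16384L

#' Construct an embedder
#'
#' @param name character tag identifying the model; part of the cache key.
#' @param dimension positive integer output dimension.
#' @param embed_fn function taking a character vector and returning a numeric
#'   matrix with one row per text and `dimension` columns.
#' @param deterministic logical; TRUE if the backend is pure in the text.
#' @param token_budget maximum whitespace-token count accepted per text.
#' @return an `embedder` object.
#' @export
embedder <- function(name, dimension, embed_fn, deterministic = TRUE,
                     token_budget = DEFAULT_TOKEN_BUDGET) {
  stopifnot(is.character(name), length(name) == 1L,
            dimension >= 1L, is.function(embed_fn))
  structure(list(name = name, dimension = as.integer(dimension),
                 deterministic = isTRUE(deterministic),
                 token_budget = as.integer(token_budget),
                 embed_fn = embed_fn),
            class = "embedder")
}

#' Offline deterministic embedder
#'
#' Hashes each text (FNV-1a) to seed a private RNG, draws `dimension`
#' standard-normal values, and scales to unit norm. Pure in
#' (text, seed, dimension); useful for tests and offline runs. Carries no
#' class signal -- pair it with [generate_embeddings()] when separation is
#' needed.
#'
#' @param dimension output dimension (default 1536, matching the
#'   text-embedding-ada-002 contract).
#' @param seed integer mixed into every text hash.
#' @return an `embedder`.
#' @export
offline_embedder <- function(dimension = 1536L, seed = 0L) {
  dimension <- as.integer(dimension)
  force(seed)
  embed_fn <- function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dimension)
    for (i in seq_along(texts)) {
      h <- (fnv1a32(texts[i]) + as.numeric(seed)) %% 2147483647
      v <- with_seed(h, stats::rnorm(dimension))
      out[i, ] <- v / sqrt(sum(v^2))
    }
    out
  }
  embedder(sprintf("offline-hash-d%d-s%d", dimension, as.integer(seed)),
           dimension, embed_fn)
}

#' Embed a batch of texts
#'
#' Validates inputs, enforces the token budget, calls the backend, and
#' checks the output contract (one finite vector of the declared dimension
#' per text, order preserved).
#'
#' @param texts character vector of non-empty texts.
#' @param emb an `embedder`.
#' @return numeric matrix, `length(texts)` rows by `emb$dimension` columns,
#'   rownames unset.
#' @export
embed_batch <- function(texts, emb) {
  stopifnot(inherits(emb, "embedder"))
  if (length(texts) == 0L) stop_validation("no texts to embed")
  if (any(!nzchar(texts) | is.na(texts)))
    stop_validation("empty text at position %d", which(!nzchar(texts) | is.na(texts))[1L])
  wc <- count_words(texts)
  if (any(wc > emb$token_budget))
    stop_validation("text at position %d exceeds the token budget (%d > %d)",
                    which(wc > emb$token_budget)[1L], max(wc), emb$token_budget)
  out <- emb$embed_fn(texts)
  if (!is.matrix(out) || nrow(out) != length(texts) || ncol(out) != emb$dimension)
    stop_validation("backend '%s' violated its contract: expected %d x %d matrix",
                    emb$name, length(texts), emb$dimension)
  if (!all(is.finite(out)))
    stop_validation("backend '%s' returned non-finite values", emb$name)
  dimnames(out) <- NULL
  out
}

# ---- content-addressed cache -------------------------------------------------
# Format (versioned): JSON Lines. First line is a header object
#   {"format":"cbptsdscreen-embedding-cache","version":1}
# then one object per vector:
#   {"key":"<model>:<fnv1a32 hex of text>","dim":d,"b64":"<base64 doubles>"}
# Doubles are serialized with writeBin (native endianness of the writing
# machine) and base64-encoded, so read-back is bit-exact.

cache_key <- function(emb_name, text) paste0(emb_name, ":", hash_hex(text))

encode_vec <- function(v) jsonlite::base64_enc(writeBin(as.double(v), raw()))
decode_vec <- function(b64, d) readBin(jsonlite::base64_dec(b64), "double", n = d)

read_cache <- function(path) {
  store <- new.env(parent = emptyenv())
  if (!file.exists(path)) return(store)
  ok <- tryCatch({
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L) stop("empty cache")
    header <- jsonlite::fromJSON(lines[1L])
    if (!identical(header$format, "cbptsdscreen-embedding-cache"))
      stop("unrecognized cache header")
    for (l in lines[-1L]) {
      rec <- jsonlite::fromJSON(l)
      assign(rec$key, decode_vec(rec$b64, rec$dim), envir = store)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    warning(sprintf("embedding cache '%s' is corrupt; rebuilding", path),
            call. = FALSE)
    store <- new.env(parent = emptyenv())
  }
  store
}

write_cache <- function(store, path) {
  keys <- sort(ls(store))
  header <- as.character(jsonlite::toJSON(
    list(format = "cbptsdscreen-embedding-cache", version = 1L),
    auto_unbox = TRUE))
  lines <- vapply(keys, function(k) {
    v <- get(k, envir = store)
    as.character(jsonlite::toJSON(
      list(key = k, dim = length(v), b64 = encode_vec(v)), auto_unbox = TRUE))
  }, character(1))
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Embed texts through a content-addressed cache
#'
#' Results are identical to [embed_batch()]; texts whose
#' (embedder name, content hash) key is already present in the cache file are
#' served from it, and only the misses reach the backend. The cache file is
#' rewritten after new vectors are added. A corrupt cache is rebuilt with a
#' warning.
#'
#' @inheritParams embed_batch
#' @param cache_path path to the cache file (created if absent).
#' @return numeric matrix as from [embed_batch()].
#' @export
cached_embed <- function(texts, emb, cache_path) {
  stopifnot(inherits(emb, "embedder"))
  store <- read_cache(cache_path)
  keys <- vapply(texts, function(t) cache_key(emb$name, t), character(1),
                 USE.NAMES = FALSE)
  hit <- vapply(keys, function(k) exists(k, envir = store), logical(1))
  out <- matrix(NA_real_, nrow = length(texts), ncol = emb$dimension)
  if (any(hit)) {
    got <- t(vapply(keys[hit], function(k) get(k, envir = store),
                    numeric(emb$dimension)))
    if (any(!is.finite(got)) || ncol(got) != emb$dimension)
      stop_validation("cached vectors do not match dimension %d", emb$dimension)
    out[hit, ] <- got
  }
  if (any(!hit)) {
    fresh <- embed_batch(texts[!hit], emb)
    out[!hit, ] <- fresh
    miss_keys <- keys[!hit]
    for (j in seq_along(miss_keys))
      assign(miss_keys[j], fresh[j, ], envir = store)
    write_cache(store, cache_path)
  }
  dimnames(out) <- NULL
  out
}
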