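# Pairwise data augmentation. Three pair sets are built from the training
# split: set1 = all within-class pairs of class 1, set2 = all within-class
# pairs of class 0 (both labeled 1, "similar"), and set3 = randomly sampled
# cross-class pairs labeled 0 ("dissimilar"), sized |set1| + |set2| by
# default. Each pair's feature is the Hadamard (elementwise) product of the
# two narrative embeddings, so at n train narratives per class the augmented
# set has 4 * choose(n, 2) examples, balanced by construction.

#' Hadamard (elementwise) product feature of two embedding vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return numeric vector `u * v`.
#' @export
hadamard_feature <- function(u, v) {
  if (length(u) != length(v))
    stop_validation("vector length mismatch: %d vs %d", length(u), length(v))
  u * v
}

#' Enumerate all unordered distinct pairs of IDs
#'
#' @param ids vector of at least two unique IDs.
#' @return two-column character matrix (`u_id`, `v_id`) with
#'   `choose(length(ids), 2)` rows; within each row `u_id < v_id`, so pairs
#'   are canonical and duplicate-free in either order.
#' @export
enumerate_within_pairs <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) < 2L)
    stop_validation("need at least 2 IDs to form pairs, got %d", length(ids))
  if (anyDuplicated(ids)) stop_validation("IDs must be unique")
  m <- t(utils::combn(sort(ids), 2L))
  colnames(m) <- c("u_id", "v_id")
  m
}

#' Sample distinct cross-class pairs without replacement
#'
#' Draws `k` distinct (class-1, class-0) pairs uniformly from the full cross
#' product. Deterministic given `seed`.
#'
#' @param ids_class1,ids_class0 ID vectors for each class.
#' @param k number of pairs; at most `length(ids_class1) * length(ids_class0)`.
#' @param seed integer seed.
#' @return two-column character matrix (`u_id` from class 1, `v_id` from
#'   class 0) with `k` rows.
#' @export
sample_cross_pairs <- function(ids_class1, ids_class0, k, seed) {
  n1 <- length(ids_class1); n0 <- length(ids_class0)
  total <- n1 * n0
  if (k < 1L || k > total)
    stop_validation("k = %d out of range; at most %d distinct cross pairs exist",
                    k, total)
  idx <- with_seed(seed, sample.int(total, k))
  i1 <- ((idx - 1L) %% n1) + 1L
  i0 <- ((idx - 1L) %/% n1) + 1L
  m <- cbind(u_id = as.character(ids_class1)[i1],
             v_id = as.character(ids_class0)[i0])
  m
}

#' Build the augmented pair training set
#'
#' Enumerates both within-class pair sets over the training split, samples
#' the cross-class set (default size `|set1| + |set2|`), and computes the
#' Hadamard feature for every pair.
#'
#' @param split a `split_plan` from [make_split()].
#' @param vectors numeric matrix of embeddings with rownames = subject IDs;
#'   every train ID must be present.
#' @param seed integer seed for the cross-pair sample.
#' @param n_cross size of the dissimilar set; defaults to the combined size
#'   of the two similar sets.
#' @return a `pair_set` list: `u_id`, `v_id`, `pair_label` (1 similar /
#'   0 dissimilar), `provenance` (set1/set2/set3), and feature matrix `z`
#'   (one row per pair).
#' @export
build_training_set <- function(split, vectors, seed, n_cross = NULL) {
  stopifnot(inherits(split, "split_plan"))
  ids1 <- split$train_ids$`1`; ids0 <- split$train_ids$`0`
  need <- c(ids1, ids0)
  absent <- setdiff(need, rownames(vectors))
  if (length(absent))
    stop_validation("no embedding vector for subject '%s'", absent[1L])
  set1 <- enumerate_within_pairs(ids1)
  set2 <- enumerate_within_pairs(ids0)
  if (is.null(n_cross)) n_cross <- nrow(set1) + nrow(set2)
  set3 <- sample_cross_pairs(ids1, ids0, n_cross, seed)
  u_id <- c(set1[, 1L], set2[, 1L], set3[, 1L])
  v_id <- c(set1[, 2L], set2[, 2L], set3[, 2L])
  z <- vectors[u_id, , drop = FALSE] * vectors[v_id, , drop = FALSE]
  dimnames(z) <- NULL
  structure(list(
    u_id = u_id, v_id = v_id,
    pair_label = rep(c(1L, 0L), c(nrow(set1) + nrow(set2), nrow(set3))),
    provenance = rep(c("set1", "set2", "set3"),
                     c(nrow(set1), nrow(set2), nrow(set3))),
    z = z, seed = as.integer(seed)
  ), class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf(
    "pair set: %d examples (%s), feature dim %d, %d similar / %d dissimilar\n",
    length(x$pair_label),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    ncol(x$z), sum(x$pair_label == 1L), sum(x$pair_label == 0L)))
  invisible(x)
}

#' Write a pair manifest (without features) as JSONL
#' @param pairs a `pair_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_manifest <- function(pairs, path) {
  lines <- vapply(seq_along(pairs$pair_label), function(i) {
    as.character(jsonlite::toJSON(list(
      u_id = pairs$u_id[i], v_id = pairs$v_id[i],
      provenance = pairs$provenance[i], pair_label = pairs$pair_label[i]
    ), auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
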