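# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# exhaustive double-loop enumeration of unordered distinct pairs
oracle_pairs <- function(ids) {
  ids <- sort(as.character(ids))
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) out[[length(out) + 1L]] <- c(ids[i], ids[j])
    }
  }
  do.call(rbind, out)
}

# generic trapezoidal ROC AUC from raw scores (here: predicted labels used
# as scores) and true labels
oracle_trapezoid_auc <- function(scores, truth) {
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- tpr <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    pred_pos <- scores >= thresholds[k]
    tpr[k] <- sum(pred_pos & truth == 1) / sum(truth == 1)
    fpr[k] <- sum(pred_pos & truth == 0) / sum(truth == 0)
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# expand a confusion table into per-observation label-score vectors and run
# the generic ROC routine on them
oracle_auc_from_counts <- function(tp, fp, tn, fn) {
  truth <- rep(c(1, 1, 0, 0), c(tp, fn, tn, fp))
  scores <- rep(c(1, 0, 0, 1), c(tp, fn, tn, fp))
  oracle_trapezoid_auc(scores, truth)
}

# nearest-centroid classification accuracy on raw vectors
oracle_centroid_accuracy <- function(vectors, labels) {
  mu1 <- colMeans(vectors[labels == 1L, , drop = FALSE])
  mu0 <- colMeans(vectors[labels == 0L, , drop = FALSE])
  d1 <- rowSums(sweep(vectors, 2L, mu1)^2)
  d0 <- rowSums(sweep(vectors, 2L, mu0)^2)
  mean(ifelse(d1 < d0, 1L, 0L) == labels)
}

# small balanced corpus for unit tests; word counts straddle the 30-word
# filter when requested
make_test_corpus <- function(n = 20L, seed = 1L, words_each = 35L) {
  cfg <- synth_config(n_subjects = n, prevalence = 0.5, dimension = 8,
                      delta = 1, min_words = words_each,
                      max_words = words_each, seed = seed)
  generate_corpus(cfg)
}
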