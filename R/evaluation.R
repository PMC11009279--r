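# Evaluation: confusion-matrix metrics for label-output classifiers, the
# two-point ("stepped") ROC AUC, and the repeated-resampling evaluation that
# re-runs down-sampling, splitting, augmentation, training, and testing with
# per-repeat seeds.

#' Confusion counts for a binary classifier (class 1 = positive)
#'
#' @param tp,fp,tn,fn non-negative integer counts; total must be positive.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = unname(tp), fp = unname(fp), tn = unname(tn), fn = unname(fn))
  if (any(counts < 0) || any(counts != as.integer(counts)))
    stop_validation("confusion counts must be non-negative integers")
  if (sum(counts) == 0) stop_validation("confusion counts sum to zero")
  counts <- as.list(stats::setNames(as.integer(counts), names(counts)))
  structure(counts, class = "confusion_counts")
}

#' Counts from predicted and true label vectors
#' @param predicted,truth 0/1 integer vectors of equal length.
#' @return a `confusion_counts` list.
#' @export
confusion_from_labels <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  confusion_counts(tp = sum(predicted == 1L & truth == 1L),
                   fp = sum(predicted == 1L & truth == 0L),
                   tn = sum(predicted == 0L & truth == 0L),
                   fn = sum(predicted == 0L & truth == 1L))
}

#' Sensitivity, specificity, precision and F1 from confusion counts
#'
#' F1 is the positive-class F1 (harmonic mean of precision and sensitivity).
#' A metric whose denominator is zero is reported as `NA` ("undefined"),
#' never coerced to 0.
#'
#' @param c a `confusion_counts`.
#' @return named list: `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
confusion_metrics <- function(c) {
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  sens <- rate(c$tp, c$tp + c$fn)
  spec <- rate(c$tn, c$tn + c$fp)
  prec <- rate(c$tp, c$tp + c$fp)
  f1 <- if (is.na(sens) || is.na(prec)) NA_real_
        else if (sens + prec == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

#' AUC of a label-output ("stepped") ROC
#'
#' A classifier that emits only 0/1 labels yields a two-segment ROC through
#' the single operating point (1 - specificity, sensitivity); its area
#' reduces to (sensitivity + specificity) / 2.
#'
#' @param c a `confusion_counts`.
#' @return AUC in \[0, 1\], or `NA` if either rate is undefined.
#' @export
auc_binary <- function(c) {
  m <- confusion_metrics(c)
  if (is.na(m$sensitivity) || is.na(m$specificity)) return(NA_real_)
  (m$sensitivity + m$specificity) / 2
}

# One full Model-3 pipeline run on a pre-balanced corpus: split, augment,
# train, classify the held-out test narratives by reference voting.
run_model3_once <- function(balanced, vectors, spec, seed,
                            train_per_class = NULL) {
  split <- make_split(balanced, train_per_class = train_per_class, seed = seed)
  pairs <- build_training_set(split, vectors, seed = seed)
  spec$seed <- seed
  model <- train_pair_classifier(pairs, spec)
  refs <- list(`1` = vectors[split$train_ids$`1`, , drop = FALSE],
               `0` = vectors[split$train_ids$`0`, , drop = FALSE])
  test_ids <- c(split$test_ids$`1`, split$test_ids$`0`)
  truth <- rep(c(1L, 0L), c(length(split$test_ids$`1`), length(split$test_ids$`0`)))
  predicted <- vapply(test_ids, function(id)
    classify_narrative(model, vectors[id, ], refs)$class, integer(1))
  list(split = split, model = model,
       counts = confusion_from_labels(predicted, truth),
       predicted = stats::setNames(predicted, test_ids), truth = truth)
}

#' Repeated-resampling evaluation of the similarity pipeline
#'
#' Re-runs the entire Model-3 pipeline `n_repeats` times. Each repeat uses a
#' seed derived from `seed` and the repeat index, and redraws the
#' majority-class down-sample and the train/test split, so different
#' narratives are seen across repeats. Per-repeat confusion counts and
#' metrics are recorded along with their means.
#'
#' @param corpus a filtered `narrative_corpus` (both classes present; run
#'   [filter_min_words()] first).
#' @param vectors embedding matrix with rownames = subject IDs covering
#'   every record.
#' @param spec a `classifier_spec` matching `ncol(vectors)`.
#' @param n_repeats number of repeats (default 10).
#' @param seed master seed; repeat `i` uses `derive_seed(seed, i)`.
#' @param train_per_class per-class training count, or `NULL` for the
#'   default 17/19 rule.
#' @return an `eval_report` list: `per_repeat` data.frame (seed, counts,
#'   metrics, AUC), `aggregate` (means; `NA` ignored with a flag),
#'   `pooled` metrics over summed counts, `n_repeats`, `seed`.
#' @export
repeat_evaluation <- function(corpus, vectors, spec, n_repeats = 10L,
                              seed = 1L, train_per_class = NULL) {
  stopifnot(n_repeats >= 1L)
  absent <- setdiff(corpus$subject_id, rownames(vectors))
  if (length(absent))
    stop_validation("no embedding vector for subject '%s'", absent[1L])
  rows <- vector("list", n_repeats)
  pooled <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_len(n_repeats)) {
    seed_i <- derive_seed(seed, i)
    res <- tryCatch({
      balanced <- balance_downsample(corpus, seed = seed_i)
      run_model3_once(balanced, vectors, spec, seed = seed_i,
                      train_per_class = train_per_class)
    }, error = function(e)
      stop(sprintf("repeat %d failed: %s", i, conditionMessage(e)), call. = FALSE))
    m <- confusion_metrics(res$counts)
    rows[[i]] <- data.frame(repeat_index = i, seed = seed_i,
                            tp = res$counts$tp, fp = res$counts$fp,
                            tn = res$counts$tn, fn = res$counts$fn,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            precision = m$precision, f1 = m$f1,
                            auc = auc_binary(res$counts))
    pooled <- pooled + unlist(res$counts)
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "precision", "f1", "auc")
  aggregate <- as.list(colMeans(per_repeat[metric_cols]))
  pooled_counts <- confusion_counts(pooled["tp"], pooled["fp"],
                                    pooled["tn"], pooled["fn"])
  pooled_metrics <- confusion_metrics(pooled_counts)
  pooled_metrics$auc <- auc_binary(pooled_counts)
  structure(list(per_repeat = per_repeat, aggregate = aggregate,
                 pooled = pooled_metrics, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation report: %d repeats (seed %d)\n", x$n_repeats, x$seed))
  a <- x$aggregate
  cat(sprintf("  mean AUC %s | F1 %s | sensitivity %s | specificity %s\n",
              fmt2(a$auc), fmt2(a$f1), fmt2(a$sensitivity), fmt2(a$specificity)))
  invisible(x)
}

# half-even rounding to 2 decimals for report display; raw values stay in JSON
fmt2 <- function(x) {
  if (is.null(x) || is.na(x)) return("NA")
  sprintf("%.2f", round(x, 2))
}

#' Serialize an evaluation report to JSON (raw, unrounded values)
#' @param report an `eval_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  payload <- list(format = "cbptsdscreen-eval-report", version = 1L,
                  n_repeats = report$n_repeats, seed = report$seed,
                  per_repeat = report$per_repeat,
                  aggregate = report$aggregate, pooled = report$pooled)
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                           digits = NA, na = "null")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Write the summary table (AUC, F1, sensitivity, specificity) as CSV
#' @param reports named list of `eval_report`s (names become the model column).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    a <- reports[[nm]]$aggregate
    data.frame(model = nm, auc = round(a$auc, 2), f1 = round(a$f1, 2),
               sensitivity = round(a$sensitivity, 2),
               specificity = round(a$specificity, 2))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
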