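# Corpus handling: PCL-5 scoring, provisional case labeling, word-count
# filtering, class balancing by down-sampling, and train/test splitting.
#
# A corpus is a plain data.frame with class "narrative_corpus" and columns
#   subject_id, narrative, pcl5_01 .. pcl5_20, pcl5_total, label, word_count
# PCL-5 items are integers 0..4 or NA (missing; coded as 0 when scoring).

PCL5_N_ITEMS <- 20L
PCL5_CUTOFF <- 31L
pcl5_cols <- function() sprintf("pcl5_%02d", seq_len(PCL5_N_ITEMS))

#' Score a PCL-5 item response vector
#'
#' Sums the 20 item severities (each 0-4). Missing items contribute 0, the
#' convention used when respondents skip items; the resulting total is a
#' provisional severity score in 0-80.
#'
#' @param items numeric vector of exactly 20 entries, each an integer in
#'   0..4 or `NA` for a missing item.
#' @return integer total in \[0, 80\].
#' @examples
#' score_pcl5(rep(4, 20))        # 80
#' score_pcl5(c(rep(3, 10), rep(NA, 10)))  # 30: missing coded as 0
#' @export
score_pcl5 <- function(items) {
  if (length(items) != PCL5_N_ITEMS)
    stop_validation("PCL-5 response must have %d items, got %d",
                    PCL5_N_ITEMS, length(items))
  present <- !is.na(items)
  vals <- items[present]
  bad <- which(present)[!(vals == as.integer(vals) & vals >= 0 & vals <= 4)]
  if (length(bad))
    stop_validation("PCL-5 item %d has invalid value %s (must be integer 0-4 or NA)",
                    bad[1L], format(items[bad[1L]]))
  as.integer(sum(items, na.rm = TRUE))
}

#' Provisional CB-PTSD case label from a PCL-5 total
#'
#' Applies the screening cutoff: totals of 31 or more are labeled class 1
#' (probable CB-PTSD), lower totals class 0. The label is provisional, not a
#' clinical diagnosis.
#'
#' @param total integer PCL-5 total in \[0, 80\] (vectorized).
#' @return integer vector of 0/1 labels.
#' @export
label_case <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 80))
    stop_validation("PCL-5 total must be in [0, 80]")
  as.integer(total >= PCL5_CUTOFF)
}

#' Assemble a validated narrative corpus
#'
#' Builds the canonical corpus data.frame from raw columns, deriving
#' `pcl5_total` (missing items coded 0), `label` (cutoff 31), and
#' `word_count` (whitespace-delimited tokens). Duplicate subject IDs are a
#' hard error: silent duplicates could leak between train and test splits.
#'
#' @param subject_id character vector of unique IDs.
#' @param narrative character vector of free-text narratives.
#' @param pcl5 numeric matrix or data.frame with 20 columns of item
#'   responses (0-4 or NA), rows aligned with `subject_id`.
#' @return a `narrative_corpus` data.frame.
#' @export
narrative_corpus <- function(subject_id, narrative, pcl5) {
  subject_id <- as.character(subject_id)
  narrative <- as.character(narrative)
  pcl5 <- as.matrix(pcl5)
  storage.mode(pcl5) <- "double"
  n <- length(subject_id)
  if (length(narrative) != n || nrow(pcl5) != n)
    stop_validation("subject_id, narrative and pcl5 must have matching lengths")
  if (ncol(pcl5) != PCL5_N_ITEMS)
    stop_validation("pcl5 must have %d columns, got %d", PCL5_N_ITEMS, ncol(pcl5))
  dup <- subject_id[duplicated(subject_id)]
  if (length(dup))
    stop_validation("duplicate subject_id: %s", dup[1L])
  totals <- vapply(seq_len(n), function(i) score_pcl5(pcl5[i, ]), integer(1))
  out <- data.frame(subject_id = subject_id, narrative = narrative,
                    stringsAsFactors = FALSE)
  colnames(pcl5) <- pcl5_cols()
  out <- cbind(out, as.data.frame(pcl5))
  out$pcl5_total <- totals
  out$label <- label_case(totals)
  out$word_count <- count_words(narrative)
  class(out) <- c("narrative_corpus", "data.frame")
  out
}

#' @export
print.narrative_corpus <- function(x, ...) {
  cat(sprintf("narrative corpus: %d records (%d class 1, %d class 0)\n",
              nrow(x), sum(x$label == 1L), sum(x$label == 0L)))
  cat(sprintf("  word count: median %s | PCL-5 total: median %s (cutoff %d)\n",
              stats::median(x$word_count), stats::median(x$pcl5_total),
              PCL5_CUTOFF))
  invisible(x)
}

#' Read a corpus from CSV
#'
#' Expects a UTF-8 header row `subject_id, narrative, pcl5_01..pcl5_20`.
#' Empty fields or the strings `NA`/`null` in item columns are treated as
#' missing items.
#'
#' @param path CSV file path.
#' @return a `narrative_corpus`.
#' @export
read_corpus_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         encoding = "UTF-8", check.names = FALSE)
  corpus_from_raw(raw, path)
}

#' Read a corpus from JSON Lines
#'
#' One JSON object per line with keys `subject_id`, `narrative`,
#' `pcl5_01`..`pcl5_20`; JSON `null` marks a missing item.
#'
#' @param path JSONL file path.
#' @return a `narrative_corpus`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
  raw <- do.call(rbind, lapply(rows, function(r) {
    r <- lapply(r, function(v) if (is.null(v)) NA else v)
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  corpus_from_raw(raw, path)
}

corpus_from_raw <- function(raw, path) {
  need <- c("subject_id", "narrative", pcl5_cols())
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_validation("%s: missing columns: %s", path,
                    paste(missing_cols, collapse = ", "))
  items <- raw[, pcl5_cols(), drop = FALSE]
  items[] <- lapply(items, function(v) {
    v <- as.character(v)
    v[v %in% c("", "NA", "null", "NULL")] <- NA
    suppressWarnings(as.numeric(v))
  })
  narrative_corpus(raw$subject_id, raw$narrative, items)
}

#' Write a corpus to CSV (UTF-8, missing items as empty fields)
#' @param corpus a `narrative_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_csv <- function(corpus, path) {
  cols <- c("subject_id", "narrative", pcl5_cols())
  utils::write.csv(as.data.frame(corpus)[, cols], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop narratives shorter than a minimum word count
#'
#' Narratives under 30 words carry too little signal for meaningful
#' analysis, so the pipeline discards them before balancing. Order is
#' preserved; an empty result is allowed.
#'
#' @param corpus a `narrative_corpus`.
#' @param min_words minimum word count to keep (default 30).
#' @return the filtered corpus.
#' @export
filter_min_words <- function(corpus, min_words = 30L) {
  out <- corpus[corpus$word_count >= min_words, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balance classes by down-sampling the majority class
#'
#' Keeps the minority class in full and samples the majority class uniformly
#' without replacement down to the minority size. Deterministic given `seed`.
#'
#' @param corpus a `narrative_corpus` with both classes present.
#' @param seed integer seed.
#' @return balanced corpus (minority rows first, then sampled majority rows).
#' @export
balance_downsample <- function(corpus, seed) {
  n1 <- sum(corpus$label == 1L); n0 <- sum(corpus$label == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_validation("both classes must be non-empty (class 1: %d, class 0: %d)",
                    n1, n0)
  minority <- if (n1 <= n0) 1L else 0L
  k <- min(n1, n0)
  maj_idx <- which(corpus$label != minority)
  keep_maj <- with_seed(seed, sort(maj_idx[sample.int(length(maj_idx), k)]))
  out <- corpus[c(which(corpus$label == minority), keep_maj), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a balanced corpus into train and test sets per class
#'
#' Samples `train_per_class` records per class without replacement into the
#' training set; the remainder per class becomes the test set. The default
#' `train_per_class` generalizes the 190-per-class to 170-per-class design
#' as round(17/19 x per-class count).
#'
#' @param corpus balanced `narrative_corpus` (equal class counts).
#' @param train_per_class training records per class; must be below the
#'   per-class count.
#' @param seed integer seed.
#' @return a `split_plan` list with `train_ids`/`test_ids` (per class),
#'   `train_per_class` and `seed`.
#' @export
make_split <- function(corpus, train_per_class = NULL, seed = 1L) {
  n1 <- sum(corpus$label == 1L); n0 <- sum(corpus$label == 0L)
  if (n1 != n0)
    stop_validation("corpus must be balanced before splitting (%d vs %d)", n1, n0)
  if (is.null(train_per_class)) train_per_class <- as.integer(round(17 / 19 * n1))
  train_per_class <- as.integer(train_per_class)
  if (train_per_class < 1L || train_per_class >= n1)
    stop_validation("train_per_class (%d) must be in [1, %d]", train_per_class, n1 - 1L)
  pick <- with_seed(seed, {
    lapply(c(`1` = 1L, `0` = 0L), function(cl) {
      ids <- corpus$subject_id[corpus$label == cl]
      tr <- sample(ids, train_per_class)
      list(train = sort(tr), test = sort(setdiff(ids, tr)))
    })
  })
  structure(list(
    train_ids = list(`1` = pick$`1`$train, `0` = pick$`0`$train),
    test_ids = list(`1` = pick$`1`$test, `0` = pick$`0`$test),
    train_per_class = train_per_class, seed = as.integer(seed)
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan: %d train / %d test per class (seed %d)\n",
              x$train_per_class, length(x$test_ids$`1`), x$seed))
  invisible(x)
}

#' Write balanced/split membership as a JSONL manifest
#' @param corpus the balanced corpus the split was drawn from.
#' @param split a `split_plan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(corpus, split, path) {
  assignment <- ifelse(corpus$subject_id %in% unlist(split$train_ids),
                       "train", "test")
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(subject_id = corpus$subject_id[i],
                          label = corpus$label[i],
                          split = assignment[i]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
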