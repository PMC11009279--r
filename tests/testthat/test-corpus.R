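# PCL-5 scoring, case labeling, filtering, balancing, splitting, and IO.

test_that("score_pcl5 sums items with missing coded as zero", {
  expect_identical(score_pcl5(rep(0, 20)), 0L)
  expect_identical(score_pcl5(rep(4, 20)), 80L)
  expect_identical(score_pcl5(c(rep(3, 10), rep(NA, 10))), 30L)
  expect_identical(score_pcl5(rep(NA_real_, 20)), 0L)
})

test_that("score_pcl5 rejects malformed responses, naming the slot", {
  expect_error(score_pcl5(rep(1, 19)), "20 items")
  expect_error(score_pcl5(c(rep(1, 19), 5)), "item 20")
  expect_error(score_pcl5(c(2.5, rep(1, 19))), "item 1")
  expect_error(score_pcl5(c(-1, rep(0, 19))), "item 1")
})

test_that("score_pcl5 is monotone in any item severity", {
  set.seed(11)
  for (rep_i in 1:25) {
    items <- sample(0:4, 20, replace = TRUE)
    items[sample(20, 3)] <- NA
    base <- score_pcl5(items)
    slot <- sample(which(!is.na(items) & items < 4), 1)
    bumped <- items
    bumped[slot] <- bumped[slot] + 1L
    expect_gt(score_pcl5(bumped), base)
  }
})

test_that("label_case applies the cutoff at 31", {
  expect_identical(label_case(c(30L, 31L, 0L, 80L)), c(0L, 1L, 0L, 1L))
  expect_error(label_case(81L), "0, 80")
  expect_error(label_case(-1L), "0, 80")
})

test_that("narrative_corpus derives totals, labels and word counts", {
  pcl5 <- rbind(rep(2, 20), c(rep(4, 10), rep(NA, 10)))
  corp <- narrative_corpus(c("a", "b"),
                           c("one two three", "  spaced   out  text "), pcl5)
  expect_identical(corp$pcl5_total, c(40L, 40L))
  expect_identical(corp$label, c(1L, 1L))
  expect_identical(corp$word_count, c(3L, 3L))
})

test_that("duplicate subject IDs are a hard error", {
  pcl5 <- matrix(0, 2, 20)
  expect_error(narrative_corpus(c("x", "x"), c("a b", "c d"), pcl5),
               "duplicate subject_id")
})

test_that("filter_min_words keeps exactly the long-enough records in order", {
  words <- function(k) paste(rep("w", k), collapse = " ")
  corp <- narrative_corpus(c("a", "b", "c"),
                           c(words(29), words(30), words(100)),
                           matrix(0, 3, 20))
  kept <- filter_min_words(corp)
  expect_identical(kept$subject_id, c("b", "c"))
  expect_identical(filter_min_words(kept)$subject_id, kept$subject_id)
  none <- filter_min_words(corp, min_words = 1000L)
  expect_identical(nrow(none), 0L)
})

test_that("balance_downsample equalizes classes deterministically", {
  cfg <- synth_config(n_subjects = 60, prevalence = 0.2, dimension = 4,
                      min_words = 30, max_words = 40, seed = 3)
  corp <- generate_corpus(cfg)
  bal1 <- balance_downsample(corp, seed = 9)
  bal2 <- balance_downsample(corp, seed = 9)
  expect_identical(bal1, bal2)
  expect_identical(sum(bal1$label == 1L), sum(bal1$label == 0L))
  expect_true(all(corp$subject_id[corp$label == 1L] %in% bal1$subject_id))
  bal3 <- balance_downsample(corp, seed = 10)
  expect_identical(sum(bal3$label == 1L), sum(bal3$label == 0L))
})

test_that("balance_downsample preserves labels and text and errors on one class", {
  corp <- make_test_corpus(n = 16, seed = 5)
  bal <- balance_downsample(corp, seed = 2)
  m <- match(bal$subject_id, corp$subject_id)
  expect_identical(bal$label, corp$label[m])
  expect_identical(bal$narrative, corp$narrative[m])
  only1 <- corp[corp$label == 1L, ]
  class(only1) <- class(corp)
  expect_error(balance_downsample(only1, 1), "non-empty")
})

test_that("make_split partitions each class and is seed-deterministic", {
  corp <- make_test_corpus(n = 20, seed = 7)
  bal <- balance_downsample(corp, seed = 1)
  n_class <- sum(bal$label == 1L)
  sp <- make_split(bal, train_per_class = n_class - 3L, seed = 4)
  sp2 <- make_split(bal, train_per_class = n_class - 3L, seed = 4)
  expect_identical(sp, sp2)
  for (cl in c("1", "0")) {
    ids <- sort(bal$subject_id[bal$label == as.integer(cl)])
    expect_identical(sort(c(sp$train_ids[[cl]], sp$test_ids[[cl]])), ids)
    expect_length(intersect(sp$train_ids[[cl]], sp$test_ids[[cl]]), 0)
    expect_length(sp$train_ids[[cl]], n_class - 3L)
  }
  expect_error(make_split(bal, train_per_class = n_class, seed = 1),
               "train_per_class")
})

test_that("default train_per_class follows the 17/19 rule", {
  corp <- synth_config(n_subjects = 380, prevalence = 0.5, dimension = 4,
                       min_words = 30, max_words = 35, seed = 2) |>
    generate_corpus()
  bal <- balance_downsample(corp, seed = 1)
  sp <- make_split(bal, seed = 1)
  expect_identical(sp$train_per_class,
                   as.integer(round(17 / 19 * sum(bal$label == 1L))))
})

test_that("CSV and JSONL round-trips preserve records and missing items", {
  pcl5 <- rbind(c(rep(3, 18), NA, NA), rep(1, 20))
  corp <- narrative_corpus(c("s1", "s2"),
                           c(paste(rep("word", 31), collapse = " "),
                             "short, with punctuation!"), pcl5)
  csv <- tempfile(fileext = ".csv")
  write_corpus_csv(corp, csv)
  back <- read_corpus_csv(csv)
  expect_identical(back$pcl5_total, corp$pcl5_total)
  expect_identical(back$label, corp$label)
  expect_identical(back$narrative, corp$narrative)
  expect_true(is.na(back$pcl5_19[1]))

  jl <- tempfile(fileext = ".jsonl")
  rows <- lapply(seq_len(nrow(corp)), function(i) {
    rec <- c(list(subject_id = corp$subject_id[i], narrative = corp$narrative[i]),
             as.list(corp[i, sprintf("pcl5_%02d", 1:20)]))
    jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null")
  })
  writeLines(unlist(lapply(rows, as.character)), jl)
  back2 <- read_corpus_jsonl(jl)
  expect_identical(back2$pcl5_total, corp$pcl5_total)
  expect_identical(back2$narrative, corp$narrative)
})

test_that("filter/balance/split composition never alters label or text", {
  cfg <- synth_config(n_subjects = 80, prevalence = 0.3, dimension = 4,
                      min_words = 10, max_words = 60, seed = 13)
  corp <- generate_corpus(cfg)
  piped <- balance_downsample(filter_min_words(corp), seed = 6)
  m <- match(piped$subject_id, corp$subject_id)
  expect_identical(piped$label, corp$label[m])
  expect_identical(piped$narrative, corp$narrative[m])
})
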