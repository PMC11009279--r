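# Synthetic corpora and embeddings with the statistical structure the
# pipeline assumes: two classes at a configurable prevalence, per-class
# lognormal narrative lengths, PCL-5 item vectors that reproduce the
# intended label under missing-as-zero scoring, and unit-norm embeddings
# whose class mean directions sit a configurable distance delta apart.

# Lognormal length parameters: median fixes meanlog, the mean/median ratio
# fixes sdlog (mean = exp(meanlog + sdlog^2/2)).
lognormal_from_mean_median <- function(mean, median) {
  list(meanlog = log(median), sdlog = sqrt(2 * log(mean / median)))
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the cohort the pipeline was designed around: 1295
#' subjects at prevalence 190/1295, class-1 narrative word counts with mean
#' 194.67 / median 158 and class-0 with mean 155.39 / median 106 (lognormal
#' fits), PCL-5 totals in \[31, 60\] for class 1 and \[0, 25\] for class 0,
#' and a per-subject missing-item probability of 14/1295.
#'
#' @param n_subjects number of records.
#' @param prevalence class-1 fraction in (0, 1); class-1 count is allocated
#'   exactly as `round(prevalence * n_subjects)`.
#' @param wordcount_class1,wordcount_class0 lists with `meanlog`, `sdlog`.
#' @param min_words,max_words truncation bounds for drawn word counts. The
#'   default floor of 5 lets sub-30-word narratives occur naturally (about
#'   7% of class 0), exercising the minimum-length filter.
#' @param dimension embedding dimension (default 1536).
#' @param delta class separation: Euclidean distance between the two class
#'   mean directions before normalization.
#' @param noise_scale expected norm of the isotropic Gaussian noise added to
#'   the class mean.
#' @param pcl5_range_class1,pcl5_range_class0 inclusive total-score ranges;
#'   class 1 must sit at or above the cutoff (31), class 0 below.
#' @param missing_rate per-subject probability of having 1-3 PCL-5 items
#'   missing.
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_subjects = 1295L, prevalence = 190 / 1295,
                         wordcount_class1 = lognormal_from_mean_median(194.67, 158),
                         wordcount_class0 = lognormal_from_mean_median(155.39, 106),
                         min_words = 5L, max_words = 2000L,
                         dimension = 1536L, delta = 1, noise_scale = 1,
                         pcl5_range_class1 = c(31L, 60L),
                         pcl5_range_class0 = c(0L, 25L),
                         missing_rate = 14 / 1295, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1)
    stop_validation("prevalence must be in (0, 1)")
  if (min_words > max_words)
    stop_validation("min_words (%d) exceeds max_words (%d)", min_words, max_words)
  if (delta < 0) stop_validation("delta must be >= 0")
  if (dimension < 2L) stop_validation("dimension must be >= 2")
  if (pcl5_range_class1[1L] < PCL5_CUTOFF || pcl5_range_class0[2L] >= PCL5_CUTOFF)
    stop_validation("PCL-5 ranges must straddle the cutoff (%d)", PCL5_CUTOFF)
  if (pcl5_range_class1[2L] > 68L)
    stop_validation("class-1 totals above 68 cannot survive 3 missing items")
  structure(list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
                 wordcount_class1 = wordcount_class1,
                 wordcount_class0 = wordcount_class0,
                 min_words = as.integer(min_words),
                 max_words = as.integer(max_words),
                 dimension = as.integer(dimension), delta = delta,
                 noise_scale = noise_scale,
                 pcl5_range_class1 = as.integer(pcl5_range_class1),
                 pcl5_range_class0 = as.integer(pcl5_range_class0),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Class-weighted vocabularies. Realism is a non-goal; the shared core plus
# class-tilted token frequencies give narratives a weak but recoverable
# class signal.
vocab_core <- c("the", "baby", "was", "born", "after", "hours", "of", "labor",
                "and", "then", "we", "went", "to", "hospital", "my", "partner",
                "nurse", "doctor", "said", "felt", "during", "delivery",
                "contractions", "epidural", "room", "night", "finally", "home",
                "first", "time")
vocab_class1 <- c("terrified", "emergency", "panic", "afraid", "alone",
                  "flashbacks", "nightmare", "unable", "helpless", "trauma")
vocab_class0 <- c("calm", "smooth", "supported", "happy", "grateful",
                  "peaceful", "excited", "healthy", "joy", "relieved")

# distribute `total` severity points over the item slots in `avail`,
# each capped at 4
allocate_items <- function(total, avail) {
  items <- rep(NA_integer_, PCL5_N_ITEMS)
  items[avail] <- 0L
  if (total > 0L) {
    pool <- rep(avail, 4L)
    picked <- pool[sample.int(length(pool), total)]
    tab <- table(picked)
    items[as.integer(names(tab))] <- as.integer(tab)
  }
  items
}

#' Generate a synthetic narrative corpus
#'
#' Draws labels by exact allocation at the configured prevalence, PCL-5 item
#' vectors whose missing-as-zero total lands in the per-class range (so the
#' derived label always reproduces the intended one), and narratives of
#' lognormal token counts from class-weighted vocabularies. Deterministic
#' given `config$seed`.
#'
#' @param config a `synth_config`.
#' @return a `narrative_corpus`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects
  n1 <- as.integer(round(config$prevalence * n))
  if (n1 < 1L || n1 >= n)
    stop_validation("prevalence %.4f allocates %d class-1 subjects of %d",
                    config$prevalence, n1, n)
  with_seed(config$seed, {
    labels <- sample(rep(c(1L, 0L), c(n1, n - n1)))
    ids <- sprintf("S%04d", seq_len(n))
    pcl5 <- matrix(NA_real_, n, PCL5_N_ITEMS)
    narratives <- character(n)
    for (i in seq_len(n)) {
      rng <- if (labels[i] == 1L) config$pcl5_range_class1 else config$pcl5_range_class0
      total <- sample(rng[1L]:rng[2L], 1L)
      avail <- seq_len(PCL5_N_ITEMS)
      if (stats::runif(1) < config$missing_rate)
        avail <- setdiff(avail, sample.int(PCL5_N_ITEMS, sample(1:3, 1L)))
      pcl5[i, ] <- allocate_items(total, avail)

      wc_par <- if (labels[i] == 1L) config$wordcount_class1 else config$wordcount_class0
      wc <- round(stats::rlnorm(1, wc_par$meanlog, wc_par$sdlog))
      wc <- min(max(wc, config$min_words), config$max_words)
      tilt <- if (labels[i] == 1L) vocab_class1 else vocab_class0
      vocab <- c(vocab_core, tilt)
      probs <- c(rep(1, length(vocab_core)), rep(2, length(tilt)))
      narratives[i] <- paste(sample(vocab, wc, replace = TRUE,
                                    prob = probs / sum(probs)),
                             collapse = " ")
    }
    narrative_corpus(ids, narratives, pcl5)
  })
}

#' Generate class-separated unit-norm embeddings for a corpus
#'
#' Draws one shared random direction `e`; class means are `+/- delta/2 * e`.
#' Each record's vector is its class mean plus isotropic Gaussian noise of
#' expected norm `noise_scale`, normalized to unit length. With `delta = 0`
#' the two classes are identical in law. Deterministic given `config$seed`.
#'
#' @param corpus a `narrative_corpus`.
#' @param config a `synth_config` (uses `dimension`, `delta`, `noise_scale`,
#'   `seed`).
#' @return numeric matrix with rownames = subject IDs, one unit-norm row per
#'   record.
#' @export
generate_embeddings <- function(corpus, config) {
  stopifnot(inherits(config, "synth_config"))
  d <- config$dimension
  with_seed(config$seed + 1L, {
    e <- stats::rnorm(d); e <- e / sqrt(sum(e^2))
    mu <- list(`1` = (config$delta / 2) * e, `0` = -(config$delta / 2) * e)
    V <- matrix(0, nrow(corpus), d, dimnames = list(corpus$subject_id, NULL))
    for (i in seq_len(nrow(corpus))) {
      v <- mu[[as.character(corpus$label[i])]] +
        stats::rnorm(d) * config$noise_scale / sqrt(d)
      V[i, ] <- v / sqrt(sum(v^2))
    }
    V
  })
}

#' Write corpus embeddings to an embedding cache file
#'
#' Stores the vectors under the same content-addressed keys
#' [cached_embed()] uses, so the pipeline can consume synthetic embeddings
#' through the standard cache path.
#'
#' @param corpus a `narrative_corpus`.
#' @param vectors matrix from [generate_embeddings()].
#' @param cache_path output cache file.
#' @param model_name embedder name to key the entries under.
#' @return `cache_path`, invisibly.
#' @export
write_embedding_cache <- function(corpus, vectors, cache_path,
                                  model_name = "synthetic") {
  store <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(corpus)))
    assign(cache_key(model_name, corpus$narrative[i]), vectors[i, ],
           envir = store)
  write_cache(store, cache_path)
  invisible(cache_path)
}
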