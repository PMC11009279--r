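# Training, prediction, and reference-vote classification contracts for the
# pair similarity network. Tests use a small input dimension: the recipe
# (layer widths, optimizer, early stopping) is unchanged, only the feature
# length shrinks.

# well-separated synthetic pair features: positives and negatives drawn from
# Gaussians with opposite means
make_pair_data <- function(n_per_label = 300L, d = 8L, shift = 1, seed = 1L) {
  set.seed(seed)
  z_pos <- matrix(rnorm(n_per_label * d, mean = shift, sd = 0.5), ncol = d)
  z_neg <- matrix(rnorm(n_per_label * d, mean = -shift, sd = 0.5), ncol = d)
  list(z = rbind(z_pos, z_neg),
       pair_label = rep(c(1L, 0L), each = n_per_label))
}

test_that("training on well-separated pairs reaches >= 0.95 accuracy", {
  pairs <- make_pair_data()
  spec <- classifier_spec(input_dim = 8, seed = 3)
  model <- train_pair_classifier(pairs, spec)
  acc <- mean((pair_similarity(model, pairs$z) > 0.5) == pairs$pair_label)
  expect_gte(acc, 0.95)
  expect_lte(model$stopped_epoch, spec$max_epochs)
  expect_identical(nrow(model$training_log), model$stopped_epoch)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  pairs <- make_pair_data(n_per_label = 400L, seed = 2)
  set.seed(9)
  shuffled <- sample(pairs$pair_label)
  idx_tr <- 1:640
  idx_te <- 641:800
  model <- train_pair_classifier(
    list(z = pairs$z[idx_tr, ], pair_label = shuffled[idx_tr]),
    classifier_spec(input_dim = 8, seed = 3))
  acc <- mean((pair_similarity(model, pairs$z[idx_te, ]) > 0.5) ==
                shuffled[idx_te])
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("early stopping halts after patience epochs without improvement", {
  pairs <- make_pair_data(n_per_label = 100L)
  # learning rate 0: losses cannot improve, so training stops at 1 + patience
  spec <- classifier_spec(input_dim = 8, learning_rate = 0, seed = 1)
  model <- train_pair_classifier(pairs, spec)
  expect_identical(model$stopped_epoch, 1L + spec$patience)
  expect_identical(length(unique(round(model$training_log$val_loss, 12))), 1L)
})

test_that("training validates its inputs", {
  pairs <- make_pair_data(n_per_label = 20L)
  expect_error(train_pair_classifier(
    list(z = pairs$z, pair_label = rep(1L, 40)),
    classifier_spec(input_dim = 8)), "both labels")
  expect_error(train_pair_classifier(pairs, classifier_spec(input_dim = 9)),
               "input_dim")
})

test_that("identical seeds reproduce training exactly", {
  pairs <- make_pair_data(n_per_label = 60L)
  spec <- classifier_spec(input_dim = 8, max_epochs = 5, seed = 21)
  m1 <- train_pair_classifier(pairs, spec)
  m2 <- train_pair_classifier(pairs, spec)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$weights, m2$weights)
  z <- rnorm(8)
  expect_identical(pair_similarity(m1, z), pair_similarity(m2, z))
})

test_that("pair_similarity lies strictly in (0,1) and checks dimensions", {
  pairs <- make_pair_data(n_per_label = 60L)
  model <- train_pair_classifier(pairs, classifier_spec(input_dim = 8,
                                                        max_epochs = 3, seed = 1))
  p <- pair_similarity(model, pairs$z)
  expect_true(all(p > 0 & p < 1))
  expect_error(pair_similarity(model, rnorm(7)), "input_dim")
})

test_that("held-out positive pairs of a separated fit score > 0.5 mostly", {
  train <- make_pair_data(n_per_label = 300L, seed = 4)
  held <- make_pair_data(n_per_label = 100L, seed = 5)
  model <- train_pair_classifier(train, classifier_spec(input_dim = 8, seed = 6))
  pos_scores <- pair_similarity(model, held$z[held$pair_label == 1L, ])
  expect_gte(mean(pos_scores > 0.5), 0.9)
})

# a hand-built model with all-zero weights: every similarity is exactly 0.5
null_model <- function(d = 4L) {
  structure(list(
    spec = classifier_spec(input_dim = d, hidden_dims = c(3L, 2L)),
    weights = list(weights = list(matrix(0, d, 3), matrix(0, 3, 2),
                                  matrix(0, 2, 1)),
                   biases = list(rep(0, 3), rep(0, 2), 0)),
    training_log = data.frame(), stopped_epoch = 0L),
    class = "trained_model")
}

test_that("classify_narrative ties go to class 1 and references can permute", {
  m <- null_model()
  refs <- list(`1` = matrix(rnorm(12), 3, 4), `0` = matrix(rnorm(8), 2, 4))
  out <- classify_narrative(m, rnorm(4), refs)
  expect_identical(out$class, 1L)      # exact tie -> class 1
  expect_equal(out$margin, 0)

  pairs <- make_pair_data(n_per_label = 200L, d = 4L, seed = 8)
  model <- train_pair_classifier(pairs, classifier_spec(input_dim = 4, seed = 2))
  tv <- rnorm(4)
  refs2 <- list(`1` = matrix(rnorm(40, 1), 10, 4),
                `0` = matrix(rnorm(40, -1), 10, 4))
  out1 <- classify_narrative(model, tv, refs2)
  perm <- list(`1` = refs2$`1`[sample(10), ], `0` = refs2$`0`[sample(10), ])
  out2 <- classify_narrative(model, tv, perm)
  expect_equal(out1$score_1, out2$score_1, tolerance = 1e-12)
  expect_equal(out1$score_0, out2$score_0, tolerance = 1e-12)
  expect_error(classify_narrative(model, tv, list(`1` = refs2$`1`)),
               "reference class 0 is empty")
})

test_that("model JSON container round-trips and rejects dimension clashes", {
  pairs <- make_pair_data(n_per_label = 50L)
  model <- train_pair_classifier(pairs, classifier_spec(input_dim = 8,
                                                        max_epochs = 4, seed = 3))
  path <- tempfile(fileext = ".json")
  save_model_json(model, path)
  back <- load_model_json(path)
  z <- matrix(rnorm(40), 5, 8)
  expect_identical(pair_similarity(model, z), pair_similarity(back, z))
  expect_equal(back$training_log$val_loss, model$training_log$val_loss)

  # corrupt the declared input dimension
  txt <- readLines(path, warn = FALSE)
  txt <- sub('"input_dim":8', '"input_dim":9', txt, fixed = TRUE)
  path2 <- tempfile(fileext = ".json")
  writeLines(txt, path2)
  expect_error(load_model_json(path2), "conflict")
})
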