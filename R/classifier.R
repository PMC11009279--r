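# Deep feedforward similarity classifier over Hadamard pair features.
# Architecture: input -> 400 ReLU -> 50 ReLU -> 1 sigmoid, binary
# cross-entropy loss, Adam (lr 1e-4), batch size 32, at most 50 epochs with
# early stopping after 3 epochs without validation-loss improvement, 20% of
# the training pairs held out (stratified by pair label) for validation.
# Implemented directly on R matrices: the layers are small enough that BLAS
# matrix products dominate and no deep-learning framework is needed.

#' Specification of the pair similarity network
#'
#' Defaults reproduce the training recipe used throughout the package:
#' two hidden layers of 400 and 50 rectified units, a sigmoid output unit,
#' Adam with learning rate 1e-4, batch size 32, up to 50 epochs, early
#' stopping after 3 epochs without strict validation-loss improvement
#' (min_delta = 0), and a 20% label-stratified validation split.
#'
#' @param input_dim feature (embedding) dimension; default 1536.
#' @param hidden_dims positive integer vector of hidden-layer widths.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of passes over the training pairs.
#' @param patience epochs without validation-loss improvement before stopping.
#' @param validation_fraction fraction of pairs held out for validation,
#'   in (0, 1).
#' @param seed integer seed governing initialization, the validation split,
#'   and shuffling.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(input_dim = 1536L, hidden_dims = c(400L, 50L),
                            learning_rate = 1e-4, batch_size = 32L,
                            max_epochs = 50L, patience = 3L,
                            validation_fraction = 0.2, seed = 1L) {
  stopifnot(input_dim >= 1L, length(hidden_dims) >= 1L, all(hidden_dims >= 1L),
            validation_fraction > 0, validation_fraction < 1,
            batch_size >= 1L, max_epochs >= 1L, patience >= 1L)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))  # column-major recycle

forward_pass <- function(W, X) {
  n_hidden <- length(W$weights) - 1L
  acts <- vector("list", n_hidden)
  H <- X
  for (l in seq_len(n_hidden)) {
    H <- add_bias(H %*% W$weights[[l]], W$biases[[l]])
    H[H < 0] <- 0
    acts[[l]] <- H
  }
  logits <- drop(H %*% W$weights[[n_hidden + 1L]]) + W$biases[[n_hidden + 1L]]
  list(p = sigmoid(logits), acts = acts)
}


#' Train the pair similarity network
#'
#' Fits the feedforward network of `spec` to the Hadamard pair features.
#' Training halts at `max_epochs` or when the validation loss has not
#' strictly improved for `patience` consecutive epochs, whichever comes
#' first. Fully deterministic given `spec$seed`.
#'
#' @param pairs a `pair_set` from [build_training_set()], or any list with a
#'   feature matrix `z` and 0/1 vector `pair_label`.
#' @param spec a `classifier_spec`; `spec$input_dim` must equal `ncol(pairs$z)`.
#' @return a `trained_model` list with `spec`, fitted `weights`/`biases`,
#'   `training_log` (per-epoch train/validation loss) and `stopped_epoch`.
#' @export
train_pair_classifier <- function(pairs, spec = classifier_spec()) {
  Z <- pairs$z; y <- as.integer(pairs$pair_label)
  stopifnot(is.matrix(Z), length(y) == nrow(Z))
  if (length(unique(y)) < 2L)
    stop_validation("training pairs must contain both labels")
  if (ncol(Z) != spec$input_dim)
    stop_validation("feature dimension %d does not match spec input_dim %d",
                    ncol(Z), spec$input_dim)

  with_seed(spec$seed, {
    # stratified validation split
    val_idx <- unlist(lapply(c(0L, 1L), function(lab) {
      idx <- which(y == lab)
      idx[sample.int(length(idx), max(1L, floor(spec$validation_fraction * length(idx))))]
    }))
    tr_idx <- setdiff(seq_along(y), val_idx)
    Ztr <- Z[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Zval <- Z[val_idx, , drop = FALSE]; yval <- y[val_idx]

    dims <- c(spec$input_dim, spec$hidden_dims, 1L)
    L <- length(dims) - 1L
    init_w <- lapply(seq_len(L), function(l) glorot_uniform(dims[l], dims[l + 1L]))
    init_b <- lapply(seq_len(L), function(l) rep(0, dims[l + 1L]))

    fit <- .dfnn_fit(Ztr, ytr, Zval, yval, init_w, init_b,
                     spec$learning_rate, spec$batch_size,
                     spec$max_epochs, spec$patience)

    structure(list(spec = spec,
                   weights = list(weights = fit$weights, biases = fit$biases),
                   training_log = data.frame(epoch = seq_along(fit$train_loss),
                                             train_loss = fit$train_loss,
                                             val_loss = fit$val_loss),
                   stopped_epoch = fit$stopped_epoch),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "pair similarity network: %s, stopped at epoch %d (val loss %.4f)\n",
    paste(c(x$spec$input_dim, x$spec$hidden_dims, 1L), collapse = "-"),
    x$stopped_epoch, utils::tail(x$training_log$val_loss, 1L)))
  invisible(x)
}

#' Similarity score for pair features
#'
#' Applies the fitted network to one feature vector or a matrix of feature
#' rows. Scores lie strictly in (0, 1); values near 1 mean "same class".
#'
#' @param model a `trained_model`.
#' @param z numeric vector of length `input_dim`, or a matrix with
#'   `input_dim` columns.
#' @return numeric vector of similarity scores.
#' @export
pair_similarity <- function(model, z) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$spec$input_dim)
    stop_validation("feature dimension %d does not match model input_dim %d",
                    ncol(z), model$spec$input_dim)
  p <- forward_pass(model$weights, z)$p
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Classify a single narrative by reference voting
#'
#' Pairs the test embedding with every training reference of each class,
#' scores the pairs with the similarity network, and averages per class.
#' The predicted class is the one with the higher mean similarity; exact
#' ties go to class 1 (screening favors sensitivity). The margin is
#' `score_1 - score_0`.
#'
#' @param model a `trained_model`.
#' @param test_vec embedding vector of the narrative to classify.
#' @param references list with elements `"1"` and `"0"`: non-empty matrices
#'   of training-reference embeddings (one row per narrative).
#' @return list with `class` (0/1), `margin`, `score_1`, `score_0`.
#' @export
classify_narrative <- function(model, test_vec, references) {
  for (cl in c("1", "0")) {
    if (is.null(references[[cl]]) || nrow(references[[cl]]) == 0L)
      stop_validation("reference class %s is empty", cl)
  }
  score <- vapply(c("1", "0"), function(cl) {
    R <- references[[cl]]
    Zs <- sweep(R, 2L, test_vec, `*`)   # Hadamard of test_vec with each row
    mean(pair_similarity(model, Zs))
  }, numeric(1))
  cls <- if (score[["1"]] >= score[["0"]]) 1L else 0L
  list(class = cls, margin = unname(score[["1"]] - score[["0"]]),
       score_1 = unname(score[["1"]]), score_0 = unname(score[["0"]]))
}

#' Save / load a trained model as versioned JSON
#'
#' The container stores the spec, all weights, and the training log.
#' Loading rejects containers whose declared input dimension conflicts with
#' the stored weight shapes.
#'
#' @param model a `trained_model`.
#' @param path file path.
#' @return `path` invisibly for save; a `trained_model` for load.
#' @export
save_model_json <- function(model, path) {
  payload <- list(
    format = "cbptsdscreen-model", version = 1L,
    spec = unclass(model$spec),
    weights = lapply(model$weights$weights, function(w)
      list(dim = dim(w), b64 = encode_vec(as.vector(w)))),
    biases = lapply(model$weights$biases, encode_vec),
    bias_lens = vapply(model$weights$biases, length, integer(1)),
    training_log = model$training_log,
    stopped_epoch = model$stopped_epoch)
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyDataFrame = TRUE)
  if (!identical(payload$format, "cbptsdscreen-model"))
    stop_validation("'%s' is not a model container", path)
  spec <- do.call(classifier_spec, payload$spec)
  weights <- lapply(seq_len(nrow(payload$weights)), function(l) {
    d <- unlist(payload$weights$dim[l])
    matrix(decode_vec(payload$weights$b64[l], prod(d)), d[1L], d[2L])
  })
  biases <- lapply(seq_along(payload$biases), function(l)
    decode_vec(payload$biases[l], payload$bias_lens[l]))
  if (nrow(weights[[1L]]) != spec$input_dim)
    stop_validation("stored weights (input %d) conflict with spec input_dim %d",
                    nrow(weights[[1L]]), spec$input_dim)
  structure(list(spec = spec, weights = list(weights = weights, biases = biases),
                 training_log = as.data.frame(payload$training_log),
                 stopped_epoch = payload$stopped_epoch),
            class = "trained_model")
}
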