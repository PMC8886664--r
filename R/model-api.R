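# Public training protocol: the 60/20/20 pretraining split, transfer
# learning with frozen convolutional weights, k-fold cross-validated
# prediction, and feature extraction for the fusion stage.

#' Random train/validation/test split
#'
#' Sizes are `floor(f_train * n)`, `floor(f_val * n)` and the remainder, so
#' e.g. 1481 subjects split 60/20/20 gives a test set of 297.
#'
#' @param n cohort size (>= 5).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed for the random assignment.
#' @return object of class `bf_foldplan` with index vectors `train`, `val`,
#'   `test`.
#' @examples
#' sp <- split_cohort(1481, seed = 1)
#' lengths(sp[c("train", "val", "test")])  # 888 296 297
#' @export
split_cohort <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(n >= 5L, length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  n_train <- floor(fractions[1L] * n)
  n_val <- floor(fractions[2L] * n)
  n_test <- n - n_train - n_val
  ord <- with_seed(seed, sample.int(n))
  structure(list(train = ord[seq_len(n_train)],
                 val = ord[n_train + seq_len(n_val)],
                 test = ord[n_train + n_val + seq_len(n_test)],
                 seed = as.integer(seed)),
            class = "bf_foldplan")
}

#' Balanced k-fold assignment
#'
#' Fold sizes differ by at most one (77 subjects in 5 folds gives
#' 16/16/15/15/15).
#'
#' @param n cohort size; `k` number of folds (`2 <= k <= n`); `seed` RNG seed.
#' @param k,seed see above.
#' @return integer vector of fold ids in `1..k`, one per subject.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (k < 2L || k > n) stop("k must be in 2..n", call. = FALSE)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  with_seed(seed, sample(rep.int(seq_len(k), sizes)))
}

#' Assemble a prediction set
#'
#' One row per subject; the signed error is always recomputed as
#' `predicted - chronological`.
#'
#' @param chronological,predicted ages in years.
#' @param fold fold id per subject (optional).
#' @param tag model tag (character).
#' @param id subject identifiers (optional).
#' @return data.frame of class `bf_predictions`.
#' @export
prediction_set <- function(chronological, predicted, fold = NA_integer_,
                           tag = "model", id = NULL) {
  n <- length(chronological)
  stopifnot(n == length(predicted))
  out <- data.frame(
    id = rep_len(id %||% sprintf("S%04d", seq_len(max(n, 1L))), n),
    chronological = chronological, predicted = predicted,
    error = predicted - chronological,
    fold = rep_len(fold, n), tag = rep_len(tag, n),
    stringsAsFactors = FALSE)
  class(out) <- c("bf_predictions", "data.frame")
  out
}

#' Pretrain the network on a large cohort
#'
#' Minibatch Adam with MAE loss on the plan's training partition; the
#' returned weights are those of the epoch with the lowest validation MAE.
#'
#' @param model a [build_network()] result.
#' @param volumes list of 3D arrays (already intensity-scaled, see
#'   [scale_volumes()]).
#' @param ages chronological ages in years.
#' @param plan a [split_cohort()] plan.
#' @param epochs training epochs (default from the spec).
#' @param seed seed for shuffling.
#' @param verbose print per-epoch MAE.
#' @return the trained `bf_model` (provenance `"pretrained"`), with the
#'   training curve in `$history` and selected epoch in `$best_epoch`.
#' @export
pretrain <- function(model, volumes, ages, plan, epochs = NULL, seed = 1L,
                     verbose = FALSE) {
  stopifnot(inherits(model, "bf_model"), inherits(plan, "bf_foldplan"))
  epochs <- epochs %||% model$spec$epochs
  fit <- train_full(model, volumes, ages, plan$train, plan$val,
                    epochs = epochs, seed = seed, verbose = verbose)
  out <- fit$model
  out$provenance <- "pretrained"
  out$history <- fit$history
  out$best_epoch <- fit$best_epoch
  out
}

#' Load pretrained weights into a freshly built network
#'
#' Checks layer-by-layer that tensor shapes match; an incompatible layer is
#' named in the error.
#'
#' @param model target `bf_model`; `bundle` source `bf_model`.
#' @param bundle see above.
#' @return `model` carrying the bundle's parameters and batch-norm state.
#' @export
load_weights <- function(model, bundle) {
  stopifnot(inherits(model, "bf_model"), inherits(bundle, "bf_model"))
  for (nm in union(names(model$params), names(bundle$params))) {
    a <- model$params[[nm]]; b <- bundle$params[[nm]]
    if (is.null(a) || is.null(b) ||
        !identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
      stop(sprintf("weight mismatch at layer '%s'", nm), call. = FALSE)
    }
  }
  model$params <- bundle$params
  model$bn <- bundle$bn
  model$provenance <- bundle$provenance
  model
}

#' Fine-tune with frozen convolutional layers
#'
#' Transfer-learning step: every convolutional tensor (weights, biases,
#' batch-norm parameters and running statistics) stays bit-identical to the
#' pretrained bundle; only the two fully-connected layers are trained, on
#' convolutional features cached in a single frozen forward pass.
#'
#' @param pretrained `bf_model` holding the pretrained weights.
#' @param volumes,ages target cohort (scaled volumes).
#' @param val_idx optional validation indices for keep-best selection; the
#'   remaining subjects train.
#' @param epochs,seed,verbose as in [pretrain()].
#' @return fine-tuned `bf_model` (provenance `"finetuned"`).
#' @export
fine_tune <- function(pretrained, volumes, ages, val_idx = integer(),
                      epochs = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(pretrained, "bf_model"))
  epochs <- epochs %||% pretrained$spec$epochs
  feats <- conv_features(pretrained, volumes)
  train_idx <- setdiff(seq_along(volumes), val_idx)
  fit <- train_fc(pretrained, feats, ages, train_idx, val_idx,
                  epochs = epochs, seed = seed, verbose = verbose)
  out <- fit$model
  out$provenance <- "finetuned"
  out$history <- fit$history
  out$best_epoch <- fit$best_epoch
  out
}

#' Predict ages for a set of volumes
#'
#' Deterministic eval-mode forward pass (batch-norm uses running statistics).
#'
#' @param model trained `bf_model`.
#' @param volumes list of 3D arrays matching the spec's input shape.
#' @param batch_size forward batch size.
#' @return numeric vector of predicted ages (years).
#' @export
predict_ages <- function(model, volumes, batch_size = 8L) {
  stopifnot(inherits(model, "bf_model"))
  net_predict(model, volumes, batch_size)
}

#' Extract the penultimate feature embedding
#'
#' Deterministic forward pass up to the embedding layer (ReLU output of the
#' first fully-connected layer; 256 dimensions at the default spec). Feeding
#' the embedding through the final layer reproduces [predict_ages()] exactly.
#'
#' @param model trained `bf_model`.
#' @param volumes a single 3D array or a list of them.
#' @return a numeric vector (single volume) or matrix (n x embedding_dim).
#' @export
extract_features <- function(model, volumes) {
  stopifnot(inherits(model, "bf_model"))
  single <- !is.list(volumes)
  if (single) volumes <- list(volumes)
  n <- length(volumes)
  out <- matrix(0, n, model$spec$embedding_dim)
  i <- 1L
  while (i <= n) {
    j <- min(i + 7L, n)
    X <- stack_volumes(volumes, i:j)
    fwd <- net_forward(model, X, B = j - i + 1L, train = FALSE)
    out[i:j, ] <- fwd$embedding
    i <- j + 1L
  }
  stop_if_not_finite(out, "embedding")
  if (single) drop(out) else out
}

#' k-fold cross-validated prediction
#'
#' Each subject is predicted exactly once, by a model trained on the other
#' folds. The builder abstracts the model family: it receives the training
#' volumes (or feature rows) and ages plus a fold-specific seed, and returns
#' a prediction function.
#'
#' @param builder `function(train_x, train_ages, seed)` returning
#'   `function(x) -> predicted ages`.
#' @param x list of volumes or a feature matrix (rows = subjects).
#' @param ages chronological ages.
#' @param k folds (default 5).
#' @param seed seed controlling fold assignment and per-fold training seeds.
#' @param tag model tag for the returned prediction set.
#' @return [prediction_set()] data.frame with fold ids.
#' @export
crossval_predict <- function(builder, x, ages, k = 5L, seed = 1L,
                             tag = "cv") {
  n <- if (is.list(x)) length(x) else nrow(x)
  stopifnot(n == length(ages))
  folds <- make_folds(n, k, seed)
  pred <- numeric(n)
  take <- function(obj, idx) if (is.list(obj)) obj[idx] else obj[idx, , drop = FALSE]
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- builder(take(x, tr), ages[tr], derive_seed(seed, f))
    pred[te] <- fit(take(x, te))
  }
  prediction_set(ages, pred, fold = folds, tag = tag)
}
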