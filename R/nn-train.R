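# Optimization: Adam with MAE loss, per-update learning-rate decay
# lr_t = lr / (1 + decay * t), minibatch training with keep-best-on-validation
# model selection. Fine-tuning freezes every convolutional tensor (weights,
# biases, batch-norm parameters and running statistics) and trains only the
# two fully-connected layers on cached convolutional features.

adam_new <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(opt, params, grads, spec) {
  opt$t <- opt$t + 1L
  lr <- spec$learning_rate / (1 + spec$decay * opt$t)
  b1 <- spec$beta1; b2 <- spec$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    if (startsWith(nm, ".")) next
    gr <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- gr * 0
      opt$v[[nm]] <- gr * 0
    }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * gr
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + 1e-8)
  }
  params
}

vol_to_mat <- function(v) matrix(as.vector(v), ncol = 1L)

stack_volumes <- function(volumes, idx) {
  matrix(unlist(lapply(volumes[idx], as.vector), use.names = FALSE), ncol = 1L)
}

#' Min-max scale a cohort's volumes to \[0, 1\]
#'
#' Scaling constants are computed over the whole cohort and returned so the
#' identical transform can be reused on held-out data.
#'
#' @param volumes list of 3D arrays.
#' @param lo,hi optional stored bounds from a previous call.
#' @return list with `volumes` (scaled), `lo`, `hi`.
#' @export
scale_volumes <- function(volumes, lo = NULL, hi = NULL) {
  if (is.null(lo)) {
    rng <- range(unlist(lapply(volumes, range), use.names = FALSE))
    lo <- rng[1L]; hi <- rng[2L]
  }
  span <- if (hi > lo) hi - lo else 1
  list(volumes = lapply(volumes, function(v) (v - lo) / span),
       lo = lo, hi = hi)
}

# batched eval-mode forward returning predictions (and optionally features)
net_predict <- function(model, volumes, batch_size = 8L) {
  n <- length(volumes)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    X <- stack_volumes(volumes, i:j)
    fwd <- net_forward(model, X, B = j - i + 1L, train = FALSE)
    out[i:j] <- fwd$pred
    i <- j + 1L
  }
  out
}

# eval-mode flattened conv features for a set of volumes (n x flat_dim)
conv_features <- function(model, volumes, batch_size = 8L) {
  n <- length(volumes)
  out <- matrix(0, n, model$spec$flat_dim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    X <- stack_volumes(volumes, i:j)
    fwd <- net_forward(model, X, B = j - i + 1L, train = FALSE)
    out[i:j, ] <- fwd$flat
    i <- j + 1L
  }
  out
}

# core minibatch loop over the full network
train_full <- function(model, volumes, ages, train_idx, val_idx,
                       epochs, seed, verbose = FALSE) {
  spec <- model$spec
  if (length(train_idx) == 0L) stop("empty training partition", call. = FALSE)
  if (epochs == 0L) {
    return(list(model = model,
                history = data.frame(epoch = integer(), train_mae = numeric(),
                                     val_mae = numeric()),
                best_epoch = 0L))
  }
  # scratch runs start the output bias at the train-mean age so the network
  # learns deviations rather than the 60-year offset (standard regression
  # head initialization; pretrained/fine-tuned weights are left untouched)
  if (identical(model$provenance, "scratch")) {
    model$params[["fc2.b"]] <- mean(ages[train_idx])
  }
  opt <- adam_new()
  best <- list(val = Inf, params = model$params, bn = model$bn, epoch = 0L)
  hist <- vector("list", epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      tot <- 0; cnt <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + spec$batch_size - 1L, length(ord))
        sel <- ord[i:j]
        B <- length(sel)
        X <- stack_volumes(volumes, sel)
        fwd <- net_forward(model, X, B, train = TRUE, keep_cache = TRUE)
        model$bn <- fwd$bn
        err <- fwd$pred - ages[sel]
        loss <- mean(abs(err))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (batch starting %d)",
                       ep, i), call. = FALSE)
        }
        tot <- tot + loss * B; cnt <- cnt + B
        dpred <- sign(err) / B
        grads <- net_backward(model, fwd, dpred, B, trainable = "all")
        model$params <- adam_step(opt, model$params, grads, spec)
        i <- j + 1L
      }
      val_mae <- if (length(val_idx)) {
        mean(abs(net_predict(model, volumes[val_idx]) - ages[val_idx]))
      } else tot / cnt
      hist[[ep]] <- data.frame(epoch = ep, train_mae = tot / cnt,
                               val_mae = val_mae)
      if (val_mae < best$val) {
        best <- list(val = val_mae, params = model$params, bn = model$bn,
                     epoch = ep)
      }
      if (verbose) {
        message(sprintf("epoch %d: train MAE %.3f, val MAE %.3f",
                        ep, tot / cnt, val_mae))
      }
    }
  })
  model$params <- best$params
  model$bn <- best$bn
  list(model = model, history = do.call(rbind, hist), best_epoch = best$epoch)
}

# fully-connected-only training on cached conv features (freeze contract)
train_fc <- function(model, feats, ages, train_idx, val_idx,
                     epochs, seed, verbose = FALSE) {
  spec <- model$spec
  if (length(train_idx) == 0L) stop("empty training partition", call. = FALSE)
  if (epochs == 0L) {
    return(list(model = model,
                history = data.frame(epoch = integer(), train_mae = numeric(),
                                     val_mae = numeric()),
                best_epoch = 0L))
  }
  opt <- adam_new()
  fc_predict <- function(Fm) {
    H <- relu(Fm %*% model$params[["fc1.W"]] +
                rep(model$params[["fc1.b"]], each = nrow(Fm)))
    drop(H %*% model$params[["fc2.W"]] + model$params[["fc2.b"]])
  }
  best <- list(val = Inf, params = model$params, epoch = 0L)
  hist <- vector("list", epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      tot <- 0; cnt <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + spec$batch_size - 1L, length(ord))
        sel <- ord[i:j]
        B <- length(sel)
        Fm <- feats[sel, , drop = FALSE]
        z1 <- Fm %*% model$params[["fc1.W"]] +
          rep(model$params[["fc1.b"]], each = B)
        H <- relu(z1)
        pred <- drop(H %*% model$params[["fc2.W"]] + model$params[["fc2.b"]])
        err <- pred - ages[sel]
        loss <- mean(abs(err))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d", ep), call. = FALSE)
        }
        tot <- tot + loss * B; cnt <- cnt + B
        dpred <- matrix(sign(err) / B, B, 1L)
        g <- list()
        g[["fc2.W"]] <- crossprod(H, dpred)
        g[["fc2.b"]] <- sum(dpred)
        dH <- dpred %*% t(model$params[["fc2.W"]])
        dz1 <- dH * (z1 > 0)
        g[["fc1.W"]] <- crossprod(Fm, dz1)
        g[["fc1.b"]] <- colSums(dz1)
        model$params <- adam_step(opt, model$params, g, spec)
        i <- j + 1L
      }
      val_mae <- if (length(val_idx)) {
        mean(abs(fc_predict(feats[val_idx, , drop = FALSE]) - ages[val_idx]))
      } else tot / cnt
      hist[[ep]] <- data.frame(epoch = ep, train_mae = tot / cnt,
                               val_mae = val_mae)
      if (val_mae < best$val) {
        best <- list(val = val_mae, params = model$params, epoch = ep)
      }
      if (verbose) {
        message(sprintf("epoch %d (fc): train MAE %.3f, val MAE %.3f",
                        ep, tot / cnt, val_mae))
      }
    }
  })
  model$params <- best$params
  list(model = model, history = do.call(rbind, hist), best_epoch = best$epoch)
}
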