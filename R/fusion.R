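# Multimodal compact bilinear (MCB) pooling and the regression heads.
#
# MCB approximates the outer product of the image embedding and the blood
# vector: each modality is count-sketched into R^d with a fixed random hash
# and sign map, and the sketches are circularly convolved via an element-wise
# product in FFT space. The result equals (exactly, not just in expectation)
# the count sketch of the flattened outer product under the combined hash
# h(i,j) = (h1(i)+h2(j)) mod d, s(i,j) = s1(i)*s2(j).

#' Create a count-sketch specification for two modalities
#'
#' Hash and sign maps are drawn once per spec (never per sample) and
#' independently for the two modalities.
#'
#' @param input_dims integer vector of length 2: feature dimension per
#'   modality (default `c(image = 256, blood = 14)`).
#' @param d sketch output dimension (default 1024).
#' @param seed integer seed for the hash/sign draw.
#' @return object of class `bf_sketch`: `d`, `h` (list of 1-based bucket
#'   maps), `s` (list of sign vectors), `input_dims`, `seed`.
#' @export
make_sketch_spec <- function(input_dims = c(image = 256L, blood = 14L),
                             d = 1024L, seed = 1L) {
  stopifnot(length(input_dims) == 2L, all(input_dims >= 1L))
  if (d < 1L) stop("sketch dimension d must be >= 1", call. = FALSE)
  with_seed(seed, {
    h <- lapply(input_dims, function(p) sample.int(d, p, replace = TRUE))
    s <- lapply(input_dims, function(p) sample(c(-1, 1), p, replace = TRUE))
  })
  structure(list(d = as.integer(d), h = h, s = s,
                 input_dims = as.integer(input_dims), seed = as.integer(seed)),
            class = "bf_sketch")
}

#' Count sketch of a feature vector
#'
#' `out[j] = sum over i with h(i)=j of s(i) * v[i]`; linear in `v`.
#'
#' @param v numeric vector matching the registered dimension of `modality`.
#' @param spec a [make_sketch_spec()].
#' @param modality 1 or 2.
#' @return numeric vector of length `spec$d`.
#' @export
count_sketch <- function(v, spec, modality = 1L) {
  stopifnot(inherits(spec, "bf_sketch"))
  if (!modality %in% c(1L, 2L)) stop("unregistered modality", call. = FALSE)
  if (length(v) != spec$input_dims[modality]) {
    stop(sprintf("input length %d does not match modality %d dimension %d",
                 length(v), modality, spec$input_dims[modality]), call. = FALSE)
  }
  out <- numeric(spec$d)
  acc <- rowsum(spec$s[[modality]] * v, group = spec$h[[modality]])
  out[as.integer(rownames(acc))] <- acc
  out
}

# sketch a whole cohort: X (n x p) -> (d x n)
count_sketch_matrix <- function(X, spec, modality) {
  out <- matrix(0, spec$d, nrow(X))
  acc <- rowsum(spec$s[[modality]] * t(X), group = spec$h[[modality]])
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' MCB pooling of two feature vectors
#'
#' Circular convolution of the two count sketches, computed as an
#' element-wise product in FFT space.
#'
#' @param x,y feature vectors for modalities 1 and 2.
#' @param spec a [make_sketch_spec()].
#' @return fused numeric vector of length `spec$d`.
#' @export
mcb_pool <- function(x, y, spec) {
  stop_if_not_finite(x, "x"); stop_if_not_finite(y, "y")
  cx <- count_sketch(x, spec, 1L)
  cy <- count_sketch(y, spec, 2L)
  Re(stats::fft(stats::fft(cx) * stats::fft(cy), inverse = TRUE)) / spec$d
}

#' MCB pooling for a cohort
#'
#' @param X image embeddings (n x p); `Y` blood features (n x q).
#' @param Y see above.
#' @param spec a [make_sketch_spec()].
#' @return fused feature matrix (n x d).
#' @export
mcb_pool_matrix <- function(X, Y, spec) {
  stopifnot(nrow(X) == nrow(Y))
  stop_if_not_finite(X, "X"); stop_if_not_finite(Y, "Y")
  SX <- stats::mvfft(count_sketch_matrix(X, spec, 1L))
  SY <- stats::mvfft(count_sketch_matrix(Y, spec, 2L))
  t(Re(stats::mvfft(SX * SY, inverse = TRUE)) / spec$d)
}

#' Specification of a regression head
#'
#' @param kind `"linear"`, `"svr_rbf"`, `"random_forest"` or `"lasso"`.
#' @param cost_grid,epsilon_grid SVR hyperparameter search grids (inner
#'   3-fold CV on the training folds picks the pair with lowest MAE).
#' @param lambda lasso penalty; `NULL` selects by inner cross-validation.
#' @param ntree random-forest tree count.
#' @param feature_selection `"none"` or `"univariate"` (keep features whose
#'   simple linear regression on age has p < `alpha` in the training fold;
#'   if none qualifies the single smallest-p feature is kept).
#' @param alpha selection threshold.
#' @return object of class `bf_regressor`.
#' @export
regressor_spec <- function(kind = c("linear", "svr_rbf", "random_forest", "lasso"),
                           cost_grid = c(0.1, 1, 10, 100),
                           epsilon_grid = c(0.01, 0.1, 0.5, 1),
                           lambda = NULL,
                           ntree = 500L,
                           feature_selection = c("none", "univariate"),
                           alpha = 0.05) {
  kind <- match.arg(kind)
  feature_selection <- match.arg(feature_selection)
  if (kind == "svr_rbf" && (length(cost_grid) == 0L || length(epsilon_grid) == 0L)) {
    stop("empty hyperparameter grid for svr_rbf", call. = FALSE)
  }
  structure(list(kind = kind, cost_grid = cost_grid,
                 epsilon_grid = epsilon_grid, lambda = lambda,
                 ntree = as.integer(ntree),
                 feature_selection = feature_selection, alpha = alpha),
            class = "bf_regressor")
}

# linear head: ridge least squares with intercept, penalty chosen by
# generalized cross-validation over a grid that includes 0 (so noiseless
# problems are fit exactly). With many fused features and few subjects an
# unpenalized solve would interpolate; the GCV ridge is the closed-form
# analogue of a fully-connected layer's implicitly regularized SGD fit.
lstsq_fit <- function(X, y) {
  n <- nrow(X)
  mx <- colMeans(X); my <- mean(y)
  Xc <- X - rep(mx, each = n)
  yc <- y - my
  sv <- svd(Xc, nu = min(n, ncol(X)), nv = min(n, ncol(X)))
  d2 <- sv$d^2
  uy <- crossprod(sv$u, yc)                      # U' y
  ss_perp <- sum(yc^2) - sum(uy^2)               # outside the column space
  scale <- mean(d2[d2 > 0]) %||% 1
  lambdas <- c(0, 10^seq(-8, 2, by = 1) * scale)
  gcv <- vapply(lambdas, function(lam) {
    shrink <- if (lam == 0) as.numeric(sv$d > max(sv$d[1L], 1e-12) * 1e-10)
              else d2 / (d2 + lam)
    rss <- sum((uy * (1 - shrink))^2) + ss_perp
    df <- sum(shrink) + 1
    if (df >= n) return(Inf)
    n * rss / (n - df)^2
  }, numeric(1L))
  lam <- lambdas[which.min(gcv)]
  shrink_c <- if (lam == 0) {
    ifelse(sv$d > max(sv$d[1L], 1e-12) * 1e-10, 1 / pmax(sv$d, 1e-300), 0)
  } else {
    sv$d / (d2 + lam)
  }
  beta <- sv$v %*% (uy * shrink_c)
  list(beta = drop(beta), mx = mx, my = my, lambda = lam)
}

lstsq_predict <- function(fit, X) {
  drop((X - rep(fit$mx, each = nrow(X))) %*% fit$beta) + fit$my
}

# univariate linear-regression screen on the training fold
select_univariate <- function(X, y, alpha = 0.05) {
  p <- apply(X, 2L, function(f) {
    if (stats::sd(f) == 0) return(1)
    stats::cor.test(f, y)$p.value   # equivalent to the slope t-test
  })
  keep <- which(p < alpha)
  if (length(keep) == 0L) keep <- which.min(p)
  keep[order(p[keep])]
}

# fit one regression head on a training fold; returns a prediction closure
fit_regressor <- function(X, y, spec, seed = 1L) {
  stopifnot(inherits(spec, "bf_regressor"))
  keep <- seq_len(ncol(X))
  if (spec$feature_selection == "univariate") {
    keep <- select_univariate(X, y, spec$alpha)
  }
  Xs <- X[, keep, drop = FALSE]
  predict_core <- switch(spec$kind,
    linear = {
      fit <- lstsq_fit(Xs, y)
      function(Z) lstsq_predict(fit, Z)
    },
    svr_rbf = {
      grid <- expand.grid(C = spec$cost_grid, eps = spec$epsilon_grid)
      folds <- make_folds(length(y), k = min(3L, length(y)), seed = seed)
      score <- vapply(seq_len(nrow(grid)), function(g) {
        errs <- unlist(lapply(unique(folds), function(f) {
          tr <- folds != f
          if (sum(tr) < 2L) return(numeric())
          m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
                          type = "eps-regression", kernel = "radial",
                          cost = grid$C[g], epsilon = grid$eps[g])
          abs(stats::predict(m, Xs[!tr, , drop = FALSE]) - y[!tr])
        }))
        mean(errs)
      }, numeric(1L))
      best <- grid[which.min(score), ]
      m <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                      cost = best$C, epsilon = best$eps)
      function(Z) unname(stats::predict(m, Z))
    },
    random_forest = {
      m <- with_seed(seed, randomForest::randomForest(Xs, y, ntree = spec$ntree))
      function(Z) unname(stats::predict(m, Z))
    },
    lasso = {
      if (is.null(spec$lambda)) {
        cvfit <- with_seed(seed, glmnet::cv.glmnet(Xs, y, alpha = 1, nfolds = 5L))
        lam <- cvfit$lambda.min
      } else {
        lam <- spec$lambda
      }
      m <- glmnet::glmnet(Xs, y, alpha = 1, lambda = lam)
      function(Z) drop(stats::predict(m, Z))
    })
  function(Z) predict_core(Z[, keep, drop = FALSE])
}

#' Single-modality cross-validated regression
#'
#' Per-fold hyperparameter search and feature selection run on the training
#' folds only (no leakage); each subject is predicted by the model that
#' never saw it.
#'
#' @param features numeric matrix (n x p): image embeddings or blood panel.
#' @param ages chronological ages.
#' @param spec a [regressor_spec()].
#' @param k,seed cross-validation folds and seed.
#' @param tag model tag for the prediction set.
#' @return [prediction_set()].
#' @export
fit_single_modality <- function(features, ages, spec = regressor_spec(),
                                k = 5L, seed = 1L, tag = spec$kind) {
  stop_if_not_finite(features, "features")
  crossval_predict(
    function(Xtr, ytr, s) fit_regressor(Xtr, ytr, spec, seed = s),
    features, ages, k = k, seed = seed, tag = tag)
}

#' Fit the bilinear fusion model
#'
#' Fuses the image embedding with the blood feature vector by MCB pooling
#' and trains the chosen head on the fused representation. The default head
#' is the linear fully-connected layer. The blood matrix is z-scored with
#' the training statistics, which are stored and reapplied at prediction.
#'
#' Each modality is augmented with a constant unit coordinate before
#' sketching (homogeneous coordinates), so the fused outer product spans
#' both modalities' main effects as well as all pairwise interactions; a
#' z-scored blood vector otherwise has no constant component and a linear
#' head could not represent the image-only signal.
#'
#' @param embeddings image embeddings (n x 256 at the default spec).
#' @param panel_features numeric blood features (n x 14, APOE encoded as the
#'   epsilon-4 allele count; see [panel_feature_matrix()]).
#' @param ages chronological ages.
#' @param sketch a [make_sketch_spec()] whose input dims match the
#'   *augmented* feature dimensions (p+1, q+1); built internally when `NULL`.
#' @param head a [regressor_spec()].
#' @param seed seed for the sketch draw and stochastic heads.
#' @return object of class `bf_fusion`: prediction via [predict_fusion()].
#' @export
fit_fusion_model <- function(embeddings, panel_features, ages,
                             sketch = NULL, head = regressor_spec("linear"),
                             seed = 1L) {
  embeddings <- as.matrix(embeddings)
  panel_features <- as.matrix(panel_features)
  if (anyNA(panel_features)) {
    bad <- which(is.na(panel_features), arr.ind = TRUE)[1L, ]
    stop(sprintf("NaN in blood panel: subject %d, parameter %s",
                 bad[1L], colnames(panel_features)[bad[2L]] %||% bad[2L]),
         call. = FALSE)
  }
  if (is.null(sketch)) {
    sketch <- make_sketch_spec(c(ncol(embeddings) + 1L,
                                 ncol(panel_features) + 1L),
                               d = 1024L, seed = seed)
  }
  zm <- colMeans(panel_features)
  zs <- apply(panel_features, 2L, stats::sd)
  zs[zs == 0] <- 1
  Z <- (panel_features - rep(zm, each = nrow(panel_features))) /
    rep(zs, each = nrow(panel_features))
  fused <- mcb_pool_matrix(cbind(embeddings, 1), cbind(Z, 1), sketch)
  fit <- fit_regressor(fused, ages, head, seed = seed)
  structure(list(sketch = sketch, head = head, fit = fit, zm = zm, zs = zs),
            class = "bf_fusion")
}

#' Predict ages from a fitted fusion model
#'
#' @param model a [fit_fusion_model()] result.
#' @param embeddings,panel_features held-out features.
#' @return numeric vector of predicted ages.
#' @export
predict_fusion <- function(model, embeddings, panel_features) {
  stopifnot(inherits(model, "bf_fusion"))
  Z <- (as.matrix(panel_features) - rep(model$zm, each = nrow(panel_features))) /
    rep(model$zs, each = nrow(panel_features))
  model$fit(mcb_pool_matrix(cbind(as.matrix(embeddings), 1), cbind(Z, 1),
                            model$sketch))
}

#' Cross-validated fusion vs. single-modality comparison
#'
#' Runs the same k-fold plan for the fused model; z-scoring of the blood
#' features always uses training-fold statistics.
#'
#' @param embeddings,panel_features,ages cohort features and target.
#' @param sketch a [make_sketch_spec()]; built from `seed` when `NULL`.
#' @param head a [regressor_spec()].
#' @param k,seed folds and seed.
#' @return [prediction_set()] with tag `"fusion"`.
#' @export
crossval_fusion <- function(embeddings, panel_features, ages, sketch = NULL,
                            head = regressor_spec("linear"), k = 5L,
                            seed = 1L) {
  embeddings <- as.matrix(embeddings)
  panel_features <- as.matrix(panel_features)
  p <- ncol(embeddings)
  if (is.null(sketch)) {
    sketch <- make_sketch_spec(c(p + 1L, ncol(panel_features) + 1L),
                               d = 1024L, seed = seed)
  }
  x <- cbind(embeddings, panel_features)
  crossval_predict(function(Xtr, ytr, s) {
    m <- fit_fusion_model(Xtr[, seq_len(p), drop = FALSE],
                          Xtr[, -seq_len(p), drop = FALSE],
                          ytr, sketch = sketch, head = head, seed = s)
    function(Z) predict_fusion(m, Z[, seq_len(p), drop = FALSE],
                               Z[, -seq_len(p), drop = FALSE])
  }, x, ages, k = k, seed = seed, tag = "fusion")
}

#' Numeric blood feature matrix (the 14 fusion features)
#'
#' The 13 concentration parameters plus APOE encoded as the epsilon-4 allele
#' count (0/1/2). The derived amyloid ratios are analysis-only columns and
#' are never part of the fusion panel.
#'
#' @param panel a cohort blood panel data.frame (columns [BLOOD_PARAMS] and
#'   `APOE` genotype strings such as `"e3/e4"`).
#' @return numeric matrix (n x 14) with named columns.
#' @export
panel_feature_matrix <- function(panel) {
  miss <- setdiff(c(BLOOD_PARAMS, "APOE"), names(panel))
  if (length(miss)) {
    stop(sprintf("missing column: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  e4 <- vapply(strsplit(panel$APOE, "/", fixed = TRUE),
               function(a) sum(a == "e4"), numeric(1L))
  out <- cbind(as.matrix(panel[, BLOOD_PARAMS]), APOE_e4 = e4)
  stop_if_not_finite(out, "blood panel")
  out
}
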