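# The 3D residual regression network.
#
# Architecture: n_blocks residual blocks, each
#   conv3x3x3 -> BN -> ReLU -> conv3x3x3 -> BN, plus an identity skip
#   (1x1x1 projection when the channel count changes), ReLU, then
#   3x3x3 max pooling with stride 2 (ceil-mode halving),
# followed by flatten -> fully-connected embedding (ReLU) -> fully-connected
# scalar age output. With the default five blocks and widths
# {8,16,32,64,128}, a 121x145x121 input reduces to 128 feature maps of
# size 4x5x4 and a 256-dimensional embedding.

#' Specification of the 3D residual age-regression network
#'
#' @param input_shape voxel triple of the input volumes.
#' @param n_blocks number of residual blocks (default 5).
#' @param block_channels channel width per block; the default ends at 128.
#' @param embedding_dim size of the penultimate feature vector (default 256).
#' @param learning_rate,decay,beta1,beta2 Adam settings. `decay` is the
#'   classical per-update learning-rate decay `lr / (1 + decay * t)`.
#' @param batch_size minibatch size (default 4).
#' @param epochs default training epoch budget.
#' @param loss only `"mae"` (mean absolute error) is supported.
#' @return object of class `bf_netspec`. `$conv_shapes` holds the spatial
#'   shape after each block (ceil-halving chain), `$flat_dim` the flattened
#'   convolutional output length.
#' @examples
#' sp <- network_spec(c(121, 145, 121))
#' sp$conv_shapes[[5]]  # 4 5 4
#' @export
network_spec <- function(input_shape,
                         n_blocks = 5L,
                         block_channels = c(8L, 16L, 32L, 64L, 128L),
                         embedding_dim = 256L,
                         learning_rate = 1e-4,
                         decay = 1e-6,
                         beta1 = 0.9,
                         beta2 = 0.999,
                         batch_size = 4L,
                         epochs = 100L,
                         loss = "mae") {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, n_blocks >= 1L, embedding_dim >= 1L)
  if (length(block_channels) != n_blocks) {
    stop("block_channels must have one width per block", call. = FALSE)
  }
  if (any(input_shape < 2^(n_blocks - 2L))) {
    stop(sprintf(
      "input %s too small to survive %d ceil-halving stages",
      paste(input_shape, collapse = "x"), n_blocks), call. = FALSE)
  }
  if (!identical(loss, "mae")) stop("only MAE loss is supported", call. = FALSE)
  shapes <- vector("list", n_blocks)
  s <- input_shape
  for (b in seq_len(n_blocks)) {
    s <- ceil_halve(s)
    shapes[[b]] <- s
  }
  structure(list(input_shape = input_shape, n_blocks = as.integer(n_blocks),
                 block_channels = as.integer(block_channels),
                 embedding_dim = as.integer(embedding_dim),
                 learning_rate = learning_rate, decay = decay,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 conv_shapes = shapes,
                 flat_dim = as.integer(prod(shapes[[n_blocks]]) *
                                         block_channels[n_blocks])),
            class = "bf_netspec")
}

spec_fingerprint <- function(spec) {
  digest::digest(spec[c("input_shape", "n_blocks", "block_channels",
                        "embedding_dim")], algo = "sha256")
}

#' Build (initialize) a network from its specification
#'
#' He-normal initialization for convolutional and dense weights, unit-gain
#' batch-norm parameters, zero biases. Parameter tensors are keyed by layer
#' name; convolutional-stage keys (`blockK.*`) are disjoint from the
#' fully-connected keys (`fc1.*`, `fc2.*`).
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the initialization draw.
#' @return object of class `bf_model`: list with `spec`, `params` (named
#'   list of tensors), `bn` (running batch-norm statistics), `provenance`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "bf_netspec"))
  params <- list()
  bn <- list()
  with_seed(seed, {
    cin <- 1L
    for (b in seq_len(spec$n_blocks)) {
      cout <- spec$block_channels[b]
      nm <- sprintf("block%d", b)
      params[[paste0(nm, ".conv1.W")]] <-
        matrix(stats::rnorm(27L * cin * cout, 0, sqrt(2 / (27 * cin))),
               27L * cin, cout)
      params[[paste0(nm, ".conv1.b")]] <- numeric(cout)
      params[[paste0(nm, ".bn1.gamma")]] <- rep(1, cout)
      params[[paste0(nm, ".bn1.beta")]] <- numeric(cout)
      params[[paste0(nm, ".conv2.W")]] <-
        matrix(stats::rnorm(27L * cout * cout, 0, sqrt(2 / (27 * cout))),
               27L * cout, cout)
      params[[paste0(nm, ".conv2.b")]] <- numeric(cout)
      params[[paste0(nm, ".bn2.gamma")]] <- rep(1, cout)
      params[[paste0(nm, ".bn2.beta")]] <- numeric(cout)
      if (cin != cout) {
        params[[paste0(nm, ".proj.W")]] <-
          matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
        params[[paste0(nm, ".proj.b")]] <- numeric(cout)
      }
      bn[[paste0(nm, ".bn1")]] <- list(mean = numeric(cout), var = rep(1, cout))
      bn[[paste0(nm, ".bn2")]] <- list(mean = numeric(cout), var = rep(1, cout))
      cin <- cout
    }
    params[["fc1.W"]] <- matrix(
      stats::rnorm(spec$flat_dim * spec$embedding_dim, 0,
                   sqrt(2 / spec$flat_dim)),
      spec$flat_dim, spec$embedding_dim)
    params[["fc1.b"]] <- numeric(spec$embedding_dim)
    params[["fc2.W"]] <- matrix(
      stats::rnorm(spec$embedding_dim, 0, sqrt(1 / spec$embedding_dim)),
      spec$embedding_dim, 1L)
    params[["fc2.b"]] <- numeric(1L)
  })
  structure(list(spec = spec, params = params, bn = bn,
                 provenance = "scratch",
                 fingerprint = spec_fingerprint(spec)),
            class = "bf_model")
}

#' @export
print.bf_model <- function(x, ...) {
  cat(sprintf(
    "<bf_model> input %s, %d residual blocks (widths %s), conv out %s x %d, embedding %d [%s]\n",
    paste(x$spec$input_shape, collapse = "x"), x$spec$n_blocks,
    paste(x$spec$block_channels, collapse = ","),
    paste(x$spec$conv_shapes[[x$spec$n_blocks]], collapse = "x"),
    x$spec$block_channels[x$spec$n_blocks],
    x$spec$embedding_dim, x$provenance))
  invisible(x)
}

is_conv_param <- function(nm) !startsWith(nm, "fc")

# full forward pass on a stacked batch matrix X ((B*V) x 1).
# Returns prediction, embedding, flattened conv output, final conv maps and
# (when keep_cache) everything the backward pass needs.
net_forward <- function(model, X, B, train = FALSE, keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  bn <- model$bn
  shape <- spec$input_shape
  caches <- if (keep_cache) vector("list", spec$n_blocks) else NULL

  for (b in seq_len(spec$n_blocks)) {
    nm <- sprintf("block%d", b)
    gb <- batch_gather("c", shape, B)
    X_in <- X
    cv1 <- conv_forward(X_in, p[[paste0(nm, ".conv1.W")]],
                        p[[paste0(nm, ".conv1.b")]], gb)
    f1 <- bn_forward(cv1$out, p[[paste0(nm, ".bn1.gamma")]],
                     p[[paste0(nm, ".bn1.beta")]],
                     bn[[paste0(nm, ".bn1")]], train)
    bn[[paste0(nm, ".bn1")]] <- f1$run
    a1 <- relu(f1$out)
    cv2 <- conv_forward(a1, p[[paste0(nm, ".conv2.W")]],
                        p[[paste0(nm, ".conv2.b")]], gb)
    f2 <- bn_forward(cv2$out, p[[paste0(nm, ".bn2.gamma")]],
                     p[[paste0(nm, ".bn2.beta")]],
                     bn[[paste0(nm, ".bn2")]], train)
    bn[[paste0(nm, ".bn2")]] <- f2$run
    skip <- if (!is.null(p[[paste0(nm, ".proj.W")]])) {
      X_in %*% p[[paste0(nm, ".proj.W")]] +
        rep(p[[paste0(nm, ".proj.b")]], each = nrow(X_in))
    } else X_in
    pre <- f2$out + skip
    act <- relu(pre)
    pg <- batch_gather("p", shape, B)
    pl <- pool_forward(act, pg)
    if (keep_cache) {
      caches[[b]] <- list(X_in = X_in, gb = gb, pg = pg,
                          Xcol1 = cv1$Xcol, Xcol2 = cv2$Xcol,
                          mask1 = f1$out > 0,
                          xhat1 = f1$xhat, invstd1 = f1$invstd,
                          xhat2 = f2$xhat, invstd2 = f2$invstd,
                          mask_out = pre > 0, arg = pl$arg,
                          n_in = nrow(act))
    }
    X <- pl$out
    shape <- ceil_halve(shape)
  }
  V <- prod(shape)

  # flatten: (B*Vf) x Cf -> B x (Vf*Cf), channel-major columns
  Vf <- V; Cf <- ncol(X)
  A <- X
  dim(A) <- c(Vf, B, Cf)
  A <- aperm(A, c(1L, 3L, 2L))
  flat <- t(matrix(A, Vf * Cf, B))

  z1f <- flat %*% p[["fc1.W"]] + rep(p[["fc1.b"]], each = B)
  H <- relu(z1f)
  pred <- drop(H %*% p[["fc2.W"]] + p[["fc2.b"]])

  list(pred = pred, embedding = H, flat = flat, conv_out = X,
       conv_shape = shape, mask_fc1 = z1f > 0,
       caches = caches, bn = bn)
}

# backward pass from d(loss)/d(pred). trainable = "all" or "fc".
# Returns gradients for the trainable tensors; when through_conv the
# gradient w.r.t. the final conv output is also returned (Grad-CAM support).
net_backward <- function(model, fwd, dpred, B, trainable = "all",
                         through_conv = (trainable == "all")) {
  spec <- model$spec
  p <- model$params
  g <- list()

  dH <- matrix(dpred, B, 1L) %*% t(p[["fc2.W"]])
  g[["fc2.W"]] <- crossprod(fwd$embedding, matrix(dpred, B, 1L))
  g[["fc2.b"]] <- sum(dpred)
  dz1f <- dH * fwd$mask_fc1
  g[["fc1.W"]] <- crossprod(fwd$flat, dz1f)
  g[["fc1.b"]] <- colSums(dz1f)

  if (!through_conv) return(g)

  dflat <- dz1f %*% t(p[["fc1.W"]])
  shape <- fwd$conv_shape
  Vf <- prod(shape); Cf <- ncol(fwd$conv_out)
  A <- t(dflat)                      # (Vf*Cf) x B
  dim(A) <- c(Vf, Cf, B)
  A <- aperm(A, c(1L, 3L, 2L))
  dX <- matrix(A, Vf * B, Cf)
  g[[".d_conv_out"]] <- dX

  if (trainable != "all") return(g)

  cin_of <- function(b) if (b == 1L) 1L else spec$block_channels[b - 1L]
  for (b in rev(seq_len(spec$n_blocks))) {
    nm <- sprintf("block%d", b)
    cc <- fwd$caches[[b]]
    cout <- spec$block_channels[b]
    dact <- pool_backward(dX, cc$arg, cc$pg, cc$n_in)
    dpre <- dact * cc$mask_out
    # BN2 branch
    b2 <- bn_backward(dpre, cc$xhat2, cc$invstd2,
                      model$params[[paste0(nm, ".bn2.gamma")]])
    g[[paste0(nm, ".bn2.gamma")]] <- b2$dgamma
    g[[paste0(nm, ".bn2.beta")]] <- b2$dbeta
    c2 <- conv_backward(b2$dX, cc$Xcol2, model$params[[paste0(nm, ".conv2.W")]],
                        cout, cc$gb, need_dx = TRUE)
    g[[paste0(nm, ".conv2.W")]] <- c2$dW
    g[[paste0(nm, ".conv2.b")]] <- c2$db
    da1 <- c2$dX * cc$mask1
    b1 <- bn_backward(da1, cc$xhat1, cc$invstd1,
                      model$params[[paste0(nm, ".bn1.gamma")]])
    g[[paste0(nm, ".bn1.gamma")]] <- b1$dgamma
    g[[paste0(nm, ".bn1.beta")]] <- b1$dbeta
    need_dx <- b > 1L
    c1 <- conv_backward(b1$dX, cc$Xcol1, model$params[[paste0(nm, ".conv1.W")]],
                        cin_of(b), cc$gb, need_dx = need_dx)
    g[[paste0(nm, ".conv1.W")]] <- c1$dW
    g[[paste0(nm, ".conv1.b")]] <- c1$db
    # skip branch
    if (!is.null(model$params[[paste0(nm, ".proj.W")]])) {
      g[[paste0(nm, ".proj.W")]] <- crossprod(cc$X_in, dpre)
      g[[paste0(nm, ".proj.b")]] <- colSums(dpre)
      if (need_dx) {
        dX <- c1$dX + dpre %*% t(model$params[[paste0(nm, ".proj.W")]])
      }
    } else if (need_dx) {
      dX <- c1$dX + dpre
    }
  }
  g
}
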