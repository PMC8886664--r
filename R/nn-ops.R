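# Low-level 3D network primitives.
#
# Feature maps live in matrices of shape (B*V) x C: V spatial voxels in
# column-major array order, samples stacked sample-major along rows, one
# column per channel. Convolutions are evaluated as an im2col gather followed
# by a single BLAS matrix product; the data gradient is a transposed
# convolution (gather + GEMM with the offset-flipped kernel), so no scatter
# is needed. Max pooling uses the same gather with -Inf padding. Gather
# tables depend only on (spatial shape, batch size) and are memoized.

.bf_cache <- new.env(parent = emptyenv())

# 3x3x3 neighborhood index table for stride-1 "same" convolution:
# V x 27 integer matrix, 0 marks an out-of-bounds (zero-padded) neighbor.
# Offset order is column-major over (dx, dy, dz) in {-1,0,1}^3, so the
# spatially flipped offset of column k is column 28-k.
conv_idx <- function(shape) {
  key <- paste0("c", paste(shape, collapse = "_"))
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  V <- nx * ny * nz
  x <- rep.int(seq_len(nx), ny * nz)
  y <- rep.int(rep(seq_len(ny), each = nx), nz)
  z <- rep(seq_len(nz), each = nx * ny)
  idx <- matrix(0L, V, 27L)
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    xn <- x + dx; yn <- y + dy; zn <- z + dz
    ok <- xn >= 1L & xn <= nx & yn >= 1L & yn <= ny & zn >= 1L & zn <= nz
    v <- xn + (yn - 1L) * nx + (zn - 1L) * nx * ny
    v[!ok] <- 0L
    idx[, k] <- v
  }
  .bf_cache[[key]] <- idx
  idx
}

# kernel-3 stride-2 pooling windows with ceil-mode output size:
# output voxel o covers input positions 2o-1 .. 2o+1 per axis (end-padded),
# so each output dimension is ceiling(d/2).
pool_idx <- function(shape) {
  key <- paste0("p", paste(shape, collapse = "_"))
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  out <- ceil_halve(shape)
  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  ox <- rep.int(seq_len(out[1L]), out[2L] * out[3L])
  oy <- rep.int(rep(seq_len(out[2L]), each = out[1L]), out[3L])
  oz <- rep(seq_len(out[3L]), each = out[1L] * out[2L])
  Vo <- prod(out)
  idx <- matrix(0L, Vo, 27L)
  k <- 0L
  for (tz in 0:2) for (ty in 0:2) for (tx in 0:2) {
    k <- k + 1L
    xn <- 2L * ox - 1L + tx; yn <- 2L * oy - 1L + ty; zn <- 2L * oz - 1L + tz
    ok <- xn <= nx & yn <= ny & zn <= nz
    v <- xn + (yn - 1L) * nx + (zn - 1L) * nx * ny
    v[!ok] <- 0L
    idx[, k] <- v
  }
  .bf_cache[[key]] <- idx
  idx
}

# replicate a per-sample index table across a batch (0 stays 0); memoized.
# Returns the index matrix plus the 1-shifted flat gather vector used by
# row subsetting against a zero-padded first row.
batch_gather <- function(kind, shape, B) {
  key <- paste0(kind, paste(shape, collapse = "_"), "B", B)
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  idx <- if (kind == "c") conv_idx(shape) else pool_idx(shape)
  V <- prod(shape)
  if (B > 1L) {
    Vr <- nrow(idx)
    base <- idx[rep.int(seq_len(Vr), B), , drop = FALSE]
    off <- rep(0L:(B - 1L) * V, each = Vr)
    pad <- base == 0L
    base <- base + off
    base[pad] <- 0L
    idx <- base
  }
  res <- list(idx = idx, gvec = as.vector(idx) + 1L)
  .bf_cache[[key]] <- res
  res
}

# im2col: (B*V) x C feature matrix -> (B*V) x (27*C) patch matrix.
# Column order: offset k fastest, then input channel (matches conv weights).
im2col <- function(X, gb, fill = 0) {
  C <- ncol(X)
  Xa <- rbind(matrix(fill, 1L, C), X)
  A <- Xa[gb$gvec, , drop = FALSE]                  # (27*rows) x C
  dim(A) <- c(nrow(gb$idx), 27L * C)
  A
}

# Convolution weights are (27*Cin) x Cout matrices with row order
# (offset k fastest, then input channel); bias is length Cout.
# Returns the output and the patch matrix (reused for the weight gradient).
conv_forward <- function(X, W, b, gb) {
  Xcol <- im2col(X, gb)
  Y <- Xcol %*% W
  list(out = Y + rep(b, each = nrow(Y)), Xcol = Xcol)
}

# offset-flip and transpose a conv weight for the data gradient
flip_weights <- function(W, Cin, Cout) {
  A <- W
  dim(A) <- c(27L, Cin, Cout)
  A <- A[27:1, , , drop = FALSE]
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(27L * Cout, Cin)
  A
}

conv_backward <- function(dY, Xcol, W, Cin, gb, need_dx = TRUE) {
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dx) {
    dX <- im2col(dY, gb) %*% flip_weights(W, Cin, ncol(dY))
  }
  list(dW = dW, db = db, dX = dX)
}

# plain gather without the patch-matrix reshape
gather_raw <- function(X, gb, fill = 0) {
  C <- ncol(X)
  Xa <- rbind(matrix(fill, 1L, C), X)
  Xa[gb$gvec, , drop = FALSE]
}

# ceil-mode 3x3x3 stride-2 max pooling; returns pooled values plus the
# argmax bookkeeping needed for the backward scatter
pool_forward <- function(X, gb) {
  Vo <- nrow(gb$idx)
  g <- gather_raw(X, gb, fill = -Inf)               # (27*Vo) x C
  m <- g[seq_len(Vo), , drop = FALSE]
  arg <- matrix(1L, Vo, ncol(X))
  for (k in 2:27) {
    v <- g[((k - 1L) * Vo + 1L):(k * Vo), , drop = FALSE]
    upd <- v > m
    if (any(upd)) {
      m[upd] <- v[upd]
      arg[upd] <- k
    }
  }
  list(out = m, arg = arg)
}

pool_backward <- function(dY, arg, gb, n_in) {
  Vo <- nrow(gb$idx); C <- ncol(dY)
  flat <- rep.int(seq_len(Vo), C) + (as.vector(arg) - 1L) * Vo
  iv <- gb$idx[flat]                                 # input row per (v,c)
  key <- iv + (rep(seq_len(C), each = Vo) - 1L) * n_in
  acc <- rowsum(as.vector(dY), group = key)
  dX <- numeric(n_in * C)
  dX[as.numeric(rownames(acc))] <- acc
  dim(dX) <- c(n_in, C)
  dX
}

# batch normalization over rows (batch x spatial), per channel
bn_forward <- function(X, gamma, beta, run, train, eps = 1e-5, momentum = 0.9) {
  n <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    va <- colMeans(xc * xc)
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * va
  } else {
    mu <- run$mean
    va <- run$var
    xc <- X - rep(mu, each = n)
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(invstd, each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = out, xhat = xhat, invstd = invstd, run = run)
}

bn_backward <- function(dY, xhat, invstd, gamma) {
  n <- nrow(dY)
  dbeta <- colSums(dY)
  dgamma <- colSums(dY * xhat)
  dX <- rep(gamma * invstd, each = n) *
    (dY - rep(dbeta / n, each = n) - xhat * rep(dgamma / n, each = n))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu <- function(X) {
  X[X < 0] <- 0
  X
}

# trilinear upsampling of a 3D array to a target shape (half-voxel-center
# alignment, the standard image-resize convention)
upsample_trilinear <- function(arr, out_shape) {
  ins <- dim(arr)
  axes <- lapply(1:3, function(a) {
    n_in <- ins[a]; n_out <- out_shape[a]
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    lo <- pmin(pmax(floor(pos), 0), n_in - 1)
    hi <- pmin(lo + 1, n_in - 1)
    w <- pos - lo
    w[pos < 0] <- 0
    w[pos > n_in - 1] <- 0
    list(lo = as.integer(lo) + 1L, hi = as.integer(hi) + 1L, w = w)
  })
  out <- array(0, dim = out_shape)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) axes[[1]]$hi else axes[[1]]$lo
    iy <- if (cy) axes[[2]]$hi else axes[[2]]$lo
    iz <- if (cz) axes[[3]]$hi else axes[[3]]$lo
    wx <- if (cx) axes[[1]]$w else 1 - axes[[1]]$w
    wy <- if (cy) axes[[2]]$w else 1 - axes[[2]]$w
    wz <- if (cz) axes[[3]]$w else 1 - axes[[3]]$w
    w3 <- outer(outer(wx, wy), wz)
    out <- out + arr[ix, iy, iz, drop = FALSE] * w3
  }
  out
}

# nearest-neighbour variant (exact label-boundary studies)
upsample_nearest <- function(arr, out_shape) {
  ins <- dim(arr)
  ix <- pmin(pmax(round(((seq_len(out_shape[1]) - 0.5) * ins[1] / out_shape[1]) + 0.5), 1), ins[1])
  iy <- pmin(pmax(round(((seq_len(out_shape[2]) - 0.5) * ins[2] / out_shape[2]) + 0.5), 1), ins[2])
  iz <- pmin(pmax(round(((seq_len(out_shape[3]) - 0.5) * ins[3] / out_shape[3]) + 0.5), 1), ins[3])
  arr[ix, iy, iz, drop = FALSE]
}
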