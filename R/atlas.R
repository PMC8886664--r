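#' Build a synthetic mirror-symmetric parcellation
#'
#' Stands in for a hemisphere-paired anatomical parcellation (such as the
#' 90-region AAL atlas) on an arbitrary grid. Each region pair consists of an
#' axis-aligned ellipsoid placed in the left half of the grid (first axis is
#' left-right) and its mirror image about the mid-sagittal plane. Ellipsoids
#' are placed on a jittered cell grid, which guarantees that regions are
#' contiguous, non-overlapping, and exactly mirror-symmetric.
#'
#' Labels are integers `1..2*n_region_pairs`; pair `p` occupies labels
#' `2p-1` (left) and `2p` (right); label 0 is background.
#'
#' @param grid_shape integer triple, each dimension at least 8.
#' @param n_region_pairs number of hemisphere pairs (1 to 45; 45 gives the
#'   90 labels of a full AAL-style parcellation).
#' @param seed integer seed controlling cell choice, jitter and radii.
#' @return an object of class `bf_atlas`: list with `labels` (3D integer
#'   array), `names` (character vector indexed by label), `hemi_pairs`
#'   (integer vector mapping each left label to its right partner),
#'   `grid_shape`, and `n_pairs`.
#' @examples
#' atl <- make_atlas(c(24, 28, 24), n_region_pairs = 4, seed = 1)
#' table(atl$labels)[-1]  # 8 non-background labels
#' @export
make_atlas <- function(grid_shape, n_region_pairs = 45L, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (any(grid_shape < 8L)) {
    stop("all grid dimensions must be >= 8", call. = FALSE)
  }
  n_region_pairs <- as.integer(n_region_pairs)
  if (n_region_pairs < 1L || n_region_pairs > 45L) {
    stop("n_region_pairs must be between 1 and 45", call. = FALSE)
  }

  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  half_x <- nx %/% 2L  # left hemisphere: x in 1..half_x (odd nx leaves a
                       # one-voxel mid-sagittal background column)

  # minimal cell edge is 3 voxels so every cell can host an ellipsoid with
  # radius >= 1 strictly inside it
  max_cells <- c(half_x %/% 3L, ny %/% 3L, nz %/% 3L)
  if (prod(max_cells) < n_region_pairs) {
    stop(sprintf(
      "cannot pack %d region pairs into a %dx%dx%d grid (capacity %d)",
      n_region_pairs, nx, ny, nz, prod(max_cells)), call. = FALSE)
  }

  # smallest cell grid (fewest, hence largest, cells) with enough capacity
  n_cells <- c(1L, 1L, 1L)
  while (prod(n_cells) < n_region_pairs) {
    grow <- which(n_cells < max_cells)
    # grow the axis whose cells are currently largest
    sizes <- c(half_x, ny, nz) / n_cells
    ax <- grow[which.max(sizes[grow])]
    n_cells[ax] <- n_cells[ax] + 1L
  }

  bounds <- function(extent, k) {
    cuts <- floor(seq(0L, extent, length.out = k + 1L))
    cbind(lo = cuts[-(k + 1L)] + 1L, hi = cuts[-1L])
  }
  bx <- bounds(half_x, n_cells[1L])
  by <- bounds(ny, n_cells[2L])
  bz <- bounds(nz, n_cells[3L])

  cells <- expand.grid(i = seq_len(n_cells[1L]), j = seq_len(n_cells[2L]),
                       k = seq_len(n_cells[3L]))

  labels <- array(0L, dim = grid_shape)
  with_seed(seed, {
    pick <- sample.int(nrow(cells), n_region_pairs)
    for (p in seq_len(n_region_pairs)) {
      cc <- cells[pick[p], ]
      lo <- c(bx[cc$i, "lo"], by[cc$j, "lo"], bz[cc$k, "lo"])
      hi <- c(bx[cc$i, "hi"], by[cc$j, "hi"], bz[cc$k, "hi"])
      mid <- (lo + hi) / 2
      halfw <- (hi - lo + 1) / 2
      # jittered center, radii strictly inside the cell
      ctr <- mid + stats::runif(3, -0.15, 0.15) * halfw
      rad <- pmax(1.0, (halfw - 0.51) * stats::runif(3, 0.7, 0.98))

      xr <- lo[1L]:hi[1L]; yr <- lo[2L]:hi[2L]; zr <- lo[3L]:hi[3L]
      dx2 <- ((xr - ctr[1L]) / rad[1L])^2
      dy2 <- ((yr - ctr[2L]) / rad[2L])^2
      dz2 <- ((zr - ctr[3L]) / rad[3L])^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
      if (!any(inside)) {  # guarantee a non-empty region
        inside[which.min(outer(outer(dx2, dy2, `+`), dz2, `+`))] <- TRUE
      }
      sub <- labels[xr, yr, zr, drop = FALSE]
      sub[inside] <- 2L * p - 1L
      labels[xr, yr, zr] <- sub
    }
  })

  # mirror the left labels into the right hemisphere
  mirror_x <- nx:1L
  right <- labels[mirror_x, , , drop = FALSE]
  right[right > 0L] <- right[right > 0L] + 1L
  labels[right > 0L] <- right[right > 0L]

  nm <- character(2L * n_region_pairs)
  nm[2L * seq_len(n_region_pairs) - 1L] <- sprintf("Region%02d.L", seq_len(n_region_pairs))
  nm[2L * seq_len(n_region_pairs)] <- sprintf("Region%02d.R", seq_len(n_region_pairs))
  pairs <- stats::setNames(2L * seq_len(n_region_pairs),
                           as.character(2L * seq_len(n_region_pairs) - 1L))

  structure(list(labels = labels, names = nm, hemi_pairs = pairs,
                 grid_shape = grid_shape, n_pairs = n_region_pairs),
            class = "bf_atlas")
}

#' @export
print.bf_atlas <- function(x, ...) {
  cat(sprintf("<bf_atlas> %s grid, %d region pairs (%d labels), %d labeled voxels\n",
              paste(x$grid_shape, collapse = "x"), x$n_pairs, 2L * x$n_pairs,
              sum(x$labels > 0L)))
  invisible(x)
}

# voxel indices (flat, column-major) for one label
atlas_label_voxels <- function(atlas, label) which(atlas$labels == label)

#' Mean gray-matter intensity per region pair
#'
#' The synthetic analogue of regional volumetry: per subject, the mean
#' voxel intensity over both hemispheres of each region pair.
#'
#' @param volumes list of 3D arrays on the atlas grid.
#' @param atlas a [make_atlas()] result.
#' @return numeric matrix (n x n_pairs) with `RegionXX` column names.
#' @export
region_mean_features <- function(volumes, atlas) {
  stopifnot(inherits(atlas, "bf_atlas"))
  lab <- as.vector(atlas$labels)
  pair_of <- integer(2L * atlas$n_pairs)
  pair_of[2L * seq_len(atlas$n_pairs) - 1L] <- seq_len(atlas$n_pairs)
  pair_of[2L * seq_len(atlas$n_pairs)] <- seq_len(atlas$n_pairs)
  grp <- ifelse(lab > 0L, pair_of[pmax(lab, 1L)], 0L)
  keep <- grp > 0L
  counts <- tabulate(grp[keep], nbins = atlas$n_pairs)
  out <- t(vapply(volumes, function(v) {
    acc <- rowsum(as.vector(v)[keep], group = grp[keep])
    drop(acc) / counts
  }, numeric(atlas$n_pairs)))
  colnames(out) <- sprintf("Region%02d", seq_len(atlas$n_pairs))
  out
}
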