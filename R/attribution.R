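# Grad-CAM attention for the scalar-output 3D network, cohort averaging,
# and atlas-based region-importance scoring.
#
# Channel weights are the spatial averages of d(predicted age)/d(final
# convolutional feature maps); the map is the rectified weighted sum of
# those maps, upsampled to the input grid. Per-region raw importance is
# (sum of attention values) / (voxel count); hemisphere pairs are averaged,
# scores min-max normalized to [0, 1] and ranked.

#' Grad-CAM attention map for one volume
#'
#' @param model trained [build_network()] model.
#' @param volume 3D array matching the model's input shape.
#' @param upsample `"trilinear"` (default) or `"nearest"`.
#' @return object of class `bf_attention`: `grid` (non-negative 3D array on
#'   the input grid), `source`, `fingerprint`.
#' @export
grad_cam <- function(model, volume, upsample = c("trilinear", "nearest")) {
  stopifnot(inherits(model, "bf_model"))
  upsample <- match.arg(upsample)
  if (model$spec$n_blocks < 1L) {
    stop("model has no convolutional stage", call. = FALSE)
  }
  if (!identical(dim(volume), as.integer(model$spec$input_shape))) {
    stop("volume shape does not match the model input shape", call. = FALSE)
  }
  X <- vol_to_mat(volume)
  fwd <- net_forward(model, X, B = 1L, train = FALSE)
  g <- net_backward(model, fwd, dpred = 1, B = 1L, trainable = "fc",
                    through_conv = TRUE)
  G <- g[[".d_conv_out"]]                     # (Vf) x Cf gradient
  alpha <- colMeans(G)                        # spatially averaged weights
  cam <- pmax(drop(fwd$conv_out %*% alpha), 0)
  arr <- array(cam, dim = fwd$conv_shape)
  up <- if (upsample == "trilinear") {
    upsample_trilinear(arr, model$spec$input_shape)
  } else {
    upsample_nearest(arr, model$spec$input_shape)
  }
  structure(list(grid = up, source = "single-subject",
                 fingerprint = model$fingerprint),
            class = "bf_attention")
}

#' Voxelwise average of attention maps
#'
#' @param maps non-empty list of [grad_cam()] results with identical shapes.
#' @return `bf_attention` with `source = "cohort-average"`.
#' @export
average_attention <- function(maps) {
  stopifnot(length(maps) >= 1L)
  shp <- dim(maps[[1L]]$grid)
  acc <- array(0, dim = shp)
  for (m in maps) {
    stopifnot(inherits(m, "bf_attention"))
    if (!identical(dim(m$grid), shp)) {
      stop("attention map shape mismatch", call. = FALSE)
    }
    acc <- acc + m$grid
  }
  structure(list(grid = acc / length(maps), source = "cohort-average",
                 fingerprint = maps[[1L]]$fingerprint),
            class = "bf_attention")
}

#' Atlas-based region importance from an attention map
#'
#' Raw per-label importance is (sum of attention values in the label) /
#' (label voxel count). Hemisphere partners are averaged to one score per
#' pair (45 scores for a 90-label atlas), min-max normalized to \[0, 1\]
#' and ranked in descending order; the `top_k` highest are flagged.
#'
#' When every pair scores identically the min-max map is degenerate; all
#' normalized scores are then defined as 1 (with a warning), preserving the
#' "top region scores 1.00" reading. Empty labels are excluded with a
#' warning.
#'
#' @param attention a [grad_cam()] or [average_attention()] result.
#' @param atlas a [make_atlas()] result on the same grid.
#' @param top_k number of regions to flag (default 8).
#' @return data.frame (class `bf_importance`): `pair`, `region`, `size`
#'   (voxels in the pair), `raw`, `normalized`, `rank`, `top`.
#' @export
region_importance <- function(attention, atlas, top_k = 8L) {
  stopifnot(inherits(attention, "bf_attention"), inherits(atlas, "bf_atlas"))
  if (!identical(dim(attention$grid), dim(atlas$labels))) {
    stop("attention map and atlas are on different grids", call. = FALSE)
  }
  att <- as.vector(attention$grid)
  lab <- as.vector(atlas$labels)
  nlab <- 2L * atlas$n_pairs
  counts <- tabulate(lab, nbins = nlab)
  sums <- numeric(nlab)
  acc <- rowsum(att[lab > 0L], group = lab[lab > 0L])
  sums[as.integer(rownames(acc))] <- acc
  raw_label <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  for (l in which(counts == 0L)) {
    warning(sprintf("label %d (%s) has no voxels; excluded from its pair score",
                    l, atlas$names[l]), call. = FALSE)
  }
  left <- 2L * seq_len(atlas$n_pairs) - 1L
  right <- left + 1L
  raw <- rowMeans(cbind(raw_label[left], raw_label[right]), na.rm = TRUE)
  region <- sub("\\.L$", "", atlas$names[left])
  size <- counts[left] + counts[right]
  ok <- is.finite(raw)
  if (!any(ok)) stop("no region has voxels", call. = FALSE)
  rng <- range(raw[ok])
  degenerate <- rng[2L] <= rng[1L]
  if (!degenerate) {
    normalized <- (raw - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    # a flat map (e.g. fully rectified Grad-CAM) carries no ordering
    # information: keep the "top region scores 1.00" convention but leave
    # ranks undefined
    warning("all region scores equal; normalized importance set to 1",
            call. = FALSE)
    normalized <- ifelse(ok, 1, NA_real_)
  }
  rank <- rep(NA_integer_, length(raw))
  if (!degenerate) {
    rank[ok] <- as.integer(rank(-raw[ok], ties.method = "min"))
  }
  out <- data.frame(pair = seq_len(atlas$n_pairs), region = region,
                    size = size, raw = raw, normalized = normalized,
                    rank = rank, top = !is.na(rank) & rank <= top_k,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("bf_importance", "data.frame")
  out
}

#' Cohort attention workflow
#'
#' Computes per-subject Grad-CAM maps with the final model, averages them,
#' and scores regions against the atlas — the standard interpretation path
#' after fine-tuning.
#'
#' @param model trained model; `volumes` evaluation cohort (scaled);
#'   `atlas` matching atlas; `top_k` regions to flag.
#' @param volumes,atlas,top_k see above.
#' @return list with `average` (`bf_attention`) and `importance`
#'   (`bf_importance`).
#' @export
attention_importance <- function(model, volumes, atlas, top_k = 8L) {
  maps <- lapply(volumes, function(v) grad_cam(model, v))
  avg <- average_attention(maps)
  list(average = avg, importance = region_importance(avg, atlas, top_k))
}
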