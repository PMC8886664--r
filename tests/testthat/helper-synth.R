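# Shared fixtures: everything is generated in code at test time.

# a small cohort with clear atrophy signal on a 24x28x24 grid
tiny_cohort <- function(n = 40, pairs = 4L, seed = 1L,
                        grid = c(24L, 28L, 24L),
                        slopes = rep(0.008, pairs), ...) {
  cfg <- simulation_config(n_subjects = n, grid_shape = grid,
                           n_region_pairs = pairs,
                           atrophy_slopes = slopes, seed = seed, ...)
  simulate_cohort(cfg)
}

# blood settings where the panel carries a strong age signal independent of
# the image (the fusion-benefit study condition)
strong_blood_effects <- function() {
  be <- default_blood_effects()
  be$slope[be$param == "NFL"] <- 0.04
  be$sd[be$param == "NFL"] <- 0.20
  be$slope[be$param == "Abeta40"] <- 0.02
  be$sd[be$param == "Abeta40"] <- 0.20
  be$slope[be$param == "HCY"] <- 0.02
  be$sd[be$param == "HCY"] <- 0.20
  be
}

# scaled-down network: the paper's architecture with narrow widths and a
# larger learning rate fit to the desk-scale step budget
small_netspec <- function(grid = c(24L, 28L, 24L), n_blocks = 5L,
                          widths = c(2L, 4L, 8L, 8L, 8L)[seq_len(n_blocks)],
                          embedding = 32L, lr = 3e-3, batch = 8L) {
  network_spec(grid, n_blocks = n_blocks, block_channels = widths,
               embedding_dim = embedding, learning_rate = lr,
               batch_size = batch)
}

# brute-force MCB oracle: count sketch of the flattened outer product under
# the combined hash h(i,j) = ((h1(i)-1 + h2(j)-1) mod d) + 1, s = s1*s2
mcb_oracle <- function(x, y, spec) {
  d <- spec$d
  out <- numeric(d)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      b <- ((spec$h[[1]][i] - 1L + spec$h[[2]][j] - 1L) %% d) + 1L
      out[b] <- out[b] + spec$s[[1]][i] * spec$s[[2]][j] * x[i] * y[j]
    }
  }
  out
}
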