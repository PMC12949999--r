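# shared fixtures and independent brute-force oracles

localization_geometry <- function() voxel_geometry(0.065, 0.065, 0.5, 15, 21L)

# per-file cache so expensive simulations are built once per test file
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_sim <- function(seed = 3) cached(paste0("sim", seed), function() {
  cfg <- sim_preset("fusogenic-default", seed = seed,
                    frame_times_min = c(0, 30, 60))
  list(cfg = cfg, sim = simulate_fov(cfg, seed = seed))
})

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

truth_positions <- function(truth, frame) {
  vis <- which(!is.na(truth$traj_um[, frame, 1]))
  matrix(truth$traj_um[vis, frame, ], ncol = 3)
}

spot_xyz <- function(spots) as.matrix(spots[, c("z_um", "y_um", "x_um")])

# O(n*k) per-voxel reference for outlier removal (3x3 in-plane median)
bf_remove_outliers <- function(vol, factor = 3) {
  d <- dim(vol)
  out <- vol
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    ys <- max(1, y - 1):min(d[2], y + 1)
    xs <- max(1, x - 1):min(d[3], x + 1)
    med <- median(vol[z, ys, xs])
    if (vol[z, y, x] > factor * med) out[z, y, x] <- med
  }
  out
}

# per-pixel disc median reference
bf_median_disc <- function(vol, r) {
  d <- dim(vol)
  out <- vol
  off <- expand.grid(a = -r:r, b = -r:r)
  off <- off[off$a^2 + off$b^2 <= r^2, ]
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    ys <- y + off$a; xs <- x + off$b
    ok <- ys >= 1 & ys <= d[2] & xs >= 1 & xs <= d[3]
    out[z, y, x] <- median(vol[cbind(z, ys[ok], xs[ok])])
  }
  out
}

# all-pairs anisotropic distance to nearest foreground voxel
bf_nearest_dist <- function(mask, pitch) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(fg) == 0L) return(out)
  for (i in seq_len(prod(d))) {
    v <- arrayInd(i, d)
    out[i] <- sqrt(min(colSums((t(fg) - as.numeric(v))^2 * pitch^2)))
  }
  out
}

bf_signed_dist <- function(mask, pitch) {
  out <- bf_nearest_dist(mask, pitch)
  din <- bf_nearest_dist(!mask, pitch)
  out[mask] <- -din[mask]
  out
}

# voxel-by-voxel overlap count reference
bf_overlap <- function(voxel_set, mask, thr) {
  n <- 0L
  for (i in seq_len(nrow(voxel_set)))
    if (mask[voxel_set[i, 1], voxel_set[i, 2], voxel_set[i, 3]]) n <- n + 1L
  n >= thr
}
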