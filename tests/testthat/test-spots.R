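test_that("a single punctum at SNR 8 yields exactly one sub-voxel spot", {
  cfg <- simulation_config(n_cells = 1, cell_radius_um = 5, ev_dose = 1,
                           bind_rate = 50, internalize_delay_min = 1e6,
                           field_px = c(y = 120L, x = 120L),
                           frame_times_min = 30, seed = 21)
  sim <- simulate_fov(cfg, seed = 21)
  expect_equal(sum(!is.na(sim$truth$traj_um[, 1, 1])), 1L)
  red <- preprocess_frame(get_frame(sim$stack, "ev_red", 1),
                          preprocess_params())
  sp <- detect_spots(red, cfg$geometry)
  expect_equal(nrow(sp), 1L)
  truth <- sim$truth$traj_um[1, 1, ]
  expect_lt(abs(sp$y_um - truth[2]), cfg$geometry$dy + 1e-9)
  expect_lt(abs(sp$x_um - truth[3]), cfg$geometry$dx + 1e-9)
})

test_that("noise-only frames essentially never produce spots", {
  # false-positive rate <= 0.1 per 1e6 voxels over 20 seeds means zero
  # detections are allowed on this total volume (20 x 180k voxels)
  cfg <- sim_preset("no-ev")
  fp <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    noise <- evspot:::.apply_noise(array(0, c(11, 128, 128)), cfg$noise)
    v <- preprocess_frame(noise, preprocess_params())
    fp <- fp + nrow(detect_spots(v, cfg$geometry))
  }
  expect_equal(fp, 0L)
})

test_that("well-separated puncta are detected individually", {
  g <- voxel_geometry(0.13, 0.13, 1, 15, 11L)
  pitch <- c(g$dz, g$dy, g$dx)
  base <- array(0, c(11, 100, 100))
  sig <- c(0.7, 0.34, 0.34)
  p1 <- c(5, 5, 5); p2 <- c(5, 5, 8); p3 <- c(4, 9, 4)  # >= 3 um apart
  for (p in list(p1, p2, p3))
    base <- evspot:::.add_blob(base, p, 1500, sig, pitch)
  set.seed(22)
  frame <- evspot:::.apply_noise(base,
                                 c(offset = 100, gaussian_sd = 10,
                                   poisson_scale = 10))
  v <- preprocess_frame(frame, preprocess_params())
  sp <- detect_spots(v, g)
  expect_equal(nrow(sp), 3L)
  m <- match_spots(spot_xyz(sp), rbind(p1, p2, p3), tol_um = 1)
  expect_equal(m$recall, 1)
})

test_that("detection is equivariant under whole-voxel translations", {
  g <- voxel_geometry(0.13, 0.13, 1, 15, 11L)
  pitch <- c(g$dz, g$dy, g$dx)
  base <- array(0, c(11, 90, 90))
  for (p in list(c(5, 4, 4), c(6, 8, 7)))
    base <- evspot:::.add_blob(base, p, 1500, c(0.7, 0.34, 0.34), pitch)
  set.seed(23)
  frame <- evspot:::.apply_noise(base, c(offset = 100, gaussian_sd = 10,
                                         poisson_scale = 10))
  shift <- 10L  # pixels in x
  a <- preprocess_frame(frame[, , 1:70], preprocess_params())
  b <- preprocess_frame(frame[, , (1 + shift):(70 + shift)],
                        preprocess_params())
  sa <- detect_spots(a, g); sb <- detect_spots(b, g)
  expect_equal(nrow(sa), nrow(sb))
  ord_a <- order(sa$y_um, sa$x_um); ord_b <- order(sb$y_um, sb$x_um)
  expect_equal(sa$x_um[ord_a] - sb$x_um[ord_b],
               rep(shift * g$dx, nrow(sa)), tolerance = 0.05)
  expect_equal(sa$y_um[ord_a], sb$y_um[ord_b], tolerance = 0.05)
})

test_that("spot footprints have the documented geometry", {
  g <- localization_geometry()
  dims <- c(21L, 200L, 200L)
  pitch <- c(g$dz, g$dy, g$dx)
  fp <- spot_footprint_idx(c(11, 100, 100), dims, pitch, 0.5,
                           evspot:::.footprint_rz(0.5, 1.96))
  # voxel count approximates the 1.96 um^3 target footprint (staircase
  # error of the 0.5-um Z sampling keeps this within a few percent)
  expect_lt(abs(nrow(fp) * g$voxel_volume - 1.96) / 1.96, 0.05)
  # clipped at the border: a corner spot keeps a partial footprint
  fp_edge <- spot_footprint_idx(c(1, 1, 1), dims, pitch, 0.5,
                                evspot:::.footprint_rz(0.5, 1.96))
  expect_lt(nrow(fp_edge), nrow(fp))
  expect_true(all(fp_edge >= 1))
})

test_that("cell association keeps spots by signed distance with exclusions", {
  g <- voxel_geometry(0.5, 0.5, 0.5, 15, 8L)   # isotropic toy
  lab <- array(0L, c(8, 16, 16))
  lab[2:7, 3:10, 3:10] <- 1L
  seg <- cell_segmentation(lab, g)
  d <- distance_to_surface(seg, g)
  # spots at voxel centres so interpolation equals the exact field value
  mk <- function(v) data.frame(z_um = (v[, 1] - 1) * 0.5,
                               y_um = (v[, 2] - 1) * 0.5,
                               x_um = (v[, 3] - 1) * 0.5,
                               z_vox = v[, 1], y_vox = v[, 2], x_vox = v[, 3])
  set.seed(24)
  vox <- cbind(sample(8, 60, TRUE), sample(16, 60, TRUE), sample(16, 60, TRUE))
  spots <- mk(vox)
  pitch <- c(0.5, 0.5, 0.5)
  d_bf <- bf_signed_dist(lab > 0L, pitch)
  kept_prev <- -1L
  for (cutoff in c(0, 0.5, 1, 2, 5)) {
    kept <- filter_cell_associated(spots, d, g, d_assoc_um = cutoff)
    manual <- sum(d_bf[vox] <= cutoff)
    expect_equal(nrow(kept), manual)
    expect_gte(nrow(kept), kept_prev)     # monotone in the cutoff
    kept_prev <- nrow(kept)
  }
  # spots inside an excluded (bright) cell are dropped
  seg_ex <- cell_segmentation(lab, g, excluded_labels = 1L)
  d_ex <- distance_to_surface(seg_ex, g)
  kept <- filter_cell_associated(spots, d_ex, g, d_assoc_um = 1, seg = seg_ex)
  expect_true(all(lab[as.matrix(kept[, c("z_vox", "y_vox", "x_vox")])] == 0L))
  # empty segmentation: infinite distances, nothing is associated
  seg0 <- cell_segmentation(array(0L, c(8, 16, 16)), g)
  kept0 <- filter_cell_associated(spots, distance_to_surface(seg0, g), g)
  expect_equal(nrow(kept0), 0L)
})

test_that("membrane proximity splits cell-associated spots into a partition", {
  spots <- data.frame(surface_dist_um = c(-0.3, -3, 0.2, -0.49, -0.51, 0.49))
  cls <- classify_membrane_proximity(spots)
  expect_equal(as.character(cls$membrane_class),
               c("proximal", "distal", "proximal", "proximal", "distal",
                 "proximal"))
  for (cutoff in c(0.1, 0.5, 2)) {
    cls <- classify_membrane_proximity(spots, cutoff)
    expect_equal(sum(cls$membrane_class == "proximal") +
                   sum(cls$membrane_class == "distal"), nrow(spots))
  }
  expect_error(classify_membrane_proximity(data.frame(x = 1)),
               "filter_cell_associated")
})

test_that("proximal-to-distal transitions track internalization times", {
  cfg <- sim_preset("fusogenic-default", seed = 31,
                    frame_times_min = seq(0, 60, by = 15))
  sim <- simulate_fov(cfg, seed = 31)
  g <- cfg$geometry
  gt <- sim$truth
  times <- cfg$frame_times_min
  # classify detected spots per frame; track each EV by nearest centroid
  cls <- vector("list", length(times))
  for (fr in seq_along(times)) {
    red <- preprocess_frame(get_frame(sim$stack, "ev_red", fr),
                            preprocess_params())
    green <- preprocess_frame(get_frame(sim$stack, "reporter_green", fr),
                              preprocess_params())
    seg <- segment_cells(green, g)
    d <- distance_to_surface(seg, g)
    sp <- detect_spots(red, g)
    sp <- filter_cell_associated(sp, d, g)
    cls[[fr]] <- classify_membrane_proximity(sp)
  }
  hits <- 0L; tracked <- 0L
  for (i in seq_len(nrow(gt$ev))) {
    t_int <- gt$ev$t_internalize_min[i]
    if (!is.finite(t_int) || t_int > max(times) - 15) next
    if (gt$ev$t_bind_min[i] > t_int) next
    # the EV must be visible (and matched) in every frame after binding
    frames <- which(times >= gt$ev$t_bind_min[i])
    states <- rep(NA_character_, length(frames))
    ok <- TRUE
    for (k in seq_along(frames)) {
      fr <- frames[k]
      pos <- gt$traj_um[i, fr, ]
      sp <- cls[[fr]]
      if (nrow(sp) == 0L) { ok <- FALSE; break }
      dd <- sqrt((sp$z_um - pos[1])^2 + (sp$y_um - pos[2])^2 +
                   (sp$x_um - pos[3])^2)
      if (min(dd) > 1) { ok <- FALSE; break }
      states[k] <- as.character(sp$membrane_class[which.min(dd)])
    }
    if (!ok) next
    first_distal <- which(states == "distal")[1]
    if (is.na(first_distal)) next
    tracked <- tracked + 1L
    observed <- times[frames[first_distal]]
    expected <- times[which(times >= t_int)[1]]
    if (abs(observed - expected) <= 15 + 1e-9) hits <- hits + 1L
  }
  expect_gte(tracked, 10L)
  expect_gte(hits / tracked, 0.8)
})

test_that("nearest-centroid matching is one-to-one and scores correctly", {
  det <- rbind(c(0, 0, 0), c(0, 5, 5), c(0, 9, 9))
  tru <- rbind(c(0, 0.2, 0), c(0, 5, 5.3), c(0, 20, 20))
  m <- match_spots(det, tru, tol_um = 1)
  expect_equal(nrow(m$matches), 2L)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_true(!anyDuplicated(m$matches$det) && !anyDuplicated(m$matches$truth))
})
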