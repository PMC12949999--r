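test_that("simulation configs enforce their invariants", {
  expect_error(simulation_config(frame_times_min = c(0, 0, 15)),
               "strictly increasing")
  expect_error(simulation_config(fuse_fraction = 1.5))
  cfg <- simulation_config(fusogenic = FALSE, fuse_fraction = 0.8)
  expect_equal(cfg$fuse_fraction, 0)    # non-fusogenic forces 0
  expect_error(simulate_cell_field(simulation_config(n_cells = 0)),
               "n_cells")
})

test_that("a single spherical cell is voxelized to its analytic volume", {
  cfg <- simulation_config(n_cells = 1, cell_radius_um = 5,
                           cell_radius_sd_um = 0, cell_aspect_z = 1,
                           deform = 0, ev_dose = 0,
                           field_px = c(y = 120L, x = 120L),
                           frame_times_min = 0, seed = 1)
  cf <- simulate_cell_field(cfg, seed = 1)
  expect_length(cf$cell_volumes_um3, 1L)
  analytic <- 4 / 3 * pi * 5^3
  expect_lt(abs(sum(cf$cell_volumes_um3) - analytic) / analytic, 0.05)
  # nucleus strictly inside its cell
  expect_true(all(cf$labels[cf$nucleus_mask] == 1L))
})

test_that("cell fields and schedules are deterministic in the seed", {
  cfg <- sim_preset("demo", seed = 7)
  a <- simulate_cell_field(cfg, seed = 7)
  b <- simulate_cell_field(cfg, seed = 7)
  expect_identical(a$labels, b$labels)
  ga <- simulate_event_schedule(cfg, a, seed = 7)
  gb <- simulate_event_schedule(cfg, b, seed = 7)
  expect_identical(ga$ev, gb$ev)
  expect_identical(ga$traj_um, gb$traj_um)
})

test_that("degenerate rates yield empty schedules, not errors", {
  cfg <- sim_preset("demo", seed = 2, bind_rate = 0)
  cf <- simulate_cell_field(cfg, seed = 2)
  gt <- simulate_event_schedule(cfg, cf, seed = 2)
  expect_true(all(gt$per_frame$n_bound == 0))
  expect_true(all(gt$per_frame$n_internalized == 0))
  expect_true(all(is.na(gt$traj_um)))
})

test_that("event ordering bind <= internalize <= fuse always holds", {
  cfg <- sim_preset("demo", seed = 3, ev_dose = 40)
  cf <- simulate_cell_field(cfg, seed = 3)
  gt <- simulate_event_schedule(cfg, cf, seed = 3)
  ev <- gt$ev
  expect_true(all(ev$t_bind_min <= ev$t_internalize_min))
  fin <- is.finite(ev$t_fuse_min)
  expect_true(any(fin))
  expect_true(all(ev$t_internalize_min[fin] <= ev$t_fuse_min[fin]))
  expect_true(all(diff(gt$per_frame$n_fused_cumulative) >= 0))
})

test_that("non-fusogenic schedules never fuse", {
  cfg <- sim_preset("no-fusogen", seed = 4, frame_times_min = c(0, 60))
  cf <- simulate_cell_field(cfg, seed = 4)
  gt <- simulate_event_schedule(cfg, cf, seed = 4)
  expect_true(all(!is.finite(gt$ev$t_fuse_min)))
  expect_true(all(gt$per_frame$n_fused_cumulative == 0))
})

test_that("fusion kinetics plateau matches the closed-form gamma CDF", {
  # near-instant binding isolates the gamma fusion clock: with the median
  # fusion time ~40 min the cumulative curve must be nearly saturated by
  # 60 min relative to 120 min
  shape <- 16; scale <- 40 / qgamma(0.5, 16)
  cfg <- sim_preset("demo", seed = 5, ev_dose = 5000, bind_rate = 100,
                    fuse_fraction = 1, fuse_time_dist = c(shape, scale),
                    frame_times_min = c(60, 120))
  cf <- simulate_cell_field(cfg, seed = 5)
  gt <- simulate_event_schedule(cfg, cf, seed = 5)
  emp <- gt$per_frame$n_fused_cumulative
  ratio <- emp[1] / emp[2]
  theor <- pgamma(60, shape, scale = scale) / pgamma(120, shape, scale = scale)
  expect_gte(ratio, 0.9)
  expect_lt(abs(ratio - theor), 0.02)
})

test_that("every bound or internalized EV is rendered as one red punctum", {
  s <- small_sim(3)
  gt <- s$sim$truth
  for (fr in seq_len(nrow(gt$per_frame))) {
    visible <- sum(!is.na(gt$traj_um[, fr, 1]))
    expect_equal(visible,
                 gt$per_frame$n_bound[fr] + gt$per_frame$n_internalized[fr])
  }
})

test_that("expected red spot count responds monotonically to dose", {
  doses <- c(2, 5, 10)
  mean_bound <- sapply(doses, function(d) {
    counts <- sapply(1:5, function(rep) {
      cfg <- sim_preset("demo", seed = 50 + rep, ev_dose = d,
                        frame_times_min = 60)
      cf <- simulate_cell_field(cfg, seed = 50 + rep)
      gt <- simulate_event_schedule(cfg, cf, seed = 50 + rep)
      sum(!is.na(gt$traj_um[, 1, 1]))
    })
    mean(counts)
  })
  expect_gte(cor(doses, mean_bound, method = "spearman"), 0)
  expect_true(all(diff(mean_bound) > 0))
})

test_that("rendering is bit-identical for identical seeds", {
  cfg <- sim_preset("demo", seed = 6, frame_times_min = c(0, 30))
  a <- simulate_fov(cfg, seed = 6)
  b <- simulate_fov(cfg, seed = 6)
  expect_identical(a$stack$data, b$stack$data)
})

test_that("a zero-EV render leaves the red channel at the noise floor", {
  cfg <- sim_preset("no-ev", seed = 8, frame_times_min = 60)
  sim <- simulate_fov(cfg, seed = 8)
  red_raw <- get_frame(sim$stack, "ev_red", 1)
  # raw intensities are offset + read + shot noise only
  expect_lt(quantile(red_raw, 0.999), cfg$noise[["offset"]] + 60)
  red <- preprocess_frame(red_raw, preprocess_params())
  expect_equal(nrow(detect_spots(red, cfg$geometry)), 0L)
})

test_that("one fused EV renders a green maximum at its true position", {
  cfg <- simulation_config(n_cells = 1, cell_radius_um = 5, ev_dose = 1,
                           bind_rate = 50, internalize_delay_min = 0.05,
                           fusogenic = TRUE, fuse_fraction = 1,
                           fuse_time_dist = c(shape = 2, scale = 0.2),
                           field_px = c(y = 120L, x = 120L),
                           frame_times_min = 30, seed = 9)
  sim <- simulate_fov(cfg, seed = 9)
  pos <- sim$truth$traj_um[1, 1, ]
  expect_true(is.finite(sim$truth$ev$t_fuse_min[1]))
  green <- get_frame(sim$stack, "reporter_green", 1)
  pk <- arrayInd(which.max(green), dim(green))
  pitch <- c(cfg$geometry$dz, cfg$geometry$dy, cfg$geometry$dx)
  offset <- abs((as.numeric(pk) - 1) * pitch - pos)
  # shot noise can tip the raw argmax between adjacent near-equal voxels
  expect_true(all(offset <= 1.5 * pitch + 1e-9))
})

test_that("dye channels return their generating masks as ground truth", {
  cfg <- sim_preset("localization", seed = 10, frame_times_min = c(0, 60))
  cf <- simulate_cell_field(cfg, seed = 10)
  gt <- simulate_event_schedule(cfg, cf, seed = 10)
  expect_error(render_dye_channel("nope", cf, gt, cfg), "arg")

  # frame 1 (t = 0): no internalized EVs yet, so the membrane mask is the
  # pure surface shell; reconstruct the same physically thin shell here
  dye <- render_dye_channel("membrane_mask", cf, gt, cfg, frame = 1L,
                            seed = 10)
  fg <- cf$labels > 0L
  pitch <- c(cfg$geometry$dz, cfg$geometry$dy, cfg$geometry$dx)
  dsq <- evspot:::cpp_edt3d_sq(!fg, dim(fg), pitch)
  shell <- fg & sqrt(dsq) <= 0.35 + 1e-9
  expect_gte(dice_coef(dye$mask, shell), 0.9)
  expect_true(all(dye$volume[dye$mask] > 0))
  expect_true(all(dye$volume[!dye$mask] == 0))

  ac <- render_dye_channel("acidic_puncta", cf, gt, cfg,
                           seed = 10)
  expect_gt(sum(ac$mask), 0)
  cfg0 <- sim_preset("localization", seed = 10, acidic_puncta_per_cell = 0,
                     frame_times_min = c(0, 60))
  ac0 <- render_dye_channel("acidic_puncta", cf, gt, cfg0, seed = 10)
  expect_equal(sum(ac0$mask), 0L)

  nls <- render_dye_channel("nucleus_nls", cf, gt, cfg, seed = 10)
  expect_identical(nls$mask, cf$nucleus_mask)
})
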