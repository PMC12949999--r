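#' Simulation configuration for synthetic EV time-lapse stacks
#'
#' Defines the study conditions emulated by the synthetic generator: a
#' confluent monolayer of reporter cells expressing a cytosolic green
#' reporter and a blue nuclear label, red punctate EV signal accumulating
#' on and in the cells, and (in fusogenic conditions only) green fusion
#' puncta that rise over the first hour and then plateau.
#'
#' Scaled-down defaults: the imaged field is 256 x 256 px at 0.13 um XY
#' (2 x 2 camera binning of the native 0.065 um pixel) and 11 Z-slices of
#' 1 um, holding 9 cells, dosed so that roughly 50 puncta
#' per field are in play (5.5 per cell across 9 cells) at a surface density where individual puncta
#' remain optically resolvable -- the density regime of the emulated
#' assay, scaled down from thousands of EVs per cell on a camera-sized
#' field, which is not desk-scale. Noise parameters give a signal-to-
#' noise ratio of about 8 at punctum centres, a standard sCMOS operating
#' point.
#'
#' @param n_cells number of cells in the field.
#' @param cell_radius_um,cell_radius_sd_um mean and SD of the in-plane cell
#'   radius (um).
#' @param cell_aspect_z axial radius as a fraction of the in-plane radius
#'   (cells in a monolayer are flattened).
#' @param deform relative amplitude of random in-plane radius deformation.
#' @param nucleus_radius_fraction nucleus radii as a fraction of cell radii.
#' @param ev_dose EVs per cell (dimensionless); 0 gives a no-EV control.
#' @param bind_rate per-EV per-minute binding probability scale
#'   (exponential rate); 0 means no EV ever binds.
#' @param internalize_delay_min mean bound-to-internalized delay (min).
#' @param fusogenic do EVs carry a fusogen? `FALSE` forces
#'   `fuse_fraction = 0`.
#' @param fuse_time_dist `c(shape, scale)` of the gamma distribution of the
#'   fusion delay after binding (min).
#' @param fuse_fraction fraction of EVs competent to fuse, in `[0, 1]`.
#' @param fusion_lifetime_min visible lifetime of a green fusion punctum
#'   before its intensity redistributes to a faint cell-boundary shell.
#' @param internalization_depth_um depth below the surface at which the
#'   endosome forms on internalization.
#' @param inward_speed_um_min slow further inward drift after
#'   internalization.
#' @param walk_sd_um per-frame random-walk jitter of internalized EVs.
#' @param spot_fwhm_um apparent XY full width at half maximum of a rendered
#'   punctum (single EVs are sub-resolution; this is what the microscope
#'   records, not the particle size).
#' @param spot_sigma_z_um apparent axial Gaussian sigma of a punctum.
#' @param psf_sigma_um `c(z, y, x)` Gaussian PSF sigmas (um).
#' @param noise `c(offset, gaussian_sd, poisson_scale)`: camera offset,
#'   additive read-noise SD, and the scaling of Poisson shot noise
#'   (variance = signal * poisson_scale).
#' @param ev_amp,fusion_amp peak pre-PSF amplitude of red / green puncta.
#'   The fusion amplitude is several-fold higher than a single-EV signal:
#'   the reporter system concentrates many fluorescent antibodies on the
#'   repeated epitope array of one fused EV, which is the assay's signal
#'   amplification premise. Per-event intensity is unvalidated against
#'   real data and flagged as a placeholder.
#' @param cytosol_level,nucleus_green_level diffuse green reporter levels in
#'   cytosol and nucleus (the reporter is partially excluded from nuclei).
#' @param nucleus_blue_level diffuse nuclear label level.
#' @param dye_level intensity of the far-red dye structures.
#' @param cytosol_depletion_per_fusion relative loss of diffuse green per
#'   cumulative fusion event (reporter sequestration into puncta).
#' @param shell_level_per_expired boundary-shell green intensity added per
#'   expired fusion spot (reporter redistribution to the plasma membrane).
#' @param acidic_puncta_per_cell number of acidic-compartment puncta per
#'   cell in the far-red dye channel.
#' @param field_px `c(y, x)` field size in pixels.
#' @param geometry a [voxel_geometry()]; defaults to the kinetic regime
#'   (11 slices of 1 um, 15-min frames).
#' @param frame_times_min acquisition times (min from EV addition),
#'   strictly increasing.
#' @param dye_kind optional far-red dye channel: one of `membrane_mask`,
#'   `acidic_puncta`, `nucleus_nls`.
#' @param seed default RNG seed used when an operation is not given one.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_cells = 9L,
    cell_radius_um = 5.5, cell_radius_sd_um = 0.4, cell_aspect_z = 0.6,
    deform = 0.08, nucleus_radius_fraction = 0.4,
    ev_dose = 5.5, bind_rate = 0.1, internalize_delay_min = 8,
    fusogenic = FALSE, fuse_time_dist = c(shape = 9, scale = 3.5),
    fuse_fraction = 0.8, fusion_lifetime_min = 45,
    internalization_depth_um = 2.0, inward_speed_um_min = 0.03,
    walk_sd_um = 0.05,
    spot_fwhm_um = 0.8, spot_sigma_z_um = 0.7,
    psf_sigma_um = c(z = 0.6, y = 0.13, x = 0.13),
    noise = c(offset = 100, gaussian_sd = 10, poisson_scale = 10),
    ev_amp = 1500, fusion_amp = 4000,
    cytosol_level = 400, nucleus_green_level = 250,
    nucleus_blue_level = 600, dye_level = 600,
    cytosol_depletion_per_fusion = 0.003, shell_level_per_expired = 5,
    acidic_puncta_per_cell = 6L,
    field_px = c(y = 256L, x = 256L),
    geometry = voxel_geometry(dx = 0.13, dy = 0.13, dz = 1, dt = 15,
                              n_z = 11L),
    frame_times_min = seq(0, 120, by = 15),
    dye_kind = NULL, seed = 1L) {
  stopifnot(cell_radius_um > 0, cell_radius_sd_um >= 0, cell_aspect_z > 0,
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 1,
            ev_dose >= 0, bind_rate >= 0, internalize_delay_min > 0,
            fuse_fraction >= 0, fuse_fraction <= 1,
            all(fuse_time_dist > 0), fusion_lifetime_min > 0,
            spot_fwhm_um > 0, all(psf_sigma_um >= 0),
            length(frame_times_min) >= 1)
  if (is.unsorted(frame_times_min, strictly = TRUE))
    stop("simulation_config: frame_times_min must be strictly increasing")
  if (!is.null(dye_kind))
    dye_kind <- match.arg(dye_kind,
                          c("membrane_mask", "acidic_puncta", "nucleus_nls"))
  if (!isTRUE(fusogenic)) fuse_fraction <- 0
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

#' Named simulation presets
#'
#' Frame-schedule and condition presets matching the three acquisition
#' regimes of the emulated assay (hourly overview, 15-min kinetics, 1-min
#' real-time) and its control conditions.
#'
#' @param name one of `fusogenic-default` (15-min interval, 0-120 min,
#'   fusion-competent EVs), `no-fusogen` (same schedule, EVs that never
#'   fuse), `no-ev` (medium-only control), `hourly` (60-min interval,
#'   0-360 min), `realtime` (1-min interval, first 30 min),
#'   `localization` (0.5-um Z-steps, 21 slices, membrane dye channel), or
#'   `demo` (miniature 2-cell field).
#' @param ... overrides passed on to [simulation_config()].
#' @return A [simulation_config()].
#' @export
sim_preset <- function(name = c("fusogenic-default", "no-fusogen", "no-ev",
                                "hourly", "realtime", "localization",
                                "demo"), ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    "fusogenic-default" = list(fusogenic = TRUE),
    "no-fusogen" = list(fusogenic = FALSE),
    "no-ev" = list(fusogenic = FALSE, ev_dose = 0),
    "hourly" = list(
      fusogenic = TRUE,
      geometry = voxel_geometry(0.13, 0.13, 1, 60, 11L),
      frame_times_min = seq(0, 360, by = 60)),
    "realtime" = list(
      fusogenic = TRUE,
      geometry = voxel_geometry(0.13, 0.13, 1, 1, 11L),
      frame_times_min = seq(0, 30, by = 1)),
    "localization" = list(
      fusogenic = TRUE, dye_kind = "membrane_mask",
      geometry = voxel_geometry(0.13, 0.13, 0.5, 15, 21L),
      frame_times_min = seq(0, 120, by = 15)),
    "demo" = list(
      fusogenic = TRUE, n_cells = 2L, cell_radius_um = 5.5,
      field_px = c(y = 160L, x = 160L), ev_dose = 12,
      frame_times_min = c(0, 30, 60)))
  do.call(simulation_config, utils::modifyList(base, list(...)))
}

# ellipsoid quadratic form over a bounding box; returns list(zi, yi, xi, q)
.ellipsoid_q <- function(centre_um, radii_um, pitch, dims) {
  lo <- pmax(1L, floor((centre_um - radii_um) / pitch) + 1L)
  hi <- pmin(dims, ceiling((centre_um + radii_um) / pitch) + 1L)
  if (any(lo > hi)) return(NULL)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  qz <- (((zi - 1) * pitch[1] - centre_um[1]) / radii_um[1])^2
  qy <- (((yi - 1) * pitch[2] - centre_um[2]) / radii_um[2])^2
  qx <- (((xi - 1) * pitch[3] - centre_um[3]) / radii_um[3])^2
  q <- outer(outer(qz, qy, `+`), qx, `+`)
  list(zi = zi, yi = yi, xi = xi, q = q)
}

#' Simulate a confluent cell field
#'
#' Places `n_cells` deformed ellipsoidal cell bodies on a jittered grid in
#' the lower half of the imaging volume (a monolayer resting on the glass),
#' with one nucleus strictly inside each cell. Overlaps are resolved by
#' assigning each voxel to the cell whose normalized ellipsoid coordinate
#' is smallest, so labels never overlap and adjacent cells form confluent
#' interfaces.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A `cell_field` list: `labels` (`(Z,Y,X)` integer array, 0 =
#'   background), `nucleus_mask` (logical array), `cell_volumes_um3`
#'   (named by label), `centres_um` and `radii_um` (per-cell, `(z,y,x)`
#'   rows), and the `geometry`.
#' @export
simulate_cell_field <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  n <- as.integer(config$n_cells)
  if (is.na(n) || n < 1L) stop("simulate_cell_field: n_cells must be >= 1")
  g <- config$geometry
  dims <- c(g$n_z, as.integer(config$field_px[["y"]]),
            as.integer(config$field_px[["x"]]))
  pitch <- geom_pitch_zyx(g)
  size_um <- dims * pitch
  # feasibility: mean cell footprint must fit the field area
  if (n * pi * config$cell_radius_um^2 > 1.6 * size_um[2] * size_um[3])
    stop("simulate_cell_field: field too small for ", n,
         " cells of radius ", config$cell_radius_um, " um (simulation error)")
  set.seed(seed)
  for (attempt in 1:5) {
    ncol_ <- ceiling(sqrt(n))
    nrow_ <- ceiling(n / ncol_)
    sy <- size_um[2] / nrow_; sx <- size_um[3] / ncol_
    idx <- seq_len(n) - 1L
    cy <- (idx %/% ncol_ + 0.5) * sy + stats::runif(n, -0.4, 0.4)
    cx <- (idx %% ncol_ + 0.5) * sx + stats::runif(n, -0.4, 0.4)
    r <- pmax(0.2 * config$cell_radius_um,
              stats::rnorm(n, config$cell_radius_um, config$cell_radius_sd_um))
    ry <- r * (1 + stats::runif(n, -config$deform, config$deform))
    rx <- r * (1 + stats::runif(n, -config$deform, config$deform))
    rz <- r * config$cell_aspect_z
    cz <- rz  # bottom of the cell touches z = 0
    bestq <- array(Inf, dims)
    labels <- array(0L, dims)
    for (i in seq_len(n)) {
      e <- .ellipsoid_q(c(cz[i], cy[i], cx[i]), c(rz[i], ry[i], rx[i]),
                        pitch, dims)
      if (is.null(e)) next
      sub <- bestq[e$zi, e$yi, e$xi, drop = FALSE]
      take <- e$q <= 1 & e$q < sub
      sub[take] <- e$q[take]
      bestq[e$zi, e$yi, e$xi] <- sub
      lsub <- labels[e$zi, e$yi, e$xi, drop = FALSE]
      lsub[take] <- i
      labels[e$zi, e$yi, e$xi] <- lsub
    }
    counts <- tabulate(labels, nbins = n)
    if (all(counts > 0L)) {
      nucleus <- array(FALSE, dims)
      f <- config$nucleus_radius_fraction
      for (i in seq_len(n)) {
        e <- .ellipsoid_q(c(cz[i], cy[i], cx[i]),
                          f * c(rz[i], ry[i], rx[i]), pitch, dims)
        if (is.null(e)) next
        sub <- nucleus[e$zi, e$yi, e$xi, drop = FALSE]
        lsub <- labels[e$zi, e$yi, e$xi, drop = FALSE]
        sub[e$q <= 1 & lsub == i] <- TRUE
        nucleus[e$zi, e$yi, e$xi] <- sub
      }
      vols <- counts * g$voxel_volume
      names(vols) <- seq_len(n)
      return(structure(
        list(labels = labels, nucleus_mask = nucleus,
             cell_volumes_um3 = vols,
             centres_um = cbind(z = cz, y = cy, x = cx),
             radii_um = cbind(z = rz, y = ry, x = rx),
             geometry = g, dims = dims),
        class = "cell_field"))
    }
  }
  stop("simulate_cell_field: could not place all cells after 5 attempts",
       " (simulation error: infeasible packing)")
}

# apical-surface voxels of one cell: its voxels with background directly
# above (EVs settle onto the monolayer from the medium, so binding is
# apical; lateral cell-cell interfaces are not exposed)
.exposed_surface_idx <- function(cell_field, cell_id) {
  lab <- cell_field$labels
  dims <- dim(lab)
  above <- array(0L, dims)
  above[seq_len(dims[1] - 1L), , ] <- lab[2:dims[1], , ]
  which(lab == cell_id & above == 0L)
}

#' Simulate the per-EV event schedule
#'
#' Each of `round(ev_dose * n_cells)` EVs independently draws a binding
#' time (exponential with rate `bind_rate`), attaches at a random exposed
#' surface voxel of its (uniformly assigned) cell, internalizes after an
#' exponential delay (mean `internalize_delay_min`) to a depth of
#' `internalization_depth_um` below the surface along the inward direction,
#' then drifts slowly inward with a small random walk. In fusogenic
#' conditions a Bernoulli(`fuse_fraction`) subset fuses at
#' `max(t_bind + gamma(fuse_time_dist), t_internalize)`, so the event order
#' bind <= internalize <= fuse always holds. Events after the last frame
#' are recorded but not rendered.
#'
#' @param config a [simulation_config()].
#' @param cell_field output of [simulate_cell_field()].
#' @param seed RNG seed.
#' @return A `ground_truth` list: `ev` (per-EV data.frame with `id`,
#'   `cell_id`, `t_bind_min`, `t_internalize_min`, `t_fuse_min`),
#'   `traj_um` (`n_ev x n_frames x 3` array of `(z,y,x)` positions, `NA`
#'   before binding), `per_frame` tallies, and `cell_volumes_um3`.
#' @export
simulate_event_schedule <- function(config, cell_field, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(cell_field, "cell_field"))
  set.seed(seed + 1L)
  n_cells <- length(cell_field$cell_volumes_um3)
  n_ev <- round(config$ev_dose * n_cells)
  times <- config$frame_times_min
  nf <- length(times)
  ev <- data.frame(id = integer(0), cell_id = integer(0),
                   t_bind_min = numeric(0), t_internalize_min = numeric(0),
                   t_fuse_min = numeric(0))
  traj <- array(NA_real_, c(max(n_ev, 1L), nf, 3L),
                dimnames = list(NULL, NULL, c("z", "y", "x")))
  if (n_ev > 0) {
    cell_id <- sample.int(n_cells, n_ev, replace = TRUE)
    t_bind <- if (config$bind_rate > 0)
      stats::rexp(n_ev, rate = config$bind_rate) else rep(Inf, n_ev)
    t_int <- t_bind + stats::rexp(n_ev, rate = 1 / config$internalize_delay_min)
    fuses <- config$fuse_fraction > 0 &
      stats::runif(n_ev) < config$fuse_fraction
    t_fuse <- rep(Inf, n_ev)
    if (any(fuses))
      t_fuse[fuses] <- pmax(
        t_bind[fuses] + stats::rgamma(sum(fuses),
                                      shape = config$fuse_time_dist[[1]],
                                      scale = config$fuse_time_dist[[2]]),
        t_int[fuses])
    ev <- data.frame(id = seq_len(n_ev), cell_id = cell_id,
                     t_bind_min = t_bind, t_internalize_min = t_int,
                     t_fuse_min = t_fuse)
    pitch <- geom_pitch_zyx(cell_field$geometry)
    surf_cache <- lapply(seq_len(n_cells), function(i)
      .exposed_surface_idx(cell_field, i))
    dims <- cell_field$dims
    # per-EV endosome depth (jittered so internalized EVs fill a 3D band
    # below the surface rather than a single thin shell)
    depth0 <- stats::runif(n_ev, 0.8, 1.5) * config$internalization_depth_um
    for (i in seq_len(n_ev)) {
      if (!is.finite(t_bind[i])) next
      surf <- surf_cache[[cell_id[i]]]
      if (length(surf) == 0L) next
      vox <- arrayInd(sample(surf, 1L), dims)
      # the physical surface lies half a Z-step above the apical voxel
      attach_um <- (as.numeric(vox) - 1) * pitch + c(pitch[1] / 2, 0, 0)
      centre <- cell_field$centres_um[cell_id[i], ]
      radii <- cell_field$radii_um[cell_id[i], ]
      # local cell thickness below the attachment column; endosomes sink
      # straight down (preserving the lateral Poisson spread of the EVs)
      # to a depth capped by the material available in that column
      rho2 <- ((attach_um[2] - centre[2]) / radii[2])^2 +
        ((attach_um[3] - centre[3]) / radii[3])^2
      half_th <- radii[1] * sqrt(max(1 - rho2, 0.01))
      for (fr in seq_len(nf)) {
        t <- times[fr]
        if (t < t_bind[i]) next
        if (t < t_int[i]) {
          traj[i, fr, ] <- attach_um
        } else {
          depth <- min(depth0[i] +
                         config$inward_speed_um_min * (t - t_int[i]),
                       1.4 * half_th)
          pos <- attach_um + c(-depth, 0, 0) +
            stats::rnorm(3, 0, config$walk_sd_um)
          pos[1] <- max(pos[1], 0)
          traj[i, fr, ] <- pos
        }
      }
    }
  }
  per_frame <- data.frame(
    frame = seq_len(nf), time_min = times,
    n_bound = vapply(times, function(t)
      sum(ev$t_bind_min <= t & ev$t_internalize_min > t), integer(1)),
    n_internalized = vapply(times, function(t)
      sum(ev$t_internalize_min <= t), integer(1)),
    n_fused_cumulative = vapply(times, function(t)
      sum(ev$t_fuse_min <= t), integer(1)),
    n_fusion_spots_visible = vapply(times, function(t)
      sum(ev$t_fuse_min <= t &
            ev$t_fuse_min + config$fusion_lifetime_min > t), integer(1)))
  structure(list(ev = ev, traj_um = traj, per_frame = per_frame,
                 cell_volumes_um3 = cell_field$cell_volumes_um3),
            class = "ground_truth")
}

# add an anisotropic Gaussian blob (peak amplitude amp) at a um position
.add_blob <- function(vol, pos_um, amp, sigma_um, pitch) {
  dims <- dim(vol)
  svox <- sigma_um / pitch
  ctr <- pos_um / pitch + 1  # 1-based fractional voxel position
  lo <- pmax(1L, floor(ctr - 3 * svox))
  hi <- pmin(dims, ceiling(ctr + 3 * svox))
  if (any(lo > hi)) return(vol)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- exp(-0.5 * ((zi - ctr[1]) * pitch[1] / sigma_um[1])^2)
  gy <- exp(-0.5 * ((yi - ctr[2]) * pitch[2] / sigma_um[2])^2)
  gx <- exp(-0.5 * ((xi - ctr[3]) * pitch[3] / sigma_um[3])^2)
  vol[zi, yi, xi] <- vol[zi, yi, xi] + amp * outer(outer(gz, gy), gx)
  vol
}

.apply_noise <- function(vol, noise) {
  n <- length(vol)
  s <- max(noise[["poisson_scale"]], 1e-9)
  out <- noise[["offset"]] + stats::rnorm(n, 0, noise[["gaussian_sd"]]) +
    stats::rpois(n, pmax(vol, 0) / s) * s
  out <- round(out)
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  array(out, dim(vol))
}

#' Render a far-red dye channel plus its true binary mask
#'
#' `membrane_mask`: a bright shell at each cell boundary plus a decaying
#' fraction of internalized-EV positions (the dye travels inward with
#' endosomes and is depleted from them over time). `acidic_puncta`:
#' perinuclear-biased puncta per cell. `nucleus_nls`: the nuclear fill.
#' The returned intensity volume is pre-PSF and pre-noise; the returned
#' mask is the generating ground truth for overlap scoring.
#'
#' @param kind `membrane_mask`, `acidic_puncta` or `nucleus_nls`.
#' @param cell_field a [simulate_cell_field()] result.
#' @param ground_truth a [simulate_event_schedule()] result.
#' @param config a [simulation_config()].
#' @param frame frame index at which to evaluate dye-carrying endosomes.
#' @param seed RNG seed.
#' @return `list(volume, mask)`, both `(Z, Y, X)`.
#' @export
render_dye_channel <- function(kind, cell_field, ground_truth, config,
                               frame = 1L, seed = config$seed) {
  kind <- match.arg(kind, c("membrane_mask", "acidic_puncta", "nucleus_nls"))
  set.seed(seed + 97L + frame)
  dims <- cell_field$dims
  pitch <- geom_pitch_zyx(cell_field$geometry)
  mask <- array(FALSE, dims)
  if (kind == "nucleus_nls") {
    mask <- cell_field$nucleus_mask
  } else if (kind == "membrane_mask") {
    fg <- cell_field$labels > 0L
    # a membrane is thin in physical units: foreground within 0.35 um of
    # the background under the anisotropic metric (at most ~2 voxels in
    # XY, sub-slice in Z)
    dsq <- cpp_edt3d_sq(!fg, dims, pitch)
    mask <- fg & dsq <= 0.35^2 + 1e-9
    # dye-positive endosomes: internalized EVs, decaying with dwell time
    t <- config$frame_times_min[frame]
    evd <- ground_truth$ev
    for (i in seq_len(nrow(evd))) {
      if (!is.finite(evd$t_internalize_min[i]) ||
          evd$t_internalize_min[i] > t) next
      if (stats::runif(1) > exp(-(t - evd$t_internalize_min[i]) / 30)) next
      pos <- ground_truth$traj_um[i, frame, ]
      if (anyNA(pos)) next
      e <- .ellipsoid_q(pos, c(0.4, 0.3, 0.3), pitch, dims)
      if (!is.null(e)) {
        sub <- mask[e$zi, e$yi, e$xi, drop = FALSE]
        sub[e$q <= 1] <- TRUE
        mask[e$zi, e$yi, e$xi] <- sub
      }
    }
  } else {  # acidic_puncta
    n_p <- as.integer(config$acidic_puncta_per_cell)
    for (ci in seq_along(cell_field$cell_volumes_um3)) {
      if (n_p < 1L) next
      ctr <- cell_field$centres_um[ci, ]
      rad <- cell_field$radii_um[ci, ]
      nr <- config$nucleus_radius_fraction
      for (p in seq_len(n_p)) {
        # perinuclear bias: just outside the nuclear surface
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        rr <- stats::runif(1, nr, min(1, nr + 0.35))
        pos <- ctr + d * rad * rr
        e <- .ellipsoid_q(pos, c(0.5, 0.35, 0.35), pitch, dims)
        if (!is.null(e)) {
          sub <- mask[e$zi, e$yi, e$xi, drop = FALSE]
          lsub <- cell_field$labels[e$zi, e$yi, e$xi, drop = FALSE]
          sub[e$q <= 1 & lsub == ci] <- TRUE
          mask[e$zi, e$yi, e$xi] <- sub
        }
      }
    }
  }
  list(volume = ifelse(mask, config$dye_level, 0), mask = mask)
}

#' Render the full multi-channel time-lapse
#'
#' Channel 1 is the diffuse green cytosolic reporter (depleted slightly as
#' fusions accumulate) plus a bright punctum at every visible fusion site;
#' expired fusion puncta redistribute intensity to a faint cell-boundary
#' shell. Channel 2 is a red punctum per bound or internalized EV.
#' Channel 3 is the diffuse nuclear label. An optional channel 4 renders
#' `config$dye_kind` via [render_dye_channel()]. All channels are blurred
#' with the anisotropic Gaussian PSF, then offset, Gaussian read noise and
#' Poisson-scaled shot noise are applied and the result is clipped to the
#' 16-bit range.
#'
#' @param cell_field a [simulate_cell_field()] result.
#' @param ground_truth a matching [simulate_event_schedule()] result.
#' @param config a [simulation_config()].
#' @param seed RNG seed.
#' @param fov_id identifier stamped on the stack.
#' @return A [timelapse_stack()] with channel roles `reporter_green = 1`,
#'   `ev_red = 2`, `nucleus_blue = 3` (+ `dye_farred = 4` if configured).
#' @export
render_timelapse <- function(cell_field, ground_truth, config,
                             seed = config$seed, fov_id = "sim") {
  set.seed(seed + 2L)
  g <- cell_field$geometry
  dims <- cell_field$dims
  pitch <- geom_pitch_zyx(g)
  times <- config$frame_times_min
  nf <- length(times)
  n_ch <- if (is.null(config$dye_kind)) 3L else 4L
  data <- array(0, c(nf, n_ch, dims))
  inside <- cell_field$labels > 0L
  cyto <- inside & !cell_field$nucleus_mask
  fgsq <- cpp_edt3d_sq(!inside, dims, c(1, 1, 1))
  shell <- inside & fgsq <= 1.0001
  sig_xy <- config$spot_fwhm_um / (2 * sqrt(2 * log(2)))
  blob_sigma <- c(config$spot_sigma_z_um, sig_xy, sig_xy)
  psf_vox <- as.numeric(config$psf_sigma_um[c("z", "y", "x")]) / pitch
  evd <- ground_truth$ev
  for (fr in seq_len(nf)) {
    t <- times[fr]
    n_fused <- ground_truth$per_frame$n_fused_cumulative[fr]
    n_expired <- n_fused - ground_truth$per_frame$n_fusion_spots_visible[fr]
    depl <- max(0.7, 1 - config$cytosol_depletion_per_fusion * n_fused)
    green <- array(0, dims)
    green[cyto] <- config$cytosol_level * depl
    green[cell_field$nucleus_mask] <- config$nucleus_green_level * depl
    green[shell] <- green[shell] +
      min(400, config$shell_level_per_expired * n_expired)
    red <- array(0, dims)
    blue <- array(0, dims)
    blue[cell_field$nucleus_mask] <- config$nucleus_blue_level
    for (i in seq_len(nrow(evd))) {
      pos <- ground_truth$traj_um[i, fr, ]
      if (anyNA(pos)) next
      red <- .add_blob(red, pos, config$ev_amp, blob_sigma, pitch)
      if (is.finite(evd$t_fuse_min[i]) && evd$t_fuse_min[i] <= t &&
          evd$t_fuse_min[i] + config$fusion_lifetime_min > t)
        green <- .add_blob(green, pos, config$fusion_amp, blob_sigma, pitch)
    }
    chans <- list(green, red, blue)
    if (n_ch == 4L) {
      dye <- render_dye_channel(config$dye_kind, cell_field, ground_truth,
                                config, frame = fr, seed = seed)
      chans[[4L]] <- dye$volume
    }
    for (ch in seq_len(n_ch)) {
      v <- cpp_gauss_blur3d(chans[[ch]], dims, psf_vox)
      data[fr, ch, , , ] <- .apply_noise(v, config$noise)
    }
  }
  roles <- c(reporter_green = 1L, ev_red = 2L, nucleus_blue = 3L)
  if (n_ch == 4L) roles <- c(roles, dye_farred = 4L)
  timelapse_stack(data, roles, g, fov_id = fov_id,
                  frame_times_min = times)
}

#' One-call simulation of a ground-truthed field of view
#'
#' Runs [simulate_cell_field()], [simulate_event_schedule()] and
#' [render_timelapse()] with per-stage seeds derived from one root seed.
#'
#' @param config a [simulation_config()].
#' @param seed root seed.
#' @param fov_id stack identifier.
#' @return `list(stack, truth, cell_field)`.
#' @export
simulate_fov <- function(config, seed = config$seed, fov_id = "sim") {
  cf <- simulate_cell_field(config, seed = seed)
  gt <- simulate_event_schedule(config, cf, seed = seed)
  st <- render_timelapse(cf, gt, config, seed = seed, fov_id = fov_id)
  list(stack = st, truth = gt, cell_field = cf)
}
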