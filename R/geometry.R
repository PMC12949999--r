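#' Physical voxel calibration
#'
#' Binds voxel indices of a Z-stack to physical micrometre coordinates and
#' frame indices to minutes. All downstream distances, volumes and kinetic
#' summaries are expressed through this object.
#'
#' @param dx,dy micrometres per pixel in X and Y (default 0.065 um, the
#'   effective pixel size of a 100x objective on an sCMOS camera).
#' @param dz micrometres per Z-slice (0.5 um for localization-grade stacks,
#'   1 um for kinetic stacks).
#' @param dt minutes per frame.
#' @param n_z number of Z-slices acquired per stack.
#' @return An object of class `voxel_geometry` with fields `dx`, `dy`, `dz`,
#'   `dt`, `n_z` and precomputed `voxel_volume` (um^3).
#' @examples
#' g <- voxel_geometry()
#' g$voxel_volume  # 0.065 * 0.065 * 0.5
#' @export
voxel_geometry <- function(dx = 0.065, dy = 0.065, dz = 0.5, dt = 1,
                           n_z = 21L) {
  for (nm in c("dx", "dy", "dz", "dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("voxel_geometry: '", nm, "' must be a single positive number")
  }
  n_z <- as.integer(n_z)
  if (is.na(n_z) || n_z < 1L) stop("voxel_geometry: n_z must be >= 1")
  structure(
    list(dx = dx, dy = dy, dz = dz, dt = dt, n_z = n_z,
         voxel_volume = dx * dy * dz),
    class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "voxel_geometry: %g x %g x %g um (x,y,z), %g min/frame, %d slices, voxel %g um^3\n",
    x$dx, x$dy, x$dz, x$dt, x$n_z, x$voxel_volume))
  invisible(x)
}

# voxel pitch in (z, y, x) order -- the package's canonical axis order
geom_pitch_zyx <- function(geometry) c(geometry$dz, geometry$dy, geometry$dx)

#' Convert 1-based voxel indices to physical coordinates
#'
#' Positions are voxel-centre coordinates in micrometres, `(z, y, x)` order,
#' with the centre of voxel `(1, 1, 1)` at the origin.
#'
#' @param idx_zyx numeric vector of length 3 or an n-by-3 matrix of 1-based
#'   voxel indices in `(z, y, x)` order.
#' @param geometry a [voxel_geometry()].
#' @return Coordinates in um, same shape as the input.
#' @export
voxel_to_um <- function(idx_zyx, geometry) {
  p <- geom_pitch_zyx(geometry)
  if (is.matrix(idx_zyx)) sweep(idx_zyx - 1, 2, p, `*`) else (idx_zyx - 1) * p
}

#' @rdname voxel_to_um
#' @param pos_um physical coordinates in um, `(z, y, x)` order.
#' @export
um_to_voxel <- function(pos_um, geometry) {
  p <- geom_pitch_zyx(geometry)
  if (is.matrix(pos_um)) sweep(pos_um, 2, p, `/`) + 1 else pos_um / p + 1
}

.channel_role_names <- c("reporter_green", "ev_red", "nucleus_blue",
                         "dye_farred")

#' Multi-channel 3D time-lapse container
#'
#' Wraps a 5-axis intensity array in the fixed internal order
#' `(time, channel, z, y, x)` together with named channel roles and voxel
#' geometry. Readers reorder on ingest so the rest of the package never has
#' to reason about axis conventions.
#'
#' @param data numeric array with `dim = c(T, C, Z, Y, X)`, non-negative.
#' @param channel_roles named integer vector mapping role names (subset of
#'   `reporter_green`, `ev_red`, `nucleus_blue`, `dye_farred`) to channel
#'   indices. `reporter_green` is required by the quantification pipeline
#'   but not by the container itself.
#' @param geometry a [voxel_geometry()].
#' @param fov_id identifier of the field of view.
#' @param frame_times_min acquisition times in minutes from EV addition;
#'   defaults to `(0:(T-1)) * geometry$dt`.
#' @return A `timelapse_stack` object.
#' @export
timelapse_stack <- function(data, channel_roles, geometry,
                            fov_id = "fov1", frame_times_min = NULL) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop("timelapse_stack: data must be a 5-axis (T,C,Z,Y,X) array")
  if (any(data < 0, na.rm = TRUE))
    stop("timelapse_stack: intensities must be non-negative")
  d <- dim(data)
  if (any(d == 0L)) stop("timelapse_stack: empty axis in data")
  roles <- validate_roles(channel_roles, n_channels = d[2])
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (is.null(frame_times_min))
    frame_times_min <- (seq_len(d[1]) - 1) * geometry$dt
  if (length(frame_times_min) != d[1] || is.unsorted(frame_times_min, strictly = TRUE))
    stop("timelapse_stack: frame_times_min must be strictly increasing, one per frame")
  structure(
    list(data = data, channel_roles = roles, geometry = geometry,
         fov_id = fov_id, frame_times_min = as.numeric(frame_times_min)),
    class = "timelapse_stack")
}

validate_roles <- function(channel_roles, n_channels) {
  if (is.null(channel_roles) || length(channel_roles) == 0L)
    return(integer(0))
  roles <- as.integer(channel_roles)
  names(roles) <- names(channel_roles)
  if (is.null(names(roles)) || any(names(roles) == ""))
    stop("channel_roles must be a named vector")
  bad <- setdiff(names(roles), .channel_role_names)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         " (configuration error)")
  if (anyDuplicated(names(roles)) || anyDuplicated(roles))
    stop("channel roles and their indices must be unique")
  if (any(roles < 1L | roles > n_channels))
    stop("channel role points past channel count (", n_channels,
         " channels available) -- configuration error")
  roles
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("timelapse_stack '%s': %d frames x %d channels x %d x %d x %d (Z,Y,X)\n",
              x$fov_id, d[1], d[2], d[3], d[4], d[5]))
  if (length(x$channel_roles))
    cat("  roles:", paste(names(x$channel_roles), x$channel_roles,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract one 3D frame of one channel role
#'
#' @param stack a [timelapse_stack()].
#' @param role channel role name or integer channel index.
#' @param frame 1-based frame index.
#' @return A `(Z, Y, X)` numeric array.
#' @export
get_frame <- function(stack, role, frame = 1L) {
  ch <- if (is.character(role)) {
    if (!role %in% names(stack$channel_roles))
      stop("role '", role, "' is not mapped in this stack")
    stack$channel_roles[[role]]
  } else as.integer(role)
  d <- dim(stack$data)
  if (frame < 1L || frame > d[1]) stop("frame index out of range")
  array(stack$data[frame, ch, , , ], dim = d[3:5])
}

#' Write a time-lapse stack to a multi-page TIFF
#'
#' Pages are emitted in `(t, c, z)` nesting order (z fastest). Integer data
#' in `[0, 65535]` round-trips losslessly through the 16-bit encoding.
#' Because baseline TIFF carries no calibrated axis metadata, the axis
#' shape, channel roles, geometry and frame times are stored in a JSON
#' sidecar at `<path>.json`, which [read_stack()] restores.
#'
#' @param stack a valid [timelapse_stack()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  if (d[1] == 0L) stop("write_stack: zero-frame stack")
  if (max(stack$data) > 65535)
    stop("write_stack: intensities exceed the 16-bit range")
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- matrix(stack$data[t, ch, z, , ], d[4], d[5]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    axes = "TCZYX", dim = as.integer(d),
    channel_roles = as.list(stack$channel_roles),
    geometry = stack$geometry[c("dx", "dy", "dz", "dt", "n_z")],
    fov_id = stack$fov_id,
    frame_times_min = stack$frame_times_min)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a time-lapse stack from a multi-page TIFF
#'
#' Expects the page layout written by [write_stack()]; the JSON sidecar (if
#' present) supplies the axis shape, geometry and channel roles, each of
#' which can be overridden by the corresponding argument. Without a sidecar,
#' `dim` and `geometry` are required.
#'
#' @param path TIFF file path.
#' @param channel_role_map optional named vector overriding the stored roles.
#' @param geometry optional [voxel_geometry()] overriding the stored one.
#' @param dim optional integer axis lengths `(T, C, Z, Y, X)`.
#' @return A [timelapse_stack()].
#' @export
read_stack <- function(path, channel_role_map = NULL, geometry = NULL,
                       dim = NULL) {
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  if (is.null(dim)) {
    if (is.null(meta)) stop("read_stack: no sidecar metadata; supply 'dim'",
                            " (format error: axis shape unknown)")
    dim <- as.integer(unlist(meta$dim))
  }
  if (length(dim) != 5L)
    stop("read_stack: cannot coerce axes to (T,C,Z,Y,X); got ",
         length(dim), " axis lengths (format error)")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != prod(dim[1:3]))
    stop("read_stack: page count ", length(pages),
         " does not factor as T*C*Z = ", prod(dim[1:3]),
         " (format error on axis T/C/Z)")
  data <- array(0, dim = dim)
  i <- 0L
  for (t in seq_len(dim[1])) for (ch in seq_len(dim[2])) for (z in seq_len(dim[3])) {
    i <- i + 1L
    data[t, ch, z, , ] <- round(pages[[i]] * 65535)
  }
  if (is.null(geometry)) {
    if (is.null(meta)) stop("read_stack: no sidecar metadata; supply 'geometry'")
    g <- meta$geometry
    geometry <- voxel_geometry(g$dx, g$dy, g$dz, g$dt, g$n_z)
  }
  roles <- channel_role_map
  if (is.null(roles) && !is.null(meta))
    roles <- unlist(meta$channel_roles)
  timelapse_stack(
    data, roles, geometry,
    fov_id = if (!is.null(meta)) meta$fov_id else
      tools::file_path_sans_ext(basename(path)),
    frame_times_min = if (!is.null(meta)) unlist(meta$frame_times_min))
}

.result_key_cols <- c("experiment", "condition", "fov_id", "timepoint_min")

#' Validate a per-timepoint result table
#'
#' One row per `(fov_id, timepoint_min)`; within a FOV timepoints must be
#' non-negative and strictly increasing.
#'
#' @param table a data.frame with the key columns `experiment`, `condition`,
#'   `fov_id`, `timepoint_min` plus count/volume columns.
#' @return The table, invisibly, or an error.
#' @export
validate_results <- function(table) {
  miss <- setdiff(.result_key_cols, names(table))
  if (length(miss))
    stop("result table missing column(s): ", paste(miss, collapse = ", "))
  if (any(table$timepoint_min < 0)) stop("negative timepoint in result table")
  key <- paste(table$fov_id, table$timepoint_min)
  if (anyDuplicated(key))
    stop("duplicate (fov_id, timepoint) rows in result table")
  for (f in unique(table$fov_id)) {
    tp <- table$timepoint_min[table$fov_id == f]
    if (is.unsorted(tp, strictly = TRUE))
      stop("timepoints not strictly increasing within FOV '", f, "'")
  }
  invisible(table)
}

#' Write / read the result table as CSV
#'
#' Comma-delimited UTF-8 with a header row; floats are rendered at full
#' precision so that a round trip reproduces counts exactly.
#'
#' @param table a validated result table.
#' @param path CSV path.
#' @return `path` invisibly (write); the table (read).
#' @export
write_results <- function(table, path) {
  validate_results(table)
  first <- intersect(.result_key_cols, names(table))
  table <- table[, c(first, setdiff(names(table), first)), drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_results(tab)
  tab
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML file may define `geometry` (dx/dy/dz/dt/n_z), `channel_roles`,
#' `preprocess`, `segmentation`, `detection`, `correction` and `overlap`
#' sections; anything omitted falls back to package defaults. Unknown top
#' level keys are rejected so that typos never silently disable a stage.
#'
#' @param path YAML file path.
#' @return A named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("geometry", "channel_roles", "preprocess", "segmentation",
             "detection", "correction", "overlap", "paths", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$geometry))
    cfg$geometry <- do.call(voxel_geometry, cfg$geometry)
  cfg
}
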