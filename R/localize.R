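#' Fractional-voxel-overlap classification rule
#'
#' A fusion spot is designated as localized to a compartment when at least
#' `overlap_fraction` of the dataset-mean spot footprint lies inside the
#' compartment's binary mask. With the defaults (25% of a 1.96 um^3 mean
#' spot at 0.065 x 0.065 x 0.5 um voxels) the mean footprint is 928 voxels
#' and the threshold 232 voxels. The `dataset_mean` basis applies that one
#' fixed threshold to every spot; the `per_spot` basis instead takes the
#' fraction of each spot's own voxel count.
#'
#' @param overlap_fraction minimum overlapping fraction (default 0.25).
#' @param mean_spot_volume_um3 dataset-mean spot volume (default 1.96).
#' @param basis `dataset_mean` (default) or `per_spot`.
#' @return An `overlap_rule`.
#' @export
overlap_rule <- function(overlap_fraction = 0.25, mean_spot_volume_um3 = 1.96,
                         basis = c("dataset_mean", "per_spot")) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            mean_spot_volume_um3 > 0)
  structure(list(overlap_fraction = overlap_fraction,
                 mean_spot_volume_um3 = mean_spot_volume_um3,
                 basis = match.arg(basis)),
            class = "overlap_rule")
}

#' Mean spot footprint in voxels
#'
#' `round(volume / voxel_volume)`, rounding half to even; 1.96 um^3 at
#' 0.065 x 0.065 x 0.5 um voxels gives 928.
#'
#' @param mean_spot_volume_um3 strictly positive mean spot volume.
#' @param geometry a [voxel_geometry()].
#' @return Integer voxel count.
#' @export
mean_spot_voxels <- function(mean_spot_volume_um3, geometry) {
  if (!is.numeric(mean_spot_volume_um3) || mean_spot_volume_um3 <= 0)
    stop("mean_spot_voxels: volume must be strictly positive")
  as.integer(round(mean_spot_volume_um3 / geometry$voxel_volume))
}

#' Overlap threshold in voxels
#'
#' `round(overlap_fraction * mean_spot_voxels)`; 25% of 928 gives 232.
#' A fraction of 0 classifies every spot as positive.
#'
#' @param rule an [overlap_rule()].
#' @param geometry a [voxel_geometry()].
#' @return Integer voxel threshold.
#' @export
overlap_threshold <- function(rule, geometry) {
  as.integer(round(rule$overlap_fraction *
                     mean_spot_voxels(rule$mean_spot_volume_um3, geometry)))
}

#' Classify one spot footprint against a binary mask
#'
#' `TRUE` iff at least `threshold_voxels` of the spot's voxel set are
#' mask positive -- each positive voxel contributes exactly 1, i.e. the
#' summed intensity of the binary mask within the footprint is compared
#' to the threshold.
#'
#' @param voxel_set integer matrix of 1-based `(z, y, x)` voxel indices
#'   (e.g. from [spot_footprint()]).
#' @param mask `(Z, Y, X)` logical array or an [organelle_mask()].
#' @param threshold_voxels integer threshold (e.g. from
#'   [overlap_threshold()]).
#' @return Logical scalar; an empty voxel set returns `FALSE` with a
#'   warning.
#' @export
classify_overlap <- function(voxel_set, mask, threshold_voxels) {
  if (inherits(mask, "organelle_mask")) mask <- mask$mask
  if (is.null(voxel_set) || nrow(voxel_set) == 0L) {
    warning("classify_overlap: empty voxel set")
    return(FALSE)
  }
  sum(mask[voxel_set]) >= threshold_voxels
}

#' Classify all spots of a table against a mask
#'
#' Applies [classify_overlap()] to every spot, adding a logical column
#' `overlap_<kind>`. Under the `per_spot` basis the threshold is the
#' rule's fraction of each spot's own voxel count (rounded half to even).
#'
#' @param spots a [detect_spots()] data.frame.
#' @param mask an [organelle_mask()] (its `kind` names the new column) or
#'   a logical array plus `kind`.
#' @param rule an [overlap_rule()].
#' @param geometry a [voxel_geometry()].
#' @param kind column suffix when `mask` is a bare array.
#' @return The data.frame with the added overlap column.
#' @export
classify_spot_overlaps <- function(spots, mask, rule, geometry,
                                   kind = NULL) {
  if (inherits(mask, "organelle_mask")) {
    if (is.null(kind)) kind <- mask$kind
    mask <- mask$mask
  }
  stopifnot(!is.null(kind))
  dims <- dim(mask)
  thr_fixed <- overlap_threshold(rule, geometry)
  col <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    fp <- spot_footprint(spots[i, ], dims, geometry,
                         footprint_volume_um3 = rule$mean_spot_volume_um3)
    thr <- if (rule$basis == "dataset_mean") thr_fixed
    else as.integer(round(rule$overlap_fraction * nrow(fp)))
    col[i] <- classify_overlap(fp, mask, thr)
  }
  spots[[paste0("overlap_", kind)]] <- col
  spots
}

#' Per-FOV fraction of mask-positive spots
#'
#' For each field of view, 100 times the cumulative mask-positive spot
#' count over the time window divided by the cumulative spot count; the
#' mean across FOVs is reported with its SEM. A FOV with zero spots in
#' the window is undefined and reported as missing, never as 0.
#'
#' @param spots a spot table carrying `fov_id`, `time_min` and an
#'   `overlap_<mask_kind>` column.
#' @param mask_kind which overlap column to summarize.
#' @param window `c(min, max)` time window in minutes (default the whole
#'   table).
#' @return `list(per_fov, mean_percent, sem_percent)`; `per_fov` has
#'   columns `fov_id`, `n_spots`, `n_positive`, `percent`.
#' @export
fraction_positive <- function(spots, mask_kind, window = NULL) {
  colname <- paste0("overlap_", mask_kind)
  if (is.null(spots[[colname]]))
    stop("fraction_positive: spots lack column ", colname)
  if (is.null(spots$fov_id)) spots$fov_id <- "fov1"
  if (is.null(spots$time_min)) spots$time_min <- 0
  if (!is.null(window))
    spots <- spots[spots$time_min >= window[1] & spots$time_min <= window[2],
                   , drop = FALSE]
  fovs <- unique(spots$fov_id)
  per_fov <- do.call(rbind, lapply(fovs, function(f) {
    s <- spots[spots$fov_id == f, , drop = FALSE]
    n <- nrow(s); np <- sum(s[[colname]])
    data.frame(fov_id = f, n_spots = n, n_positive = np,
               percent = if (n > 0) 100 * np / n else NA_real_)
  }))
  vals <- per_fov$percent[!is.na(per_fov$percent)]
  list(per_fov = per_fov,
       mean_percent = if (length(vals)) mean(vals) else NA_real_,
       sem_percent = if (length(vals) > 1)
         stats::sd(vals) / sqrt(length(vals)) else NA_real_)
}

#' Sub-classify mask-positive spots by surface proximity
#'
#' Among mask-positive spots, the percentage whose absolute signed
#' surface distance is below the cutoff (proximal) versus at or above it
#' (distal); the two percentages sum to 100 whenever any positive spot
#' exists, and are missing otherwise.
#'
#' @param spots spot table with `surface_dist_um` and the overlap column.
#' @param mask_kind overlap column suffix (e.g. `membrane`).
#' @param cutoff_um proximity cutoff (default 0.5 um).
#' @return `list(proximal_percent, distal_percent, n_positive)`.
#' @export
subclassify_positive_by_surface <- function(spots, mask_kind = "membrane",
                                            cutoff_um = 0.5) {
  colname <- paste0("overlap_", mask_kind)
  if (is.null(spots[[colname]]) || is.null(spots$surface_dist_um))
    stop("subclassify_positive_by_surface: spots need '", colname,
         "' and 'surface_dist_um' columns")
  pos <- spots[spots[[colname]], , drop = FALSE]
  n <- nrow(pos)
  if (n == 0L)
    return(list(proximal_percent = NA_real_, distal_percent = NA_real_,
                n_positive = 0L))
  p <- 100 * mean(abs(pos$surface_dist_um) < cutoff_um)
  list(proximal_percent = p, distal_percent = 100 - p, n_positive = n)
}
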