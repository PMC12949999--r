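#' Published per-dataset reference volumes (um^3 per field of view)
#'
#' Mean summed cell volumes per FOV reported for the HeLa and A549
#' cytosolic-reporter datasets, the HeLa galectin-3 rupture-reporter
#' dataset, and the localization-grade dataset; usable as named presets
#' for [correction_reference()].
#'
#' @format Named numeric vector.
#' @export
reference_volume_presets <- c(
  hela_stab = 131970.7,
  a549_stab = 127732.8,
  hela_gal3 = 111537.98,
  stab_localization = 122418.73)

#' Volume-correction reference
#'
#' The dataset-mean summed cell volume per FOV against which every FOV's
#' spot counts are normalized.
#'
#' @param dataset_mean_volume_um3 strictly positive reference volume, or
#'   one of the preset names in [reference_volume_presets].
#' @param source `computed_from_dataset` or `user_supplied`.
#' @return A `correction_reference`.
#' @export
correction_reference <- function(dataset_mean_volume_um3,
                                 source = c("user_supplied",
                                            "computed_from_dataset")) {
  source <- match.arg(source)
  if (is.character(dataset_mean_volume_um3))
    dataset_mean_volume_um3 <-
      reference_volume_presets[[match.arg(dataset_mean_volume_um3,
                                          names(reference_volume_presets))]]
  stopifnot(is.numeric(dataset_mean_volume_um3),
            length(dataset_mean_volume_um3) == 1L,
            dataset_mean_volume_um3 > 0)
  structure(list(dataset_mean_volume_um3 = dataset_mean_volume_um3,
                 source = source),
            class = "correction_reference")
}

#' Compute the reference volume from a dataset's FOV volumes
#'
#' Arithmetic mean of the summed cell volumes over all fields of view (or
#' FOV-timepoints) of a dataset.
#'
#' @param fov_volumes numeric vector of summed cell volumes (um^3), length
#'   at least 1.
#' @return A [correction_reference()] with source `computed_from_dataset`.
#' @export
compute_reference_volume <- function(fov_volumes) {
  if (length(fov_volumes) == 0L)
    stop("compute_reference_volume: need at least one FOV volume")
  stopifnot(all(fov_volumes > 0))
  correction_reference(mean(fov_volumes), source = "computed_from_dataset")
}

#' Volume-corrected spot count
#'
#' Normalizes a raw per-FOV spot count for the difference between that
#' FOV's summed cell volume and the dataset mean, compensating for cell
#' coverage and occasional focus losses. The default multiplicative rule
#' `raw * reference / fov_volume` reflects counts scaling linearly with
#' imaged cell volume; an additive reading
#' `raw - k * (fov_volume - reference)` with `k = raw / reference` (the
#' FOV's count density evaluated at the reference scale) is available
#' for comparison. Both reduce to the raw count when `fov_volume` equals
#' the reference, but they extrapolate differently. Corrected counts
#' stay fractional: they feed means and SEMs, not integer tallies.
#'
#' @param raw_count raw spot count (non-negative).
#' @param fov_volume the FOV's summed cell volume (um^3), strictly
#'   positive.
#' @param reference a [correction_reference()] or a positive number.
#' @param method `multiplicative` (default) or `additive`.
#' @return Corrected count (possibly fractional).
#' @export
correct_count <- function(raw_count, fov_volume, reference,
                          method = c("multiplicative", "additive")) {
  method <- match.arg(method)
  if (any(fov_volume <= 0))
    stop("correct_count: fov_volume must be strictly positive")
  ref <- if (inherits(reference, "correction_reference"))
    reference$dataset_mean_volume_um3 else reference
  stopifnot(ref > 0)
  if (method == "multiplicative") raw_count * ref / fov_volume
  else raw_count - raw_count / ref * (fov_volume - ref)
}

#' Maximum corrected count over the time-lapse
#'
#' The per-FOV summary statistic used for bar graphs and between-condition
#' comparison: the maximum of the per-timepoint corrected counts and the
#' earliest timepoint attaining it.
#'
#' @param counts per-timepoint (corrected) counts, length >= 1.
#' @param times_min matching timepoints in minutes (default: indices).
#' @return `list(max, argmax_time)`.
#' @export
max_over_timelapse <- function(counts, times_min = seq_along(counts)) {
  if (length(counts) == 0L)
    stop("max_over_timelapse: empty series")
  stopifnot(length(times_min) == length(counts))
  i <- which.max(counts)  # earliest index attaining the maximum
  list(max = counts[i], argmax_time = times_min[i])
}

#' EVs per cell from a dose
#'
#' @param dose_total total number of EVs added.
#' @param n_cells number of recipient cells, strictly positive.
#' @return `dose_total / n_cells`.
#' @examples
#' evs_per_cell(1e8, 4e4)  # 2500 (low dose)
#' evs_per_cell(5e8, 4e4)  # 12500 (high dose)
#' @export
evs_per_cell <- function(dose_total, n_cells) {
  if (any(n_cells <= 0))
    stop("evs_per_cell: n_cells must be strictly positive")
  dose_total / n_cells
}
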