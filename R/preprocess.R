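#' Preprocessing parameters
#'
#' Mirrors the standard FIJI-style chain applied before segmentation and
#' spot detection: single-pixel outlier removal, linear intensity
#' rescaling from twice the field-of-view minimum up to a fixed ceiling,
#' and an in-plane median filter.
#'
#' @param outlier_removal apply [remove_outliers()]?
#' @param outlier_factor replace a pixel when it exceeds this multiple of
#'   its 3x3 in-plane neighbourhood median.
#' @param rescale_min_multiplier the display/processing floor is this
#'   multiple of the per-frame minimum (default 2).
#' @param rescale_max absolute intensity mapped to the top of the output
#'   range (default 5000 camera units).
#' @param rescale_out full output range after rescaling. Defaults to
#'   `rescale_max`, so processed intensities stay in camera units and a
#'   second pass through the chain leaves the rescaling an identity map.
#' @param median_radius_px radius (pixels) of the in-plane disc median
#'   filter; 0 disables it.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(outlier_removal = TRUE, outlier_factor = 3,
                              rescale_min_multiplier = 2, rescale_max = 5000,
                              rescale_out = rescale_max,
                              median_radius_px = 2L) {
  stopifnot(rescale_max > 0, median_radius_px >= 0, outlier_factor > 0,
            rescale_out > 0)
  structure(list(outlier_removal = isTRUE(outlier_removal),
                 outlier_factor = outlier_factor,
                 rescale_min_multiplier = rescale_min_multiplier,
                 rescale_max = rescale_max,
                 rescale_out = rescale_out,
                 median_radius_px = as.integer(median_radius_px)),
            class = "preprocess_params")
}

#' Remove single-pixel intensity outliers
#'
#' A voxel whose value exceeds `factor` times the median of its in-plane
#' 3x3 neighbourhood (centre included; image borders use the in-bounds
#' pixels) is replaced by that median. Never increases any voxel.
#'
#' @param volume `(Z, Y, X)` numeric array.
#' @param factor threshold multiple (default 3).
#' @return Filtered array, same shape.
#' @export
remove_outliers <- function(volume, factor = 3) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L, factor > 0)
  array(cpp_remove_outliers(as.numeric(volume), dim(volume), factor),
        dim(volume))
}

#' Linear intensity rescaling
#'
#' Maps `lo = rescale_min_multiplier * min(volume)` to 0 and
#' `hi = rescale_max` to `rescale_out`, clipping outside `[lo, hi]`. The
#' minimum is taken over the whole 3D frame of the channel (the
#' field-of-view), not per slice. A degenerate window (`hi <= lo`) yields
#' an all-zero frame with a warning.
#'
#' @param volume `(Z, Y, X)` numeric array.
#' @param params a [preprocess_params()].
#' @return Rescaled array in `[0, rescale_out]`.
#' @export
rescale_intensity <- function(volume, params = preprocess_params()) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  lo <- params$rescale_min_multiplier * min(volume)
  hi <- params$rescale_max
  if (hi <= lo) {
    warning("rescale_intensity: degenerate window (hi <= lo); returning zeros")
    return(array(0, dim(volume)))
  }
  out <- (volume - lo) / (hi - lo) * params$rescale_out
  out[out < 0] <- 0
  out[out > params$rescale_out] <- params$rescale_out
  out
}

#' In-plane disc median filter
#'
#' Median over a disc of `radius_px` pixels applied per Z-slice (the 2D
#' convention of FIJI's median filter; Z sampling is 8-15x coarser than XY
#' so a 3D median would mix planes). Radius 0 is the identity.
#'
#' @param volume `(Z, Y, X)` numeric array.
#' @param radius_px integer pixel radius.
#' @return Filtered array.
#' @export
median_filter <- function(volume, radius_px = 2L) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L, radius_px >= 0)
  array(cpp_median_disc(as.numeric(volume), dim(volume),
                        as.integer(radius_px)), dim(volume))
}

#' Preprocess one 3D frame of one channel
#'
#' Applies, in order: outlier removal, rescaling, median filtering --
#' each per channel per frame independently (the rescale minimum is the
#' per-3D-frame minimum of that channel).
#'
#' @param volume `(Z, Y, X)` numeric array.
#' @param params a [preprocess_params()].
#' @return Preprocessed array in `[0, params$rescale_out]`.
#' @export
preprocess_frame <- function(volume, params = preprocess_params()) {
  v <- volume
  if (params$outlier_removal) v <- remove_outliers(v, params$outlier_factor)
  v <- rescale_intensity(v, params)
  if (params$median_radius_px > 0L) v <- median_filter(v, params$median_radius_px)
  v
}

#' Preprocess every channel and frame of a stack
#'
#' @param stack a [timelapse_stack()].
#' @param params a [preprocess_params()].
#' @param channels channel indices to process (default: all).
#' @return A new `timelapse_stack` with preprocessed intensities.
#' @export
preprocess_stack <- function(stack, params = preprocess_params(),
                             channels = NULL) {
  d <- dim(stack$data)
  if (is.null(channels)) channels <- seq_len(d[2])
  out <- stack$data
  for (t in seq_len(d[1])) for (ch in channels) {
    out[t, ch, , , ] <- preprocess_frame(
      array(stack$data[t, ch, , , ], d[3:5]), params)
  }
  timelapse_stack(out, stack$channel_roles, stack$geometry,
                  fov_id = stack$fov_id,
                  frame_times_min = stack$frame_times_min)
}
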