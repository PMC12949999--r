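#' Segmentation parameters
#'
#' Constants of the classical threshold-morphology pipeline that replaces
#' proprietary surface-creation tools. Every constant is exposed; the
#' defaults are stand-ins calibrated on the synthetic generator, not values
#' taken from any instrument.
#'
#' @param sigma_um Gaussian smoothing sigma (um, applied isotropically in
#'   physical units, so the voxel-space kernel is anisotropy-aware).
#' @param threshold `"otsu"` or an absolute intensity value.
#' @param min_separation minimum Otsu between-class mean separation (input
#'   intensity units) below which the frame is declared empty; guards
#'   against thresholding pure noise.
#' @param closing_radius_um radius of the per-slice morphological closing
#'   disc (um).
#' @param min_volume_um3 components below this volume are discarded.
#' @return A `segment_params` list.
#' @export
segment_params <- function(sigma_um = 0.5, threshold = "otsu",
                           min_separation = 110, closing_radius_um = 0.5,
                           min_volume_um3 = 200) {
  structure(list(sigma_um = sigma_um, threshold = threshold,
                 min_separation = min_separation,
                 closing_radius_um = closing_radius_um,
                 min_volume_um3 = min_volume_um3),
            class = "segment_params")
}

# 256-bin Otsu threshold; returns list(threshold, separation of class means)
.otsu <- function(v) {
  rng <- range(v)
  if (rng[2] <= rng[1]) return(list(threshold = rng[2], separation = 0))
  h <- tabulate(pmin(256L, floor((v - rng[1]) / (rng[2] - rng[1]) * 256) + 1L),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  thr <- rng[1] + k / 256 * (rng[2] - rng[1])
  m0 <- if (any(v <= thr)) mean(v[v <= thr]) else 0
  m1 <- if (any(v > thr)) mean(v[v > thr]) else m0
  list(threshold = thr, separation = m1 - m0)
}

# union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' 3D connected components with anisotropy-free 6-connectivity
#'
#' Labels each Z-slice in 2D and merges labels of voxels that are face
#' adjacent across neighbouring slices (union-find), yielding 3D
#' components with consecutive labels.
#'
#' @param mask `(Z, Y, X)` logical array.
#' @return Integer label array of the same shape; 0 is background.
#' @export
label_components_3d <- function(mask) {
  dims <- dim(mask)
  nz <- dims[1]
  lab <- array(0L, dims)
  offset <- 0L
  for (z in seq_len(nz)) {
    sl <- EBImage::bwlabel(matrix(as.numeric(mask[z, , ]), dims[2], dims[3]))
    sl <- matrix(as.integer(sl), dims[2], dims[3])
    sl[sl > 0L] <- sl[sl > 0L] + offset
    offset <- max(offset, if (length(sl)) max(sl) else 0L)
    lab[z, , ] <- sl
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  for (z in seq_len(nz - 1L)) {
    a <- lab[z, , ]; b <- lab[z + 1L, , ]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (k in seq_len(nrow(pairs))) {
      ra <- .uf_find(parent, pairs[k, 1]); rb <- .uf_find(parent, pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(offset), function(i) .uf_find(parent, i), integer(1))
  dense <- match(root, sort(unique(root)))
  pos <- lab > 0L
  lab[pos] <- dense[lab[pos]]
  lab
}

# per-slice morphology helpers working on the (Z,Y,X) convention; EBImage
# batches 2D ops over the 3rd axis, so volumes are transposed to (Y,X,Z)
.per_slice <- function(vol, fun) {
  v <- aperm(vol, c(2, 3, 1))
  out <- fun(v)
  aperm(array(as.numeric(out), dim(v)), c(3, 1, 2))
}

.close_and_fill <- function(mask, radius_px) {
  m <- .per_slice(mask * 1, function(v) {
    img <- EBImage::Image(v)
    if (radius_px >= 1)
      img <- EBImage::closing(img, EBImage::makeBrush(2L * radius_px + 1L,
                                                      "disc"))
    EBImage::fillHull(img)
  })
  m > 0.5
}

#' Cell segmentation container
#'
#' @param labels `(Z, Y, X)` integer label volume (0 = background).
#' @param geometry a [voxel_geometry()].
#' @param excluded_labels labels removed as over-bright; excluded cells do
#'   not count towards the summed volume and spots inside them are later
#'   discarded.
#' @return A `cell_segmentation` with exact per-cell volumes (voxel count
#'   times voxel volume) and their sum over retained labels.
#' @export
cell_segmentation <- function(labels, geometry, excluded_labels = integer(0)) {
  nlab <- if (any(labels > 0L)) max(labels) else 0L
  counts <- tabulate(labels, nbins = nlab)
  vols <- counts * geometry$voxel_volume
  names(vols) <- seq_len(nlab)
  retained <- setdiff(seq_len(nlab), excluded_labels)
  structure(
    list(labels = labels,
         per_cell_volume_um3 = vols,
         fov_sum_volume_um3 = sum(vols[retained]),
         excluded_labels = as.integer(excluded_labels),
         geometry = geometry),
    class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell_segmentation: %d cells (%d excluded), sum volume %.1f um^3\n",
              length(x$per_cell_volume_um3), length(x$excluded_labels),
              x$fov_sum_volume_um3))
  invisible(x)
}

#' Segment cell bodies in 3D from the cytosolic reporter channel
#'
#' Gaussian smoothing, global threshold (Otsu by default, absolute
#' override allowed), per-slice morphological closing and hole filling,
#' 3D connected components, optional marker-based splitting seeded at
#' nuclei, and a minimum-volume filter. An all-background result returns
#' an empty segmentation with a warning, not an error.
#'
#' @param volume preprocessed `(Z, Y, X)` green-channel frame.
#' @param geometry a [voxel_geometry()].
#' @param params a [segment_params()].
#' @param nucleus_mask optional logical array of nuclei; components
#'   containing two or more nuclei are split by nearest-nucleus
#'   assignment (anisotropic Euclidean distance).
#' @return A [cell_segmentation()].
#' @export
segment_cells <- function(volume, geometry, params = segment_params(),
                          nucleus_mask = NULL) {
  dims <- dim(volume)
  pitch <- geom_pitch_zyx(geometry)
  sm <- cpp_gauss_blur3d(volume, dims, params$sigma_um / pitch)
  if (identical(params$threshold, "otsu")) {
    ot <- .otsu(as.numeric(sm))
    if (ot$separation < params$min_separation) {
      warning("segment_cells: no foreground found (class separation ",
              round(ot$separation), " < ", params$min_separation, ")")
      return(cell_segmentation(array(0L, dims), geometry))
    }
    thr <- ot$threshold
  } else thr <- params$threshold
  mask <- sm > thr
  if (!any(mask)) {
    warning("segment_cells: all-background result")
    return(cell_segmentation(array(0L, dims), geometry))
  }
  mask <- .close_and_fill(mask, round(params$closing_radius_um / geometry$dx))
  lab <- label_components_3d(mask)
  if (!is.null(nucleus_mask) && any(nucleus_mask))
    lab <- .split_by_nuclei(lab, nucleus_mask, pitch)
  # minimum-volume filter with consecutive relabelling
  counts <- tabulate(lab, nbins = max(lab, 0L))
  keep <- which(counts * geometry$voxel_volume >= params$min_volume_um3)
  newid <- integer(length(counts))
  newid[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- newid[lab[pos]]
  cell_segmentation(lab, geometry)
}

.split_by_nuclei <- function(lab, nucleus_mask, pitch) {
  nuc_lab <- label_components_3d(nucleus_mask)
  n_nuc <- max(nuc_lab, 0L)
  if (n_nuc < 2L) return(lab)
  out <- lab
  next_label <- max(lab)
  for (comp in seq_len(max(lab, 0L))) {
    inside <- lab == comp
    nucs <- setdiff(unique(nuc_lab[inside]), 0L)
    if (length(nucs) < 2L) next
    # nearest-nucleus assignment under the anisotropic metric
    dmin <- array(Inf, dim(lab))
    assign <- array(0L, dim(lab))
    for (nu in nucs) {
      dsq <- cpp_edt3d_sq(nuc_lab == nu, dim(lab), pitch)
      closer <- inside & dsq < dmin
      dmin[closer] <- dsq[closer]
      assign[closer] <- nu
    }
    ids <- stats::setNames(c(comp, next_label + seq_len(length(nucs) - 1L)),
                           nucs)
    next_label <- next_label + length(nucs) - 1L
    out[inside] <- ids[as.character(assign[inside])]
  }
  out
}

#' Exclude over-bright cells
#'
#' Cells whose mean intensity in the reporter channel strictly exceeds
#' both the given percentile of per-cell means and `min_fold` times their
#' median are moved to `excluded_labels`; the summed FOV volume is
#' recomputed over the retained cells. The fold-change requirement keeps
#' the percentile rule from always sacrificing the brightest cell when a
#' field holds only a handful of cells with ordinary variation: only
#' genuinely over-bright outliers are removed. With equal intensities
#' (or `percentile = 100`) nothing is excluded.
#'
#' @param seg a [cell_segmentation()].
#' @param volume the (preprocessed) reporter-channel frame.
#' @param percentile exclusion percentile of per-cell mean intensity
#'   (default 98).
#' @param min_fold minimum fold-change over the median per-cell mean for
#'   a cell to count as strongly bright (default 2).
#' @return A new [cell_segmentation()] with the bright cells excluded.
#' @export
exclude_bright_cells <- function(seg, volume, percentile = 98,
                                 min_fold = 2) {
  nlab <- length(seg$per_cell_volume_um3)
  if (nlab == 0L) return(seg)
  means <- vapply(seq_len(nlab), function(i)
    mean(volume[seg$labels == i]), numeric(1))
  cut <- max(stats::quantile(means, percentile / 100, names = FALSE),
             min_fold * stats::median(means))
  excluded <- which(means > cut)
  cell_segmentation(seg$labels, seg$geometry,
                    excluded_labels = union(seg$excluded_labels, excluded))
}

#' Organelle mask container
#'
#' @param mask `(Z, Y, X)` logical volume.
#' @param kind one of `membrane`, `acidic`, `nucleus`.
#' @param source_params record of the parameters that produced the mask.
#' @return An `organelle_mask`.
#' @export
organelle_mask <- function(mask, kind = c("membrane", "acidic", "nucleus"),
                           source_params = list()) {
  kind <- match.arg(kind)
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  structure(list(mask = mask, kind = kind, source_params = source_params),
            class = "organelle_mask")
}

#' Segment nuclei from the blue channel
#'
#' Smoothing, Otsu threshold (with the same noise guard as cell
#' segmentation), per-slice closing and hole filling.
#'
#' @param volume `(Z, Y, X)` blue-channel frame.
#' @param geometry a [voxel_geometry()].
#' @param params a [segment_params()]; the minimum-volume filter is not
#'   applied to nuclei.
#' @return An [organelle_mask()] of kind `nucleus`.
#' @export
segment_nuclei <- function(volume, geometry,
                           params = segment_params(sigma_um = 0.3,
                                                   closing_radius_um = 0.3)) {
  dims <- dim(volume)
  pitch <- geom_pitch_zyx(geometry)
  sm <- cpp_gauss_blur3d(volume, dims, params$sigma_um / pitch)
  if (identical(params$threshold, "otsu")) {
    ot <- .otsu(as.numeric(sm))
    if (ot$separation < params$min_separation)
      return(organelle_mask(array(FALSE, dims), "nucleus",
                            list(threshold = NA_real_)))
    thr <- ot$threshold
  } else thr <- params$threshold
  mask <- sm > thr
  if (any(mask))
    mask <- .close_and_fill(mask, round(params$closing_radius_um / geometry$dx))
  organelle_mask(mask, "nucleus", list(threshold = thr,
                                       sigma_um = params$sigma_um))
}

#' Dye-channel mask by tophat background subtraction and absolute threshold
#'
#' Morphological white tophat (the rolling-ball style background
#' subtraction) with an in-plane structuring disc of the given physical
#' radius, followed by an absolute intensity threshold. A flat background
#' maps to zero under the tophat, so uniform frames yield empty masks.
#'
#' @param volume `(Z, Y, X)` far-red dye frame.
#' @param geometry a [voxel_geometry()].
#' @param background_radius_um structuring-element radius (default 0.3 um).
#' @param threshold absolute intensity threshold on the background-
#'   subtracted image.
#' @param kind mask kind recorded on the result (`membrane` or `acidic`).
#' @return An [organelle_mask()].
#' @export
make_dye_mask <- function(volume, geometry, background_radius_um = 0.3,
                          threshold = 45, kind = "membrane") {
  r <- max(1L, round(background_radius_um / geometry$dx))
  th <- .per_slice(volume / 65535, function(v)
    EBImage::whiteTopHat(EBImage::Image(v),
                         EBImage::makeBrush(2L * r + 1L, "disc"))) * 65535
  organelle_mask(th >= threshold, kind,
                 list(background_radius_um = background_radius_um,
                      threshold = threshold))
}

#' Signed anisotropic distance to the cell surface
#'
#' Euclidean distance (um) of every voxel to the boundary of the retained
#' cell foreground, computed with the true voxel pitch per axis (no Z
#' resampling): negative inside cells, positive outside. The zero level
#' lies between the outermost foreground voxel and its nearest background
#' voxel, so boundary-shell voxels satisfy `|d| <=` one voxel pitch.
#' An empty segmentation yields `+Inf` everywhere, which downstream
#' classifiers read as "no spot is cell associated".
#'
#' @param seg a [cell_segmentation()]; excluded (bright) cells count as
#'   background.
#' @param geometry a [voxel_geometry()] (defaults to the one in `seg`).
#' @return `(Z, Y, X)` numeric array of signed distances in um.
#' @export
distance_to_surface <- function(seg, geometry = seg$geometry) {
  lab <- seg$labels
  fg <- lab > 0L
  if (length(seg$excluded_labels))
    fg <- fg & !(lab %in% seg$excluded_labels)
  dims <- dim(lab)
  if (!any(fg)) return(array(Inf, dims))
  pitch <- geom_pitch_zyx(geometry)
  d_out <- sqrt(cpp_edt3d_sq(fg, dims, pitch))
  d_in <- sqrt(cpp_edt3d_sq(!fg, dims, pitch))
  out <- d_out
  out[fg] <- -d_in[fg]
  out
}

#' Trilinear interpolation of a volume at physical positions
#'
#' Used to evaluate the signed distance field at sub-voxel spot centroids.
#' Positions outside the volume are clamped to the border.
#'
#' @param vol `(Z, Y, X)` numeric array.
#' @param pos_um n-by-3 matrix of `(z, y, x)` positions in um.
#' @param geometry a [voxel_geometry()].
#' @return Numeric vector of interpolated values.
#' @export
interp_volume <- function(vol, pos_um, geometry) {
  dims <- dim(vol)
  pitch <- geom_pitch_zyx(geometry)
  if (!is.matrix(pos_um)) pos_um <- matrix(pos_um, ncol = 3)
  p <- sweep(pos_um, 2, pitch, `/`) + 1  # fractional 1-based indices
  p <- pmax(p, 1)
  p <- sweep(p, 2, dims, pmin)
  f <- floor(p)
  w <- p - f
  out <- numeric(nrow(p))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    zi <- pmin(f[, 1] + dz, dims[1]); yi <- pmin(f[, 2] + dy, dims[2])
    xi <- pmin(f[, 3] + dx, dims[3])
    wt <- (if (dz) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dx) w[, 3] else 1 - w[, 3])
    idx <- cbind(zi, yi, xi)
    out <- out + wt * vol[idx]
  }
  out
}
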