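#' Denoise a FISH-signal channel
#'
#' Gaussian smoothing followed by a white tophat (image minus its
#' opening): a high-pass stage that suppresses smooth background at scales
#' larger than `tophat_radius` while preserving compact bright spots.
#' Output is non-negative.
#'
#' @param img image_stack or 3D array.
#' @param sigma Gaussian sigma in micrometers.
#' @param tophat_radius structuring-element radius in micrometers.
#' @param spacing voxel spacing for bare arrays.
#' @return Denoised image (same type as input).
#' @export
denoise_spots <- function(img, sigma = 0.15, tophat_radius = 1.0,
                          spacing = NULL) {
  stopifnot(sigma > 0, tophat_radius > 0)
  sm <- gaussian_filter(img, sigma, spacing = spacing, units = "um")
  white_tophat(sm, tophat_radius, spacing = spacing)
}

#' Segment FISH spots within a nuclear mask
#'
#' Spot voxels are those of the nuclear mask whose (denoised) signal
#' reaches a fixed fraction - by default one quarter - of the maximum
#' signal within the mask. Connected components below `min_volume` um^3
#' are discarded. Centroids are intensity-weighted and reported in
#' physical coordinates.
#'
#' @param img denoised signal (image_stack or array).
#' @param nucleus nucleus mask (`label_mask` or logical array).
#' @param min_volume minimum spot volume (um^3); default 0.05.
#' @param threshold_fraction fraction of the in-mask maximum defining the
#'   cut (default 0.25, the quarter-maximum rule).
#' @param spacing voxel spacing for bare arrays.
#' @param centroid "intensity" (default: intensity-weighted center of
#'   mass) or "geometric".
#' @param nucleus_id,channel identifiers carried into the output table.
#' @return Object of class `spot_set`: `labels` (array), `table`
#'   (data.frame: spot, x, y, z um, volume um^3, intensity),
#'   `spacing`, `nucleus_id`, `channel`.
#' @export
segment_spots <- function(img, nucleus, min_volume = 0.05,
                          threshold_fraction = 0.25, spacing = NULL,
                          centroid = c("intensity", "geometric"),
                          nucleus_id = 1L, channel = NA_character_) {
  centroid <- match.arg(centroid)
  v <- as_volume(img, spacing)
  nm <- as_volume(nucleus, spacing)
  if (!all(dim(v$values) == dim(nm$values)))
    stop("image and nucleus mask must share the grid")
  fg <- nm$values != 0
  if (!any(fg)) stop("nucleus mask is empty")
  m <- max(v$values[fg])
  if (m <= 0) {
    warning("all-zero signal within the nucleus; empty spot set")
    return(empty_spot_set(dim(fg), v$spacing, nucleus_id, channel))
  }
  cut <- m * threshold_fraction
  spot_vox <- fg & (v$values >= cut)
  cc <- label_components(spot_vox, v$spacing)
  vol_vox <- voxel_volume(v$spacing)
  keep <- which(cc$counts * vol_vox >= min_volume)
  if (length(keep) == 0)
    return(empty_spot_set(dim(fg), v$spacing, nucleus_id, channel))
  lab <- array(0L, dim = dim(fg))
  rows <- vector("list", length(keep))
  dims <- dim(fg)
  for (i in seq_along(keep)) {
    idx <- which(cc$labels == keep[i])
    lab[idx] <- i
    co <- voxel_coords(idx, dims, v$spacing)
    w <- if (centroid == "intensity") v$values[idx] else rep(1, length(idx))
    wsum <- sum(w)
    rows[[i]] <- data.frame(spot = i,
                            x = sum(co[, 1] * w) / wsum,
                            y = sum(co[, 2] * w) / wsum,
                            z = sum(co[, 3] * w) / wsum,
                            volume = length(idx) * vol_vox,
                            intensity = sum(v$values[idx]))
  }
  structure(list(labels = lab, table = do.call(rbind, rows),
                 spacing = v$spacing, nucleus_id = nucleus_id,
                 channel = channel, threshold = cut),
            class = "spot_set")
}

empty_spot_set <- function(dims, spacing, nucleus_id, channel) {
  structure(list(labels = array(0L, dim = dims),
                 table = data.frame(spot = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    volume = numeric(0),
                                    intensity = numeric(0)),
                 spacing = spacing, nucleus_id = nucleus_id,
                 channel = channel, threshold = NA_real_),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spot(s), channel %s, nucleus %s\n",
              nrow(x$table), x$channel, x$nucleus_id))
  invisible(x)
}

#' Number of spots in a spot set
#' @param x a `spot_set`.
#' @export
n_spots <- function(x) nrow(x$table)

#' Per-nucleus spot summary metrics
#'
#' @param spots a `spot_set`.
#' @param nucleus nucleus mask (for the nuclear volume).
#' @param spacing voxel spacing for bare-array masks.
#' @return data.frame: `count`, `total_volume`, `mean_volume`,
#'   `volume_fraction` (total spot volume / nuclear volume); zeros for an
#'   empty spot set.
#' @export
spot_metrics <- function(spots, nucleus, spacing = NULL) {
  nm <- as_volume(nucleus, spacing)
  nuc_vol <- sum(nm$values != 0) * voxel_volume(nm$spacing)
  k <- nrow(spots$table)
  tv <- sum(spots$table$volume)
  data.frame(count = k,
             total_volume = tv,
             mean_volume = if (k > 0) tv / k else 0,
             volume_fraction = if (nuc_vol > 0) tv / nuc_vol else 0)
}
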