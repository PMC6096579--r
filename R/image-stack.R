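#' Create an image stack
#'
#' Lightweight container for one channel of a 3D confocal volume: a numeric
#' array in column-major (x, y, z) order plus the physical voxel spacing in
#' micrometers. All geometric operations in the package are anisotropy-aware
#' through the spacing.
#'
#' @param values 3D numeric array (nx, ny, nz).
#' @param spacing numeric length-3, micrometers per voxel along (x, y, z).
#' @param channel optional channel label, e.g. "dna", "a", "b".
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(values, spacing, channel = NA_character_) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("image_stack requires a 3D array")
  if (any(dim(values) < 2L))
    stop("image_stack requires at least 2 voxels per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (micrometers per voxel)")
  structure(list(values = values, spacing = spacing, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_stack> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um, channel %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$channel))
  invisible(x)
}

# Accept either an image_stack or a bare array (with spacing supplied or
# attached as attr "spacing"); returns list(values, spacing).
as_volume <- function(x, spacing = NULL) {
  if (inherits(x, "image_stack"))
    return(list(values = x$values, spacing = x$spacing))
  if (inherits(x, "label_mask"))
    return(list(values = x$labels, spacing = x$spacing))
  if (is.array(x) && length(dim(x)) == 3L) {
    sp <- if (!is.null(spacing)) spacing else attr(x, "spacing")
    if (is.null(sp))
      stop("spacing must be supplied for a bare array")
    return(list(values = x, spacing = as.numeric(sp)))
  }
  stop("expected an image_stack, label_mask, or 3D array")
}

voxel_volume <- function(spacing) prod(spacing)

# Physical coordinates (um) of voxel centers for linear indices `idx`
# within a grid of dimension `dims`: voxel (i,j,k) is centered at
# ((i - 1/2) sx, (j - 1/2) sy, (k - 1/2) sz).
voxel_coords <- function(idx, dims, spacing) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(x = (i + 0.5) * spacing[1],
        y = (j + 0.5) * spacing[2],
        z = (k + 0.5) * spacing[3])
}

# Nearest voxel linear index for physical points (n x 3 matrix, um),
# clamped to the grid.
coords_to_index <- function(pts, dims, spacing) {
  pts <- matrix(pts, ncol = 3)
  i <- pmin(pmax(ceiling(pts[, 1] / spacing[1]), 1L), dims[1])
  j <- pmin(pmax(ceiling(pts[, 2] / spacing[2]), 1L), dims[2])
  k <- pmin(pmax(ceiling(pts[, 3] / spacing[3]), 1L), dims[3])
  as.integer(i + dims[1] * (j - 1) + dims[1] * dims[2] * (k - 1))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ball structuring element offsets
#'
#' Integer voxel offsets of a ball of the given radius. With `spacing`
#' supplied the radius is in micrometers and the ball is anisotropic in
#' voxel units; otherwise the radius is in voxels and the ball is isotropic.
#'
#' @param radius ball radius (voxels, or um when `spacing` is given).
#' @param spacing optional voxel spacing (um) making the element
#'   anisotropy-aware.
#' @return Integer matrix (m x 3) of offsets, always containing (0,0,0).
#' @export
ball_offsets <- function(radius, spacing = NULL) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  r <- abs(radius)
  ext <- pmax(0L, floor(r / spacing))
  g <- expand.grid(dx = -ext[1]:ext[1], dy = -ext[2]:ext[2], dz = -ext[3]:ext[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  m <- as.matrix(g[d2 <= r^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  x <- -half:half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter; `sigma` is given in micrometers and converted
#' per axis so smoothing is isotropic in physical space despite anisotropic
#' voxels. Truncated border weights are renormalized.
#'
#' @param img image_stack or 3D array.
#' @param sigma standard deviation in micrometers (scalar) or per-axis
#'   voxel sigmas (length 3, used as-is when `units = "voxel"`).
#' @param spacing voxel spacing when `img` is a bare array.
#' @param units "um" (default) or "voxel".
#' @return Array of the same dimension (or image_stack if input was one).
#' @export
gaussian_filter <- function(img, sigma, spacing = NULL, units = c("um", "voxel")) {
  units <- match.arg(units)
  v <- as_volume(img, spacing)
  sig <- if (units == "um") rep(sigma, length.out = 3) / v$spacing
         else rep(sigma, length.out = 3)
  out <- v$values
  dims <- dim(out)
  for (ax in 0:2) {
    if (sig[ax + 1] <= 0) next
    k <- gaussian_kernel_1d(sig[ax + 1])
    out <- array(cpp_convolve_axis(as.numeric(out), dims, k, ax), dim = dims)
  }
  if (inherits(img, "image_stack")) image_stack(out, v$spacing, img$channel) else out
}

morph_apply <- function(img, spacing, offsets, dilate) {
  dims <- dim(img)
  array(cpp_morph_gray(as.numeric(img), dims, offsets, dilate), dim = dims)
}

#' Grayscale opening / closing / tophat
#'
#' Flat grayscale morphology with a ball structuring element. The white
#' tophat (image minus its opening) is the high-pass operator used to
#' isolate bright structures smaller than the element.
#'
#' @param img image_stack or 3D array.
#' @param radius element radius (um when `spacing` known, else voxels).
#' @param spacing voxel spacing for bare arrays; set `anisotropic = FALSE`
#'   to interpret `radius` in voxels even when spacing is known.
#' @param anisotropic logical; scale the element by voxel spacing.
#' @return Filtered array (or image_stack if input was one).
#' @name morphology
NULL

#' @rdname morphology
#' @export
gray_open <- function(img, radius, spacing = NULL, anisotropic = TRUE) {
  v <- as_volume(img, spacing)
  off <- ball_offsets(radius, if (anisotropic) v$spacing else NULL)
  out <- morph_apply(morph_apply(v$values, v$spacing, off, FALSE),
                     v$spacing, off, TRUE)
  if (inherits(img, "image_stack")) image_stack(out, v$spacing, img$channel) else out
}

#' @rdname morphology
#' @export
gray_close <- function(img, radius, spacing = NULL, anisotropic = TRUE) {
  v <- as_volume(img, spacing)
  off <- ball_offsets(radius, if (anisotropic) v$spacing else NULL)
  out <- morph_apply(morph_apply(v$values, v$spacing, off, TRUE),
                     v$spacing, off, FALSE)
  if (inherits(img, "image_stack")) image_stack(out, v$spacing, img$channel) else out
}

#' @rdname morphology
#' @export
white_tophat <- function(img, radius, spacing = NULL, anisotropic = TRUE) {
  v <- as_volume(img, spacing)
  opened <- as_volume(gray_open(img, radius, spacing, anisotropic), v$spacing)$values
  out <- v$values - opened
  out[out < 0] <- 0
  if (inherits(img, "image_stack")) image_stack(out, v$spacing, img$channel) else out
}

#' Median filter
#'
#' @inheritParams morphology
#' @export
median_filter <- function(img, radius, spacing = NULL, anisotropic = FALSE) {
  v <- as_volume(img, spacing)
  off <- ball_offsets(radius, if (anisotropic) v$spacing else NULL)
  out <- array(cpp_median_filter(as.numeric(v$values), dim(v$values), off),
               dim = dim(v$values))
  if (inherits(img, "image_stack")) image_stack(out, v$spacing, img$channel) else out
}

#' Grayscale hole filling
#'
#' Raises intensity minima that are not connected to the image border to
#' the level of their surroundings (morphological reconstruction by erosion
#' from a border marker). Used so that dark NPB interiors do not punch
#' holes through the nucleus mask at thresholding.
#'
#' @param img image_stack or 3D array.
#' @param spacing voxel spacing for bare arrays (unused by the filter, kept
#'   for interface symmetry).
#' @return Filled array (or image_stack).
#' @export
gray_hole_fill <- function(img, spacing = NULL) {
  v <- as_volume(img, spacing)
  x <- v$values
  dims <- dim(x)
  hi <- max(x)
  marker <- array(hi, dim = dims)
  marker[1, , ] <- x[1, , ]; marker[dims[1], , ] <- x[dims[1], , ]
  marker[, 1, ] <- x[, 1, ]; marker[, dims[2], ] <- x[, dims[2], ]
  marker[, , 1] <- x[, , 1]; marker[, , dims[3]] <- x[, , dims[3]]
  marker <- pmax(marker, x)
  # reconstruction by erosion = negated reconstruction by dilation
  out <- -array(cpp_reconstruct_dil(as.numeric(-marker), as.numeric(-x), dims),
                dim = dims)
  if (inherits(img, "image_stack")) image_stack(out, v$spacing, img$channel) else out
}

#' Morphological reconstruction by dilation
#'
#' @param marker marker array (clipped to `ceiling` if above it).
#' @param ceiling ceiling (mask image) array.
#' @return Reconstructed array.
#' @export
reconstruct_dilation <- function(marker, ceiling) {
  dims <- dim(ceiling)
  marker <- pmin(marker, ceiling)
  array(cpp_reconstruct_dil(as.numeric(marker), as.numeric(ceiling), dims),
        dim = dims)
}

#' Anisotropic Euclidean distance map
#'
#' Distance (um) from each foreground voxel to the nearest background
#' voxel, computed with the exact separable squared-distance transform on
#' the physical grid.
#'
#' @param mask logical 3D array (or image_stack/label_mask; nonzero =
#'   foreground).
#' @param spacing voxel spacing for bare arrays.
#' @return Numeric array of distances (0 on background).
#' @export
distance_map <- function(mask, spacing = NULL) {
  v <- as_volume(mask, spacing)
  fg <- v$values != 0
  if (!any(!fg))
    stop("mask has no background voxels; distance to background is undefined")
  array(sqrt(cpp_edt_sq(as.logical(fg), dim(fg), v$spacing)), dim = dim(fg))
}

#' Label connected components (6-connectivity)
#'
#' @param mask logical 3D array (nonzero = foreground).
#' @param spacing voxel spacing for bare arrays.
#' @return A `label_mask`: integer label array (0 = background), spacing,
#'   and per-label voxel counts.
#' @export
label_components <- function(mask, spacing = NULL) {
  v <- as_volume(mask, spacing)
  fg <- v$values != 0
  lab <- array(cpp_label_cc(as.logical(fg), dim(fg)), dim = dim(fg))
  new_label_mask(lab, v$spacing)
}

new_label_mask <- function(labels, spacing) {
  nlab <- max(labels)
  counts <- if (nlab > 0) tabulate(labels[labels > 0], nbins = nlab) else integer(0)
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 counts = counts),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s voxels, %d label(s)\n",
              paste(dim(x$labels), collapse = " x "), length(x$counts)))
  invisible(x)
}

#' Number of labels in a label mask
#' @param x a label_mask.
#' @export
n_labels <- function(x) length(x$counts)
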