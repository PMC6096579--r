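#' Preprocess a stack before thresholding
#'
#' Applies an ordered list of standard smoothing steps: `median(r)`,
#' `gaussian(sigma)`, `opening(r)`, `closing(r)`, `gray_hole_fill`. Radii
#' and sigma are in voxels by default; set `anisotropic = TRUE` to read
#' them as micrometers and scale the structuring elements by voxel
#' spacing.
#'
#' @param img image_stack or 3D array.
#' @param steps character vector, e.g.
#'   `c("median(1)", "gaussian(0.8)", "gray_hole_fill")`; empty = identity.
#' @param spacing voxel spacing for bare arrays.
#' @param anisotropic interpret radii in micrometers (default FALSE:
#'   voxels).
#' @return Preprocessed image (same type as input).
#' @export
preprocess <- function(img, steps = character(), spacing = NULL,
                       anisotropic = FALSE) {
  v <- as_volume(img, spacing)
  out <- img
  for (s in steps) {
    m <- regmatches(s, regexec("^([a-z_]+)\\(?([0-9.]*)\\)?$", s))[[1]]
    if (length(m) == 0) stop(sprintf("unknown preprocessing step: '%s'", s))
    name <- m[2]; arg <- suppressWarnings(as.numeric(m[3]))
    out <- switch(name,
      median = median_filter(out, arg, spacing = v$spacing,
                             anisotropic = anisotropic),
      gaussian = gaussian_filter(out, arg, spacing = v$spacing,
                                 units = if (anisotropic) "um" else "voxel"),
      opening = gray_open(out, arg, spacing = v$spacing,
                          anisotropic = anisotropic),
      closing = gray_close(out, arg, spacing = v$spacing,
                           anisotropic = anisotropic),
      gray_hole_fill = gray_hole_fill(out, spacing = v$spacing),
      stop(sprintf("unknown preprocessing step: '%s'", s)))
  }
  out
}

intensity_histogram <- function(vals, n_bins = 256L) {
  rng <- range(vals)
  if (diff(rng) == 0) stop("degenerate histogram: image is constant")
  # 8-bit-style binning: integer data in [0, 255] gets the canonical bins,
  # anything else is rescaled onto n_bins equal bins.
  if (all(vals == round(vals)) && rng[1] >= 0 && rng[2] <= 255) {
    edges <- seq(-0.5, 255.5, by = 1)
    centers <- 0:255
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    edges[1] <- edges[1] - 1e-9
    centers <- (edges[-1] + edges[-length(edges)]) / 2
  }
  counts <- tabulate(findInterval(vals, edges, rightmost.closed = TRUE),
                     nbins = length(centers))
  list(counts = counts, centers = centers, edges = edges)
}

otsu_threshold <- function(h) {
  p <- h$counts / sum(h$counts)
  mu <- h$centers
  w0 <- cumsum(p)
  m0 <- cumsum(p * mu)
  mt <- m0[length(m0)]
  w1 <- 1 - w0
  between <- (mt * w0 - m0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)  # foreground = bins above k
  h$edges[k + 1L]
}

max_entropy_threshold <- function(h) {
  p <- h$counts / sum(h$counts)
  nb <- length(p)
  cp <- cumsum(p)
  crit <- rep(-Inf, nb - 1L)
  for (k in seq_len(nb - 1L)) {
    w0 <- cp[k]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    p0 <- p[1:k] / w0
    p1 <- p[(k + 1L):nb] / w1
    h0 <- -sum(p0[p0 > 0] * log(p0[p0 > 0]))
    h1 <- -sum(p1[p1 > 0] * log(p1[p1 > 0]))
    crit[k] <- h0 + h1
  }
  k <- which.max(crit)
  h$edges[k + 1L]
}

rats_threshold <- function(img, spacing, roi) {
  dims <- dim(img)
  g2 <- array(0, dim = dims)
  for (ax in 1:3) {
    d <- (dims[ax] > 2)
    if (!d) next
    shift_p <- img; shift_m <- img
    if (ax == 1) {
      shift_p[1:(dims[1] - 1), , ] <- img[2:dims[1], , ]
      shift_m[2:dims[1], , ] <- img[1:(dims[1] - 1), , ]
    } else if (ax == 2) {
      shift_p[, 1:(dims[2] - 1), ] <- img[, 2:dims[2], ]
      shift_m[, 2:dims[2], ] <- img[, 1:(dims[2] - 1), ]
    } else {
      shift_p[, , 1:(dims[3] - 1)] <- img[, , 2:dims[3]]
      shift_m[, , 2:dims[3]] <- img[, , 1:(dims[3] - 1)]
    }
    g2 <- g2 + ((shift_p - shift_m) / (2 * spacing[ax]))^2
  }
  w <- g2[roi]
  if (sum(w) == 0) stop("degenerate histogram: no gradient within roi")
  sum(w * img[roi]) / sum(w)
}

#' Automatic threshold selection
#'
#' Three classical methods on the in-ROI intensity distribution: Otsu
#' (maximum between-class variance), maximum entropy (Kapur: maximum sum
#' of class Shannon entropies), and RATS (robust automatic threshold
#' selection: the gradient-weighted mean intensity
#' t = sum(w I) / sum(w) with w the squared gradient magnitude).
#' Histograms use 256 bins (native bins for 8-bit data). Foreground is
#' defined as intensities >= the returned threshold.
#'
#' @param img image_stack or 3D array.
#' @param method "otsu", "max_entropy" or "rats".
#' @param roi optional logical array restricting the computation.
#' @param spacing voxel spacing for bare arrays (used by the RATS
#'   gradient).
#' @return Scalar threshold.
#' @export
compute_threshold <- function(img, method = c("otsu", "max_entropy", "rats"),
                              roi = NULL, spacing = NULL) {
  method <- match.arg(method)
  v <- as_volume(img, spacing)
  roi_l <- if (is.null(roi)) array(TRUE, dim = dim(v$values)) else roi != 0
  vals <- v$values[roi_l]
  if (length(vals) == 0) stop("empty roi")
  if (diff(range(vals)) == 0) stop("degenerate histogram: image is constant")
  switch(method,
    otsu = otsu_threshold(intensity_histogram(vals)),
    max_entropy = max_entropy_threshold(intensity_histogram(vals)),
    rats = rats_threshold(v$values, v$spacing, roi_l))
}

component_border_fraction <- function(lab, label) {
  dims <- dim(lab)
  comp <- lab == label
  # surface voxels: any 6-neighbor outside the component (or outside grid)
  surface <- comp & !(shift_and(comp))
  surf_idx <- which(surface)
  if (length(surf_idx) == 0) return(0)
  idx0 <- surf_idx - 1L
  i <- idx0 %% dims[1]; j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  on_border <- i == 0 | i == dims[1] - 1 | j == 0 | j == dims[2] - 1 |
    k == 0 | k == dims[3] - 1
  mean(on_border)
}

# TRUE where all 6 neighbors exist and are TRUE (erosion by the 6-cross).
shift_and <- function(comp) {
  dims <- dim(comp)
  out <- comp
  f <- function(a, ax, by) {
    r <- array(FALSE, dim = dims)
    if (ax == 1) {
      if (by == 1) r[1:(dims[1] - 1), , ] <- a[2:dims[1], , ]
      else r[2:dims[1], , ] <- a[1:(dims[1] - 1), , ]
    } else if (ax == 2) {
      if (by == 1) r[, 1:(dims[2] - 1), ] <- a[, 2:dims[2], ]
      else r[, 2:dims[2], ] <- a[, 1:(dims[2] - 1), ]
    } else {
      if (by == 1) r[, , 1:(dims[3] - 1)] <- a[, , 2:dims[3]]
      else r[, , 2:dims[3]] <- a[, , 1:(dims[3] - 1)]
    }
    r
  }
  out & f(comp, 1, 1) & f(comp, 1, -1) & f(comp, 2, 1) & f(comp, 2, -1) &
    f(comp, 3, 1) & f(comp, 3, -1)
}

#' Segment nuclei from a stack
#'
#' Threshold, label 6-connected components, then drop components smaller
#' than `min_volume` um^3 or with more than `max_border_fraction` of their
#' surface voxels on the image border (over-truncated nuclei). Surviving
#' components are relabeled contiguously in scan order.
#'
#' @param img image_stack or 3D array (typically preprocessed).
#' @param method threshold method for [compute_threshold()].
#' @param min_volume minimum component volume (um^3).
#' @param max_border_fraction maximum tolerated fraction of surface voxels
#'   on the image border.
#' @param spacing voxel spacing for bare arrays.
#' @param threshold optional fixed threshold overriding `method`.
#' @return A `label_mask`; empty (with a warning) when nothing survives.
#' @export
segment_nuclei <- function(img, method = "otsu", min_volume = 200,
                           max_border_fraction = 0.3, spacing = NULL,
                           threshold = NULL) {
  v <- as_volume(img, spacing)
  t0 <- if (is.null(threshold)) compute_threshold(img, method, spacing = spacing)
        else threshold
  fg <- v$values >= t0
  cc <- label_components(fg, v$spacing)
  vol_vox <- voxel_volume(v$spacing)
  keep <- integer(0)
  for (l in seq_len(n_labels(cc))) {
    if (cc$counts[l] * vol_vox < min_volume) next
    if (component_border_fraction(cc$labels, l) > max_border_fraction) next
    keep <- c(keep, l)
  }
  lab <- array(0L, dim = dim(fg))
  for (i in seq_along(keep)) lab[cc$labels == keep[i]] <- i
  out <- new_label_mask(lab, v$spacing)
  if (n_labels(out) == 0)
    warning("no component survived size/border filtering; empty mask")
  attr(out, "threshold") <- t0
  out
}

#' Split touching nuclei by watershed on the distance map
#'
#' Seeds are the regional maxima of the anisotropic Euclidean distance map
#' after h-maxima suppression; the watershed floods the negated distance
#' map inside the existing foreground, so the voxel set is preserved and
#' the label count can only grow. Deterministic: ties resolve in raster
#' scan order.
#'
#' @param mask binary or labeled mask (`label_mask` or array).
#' @param h depth (um) of h-maxima suppression; maxima shallower than `h`
#'   do not seed a separate object.
#' @param spacing voxel spacing for bare arrays.
#' @return A `label_mask` with relabeled, possibly split, objects.
#' @export
split_touching <- function(mask, h = 1, spacing = NULL) {
  v <- as_volume(mask, spacing)
  fg <- v$values != 0
  dims <- dim(fg)
  if (!any(fg)) return(new_label_mask(array(0L, dim = dims), v$spacing))
  d <- array(sqrt(cpp_edt_sq(as.logical(fg), dims, v$spacing)), dim = dims)
  # h-maxima: reconstruction by dilation of (d - h) under d
  rec <- reconstruct_dilation(d - h, d)
  hm <- rec
  eps <- 1e-6
  rec2 <- reconstruct_dilation(hm - eps, hm)
  seeds_mask <- (hm - rec2) > eps / 2 & fg
  seeds <- label_components(seeds_mask, v$spacing)
  if (n_labels(seeds) == 0) {
    # no interior maximum (degenerate small object): keep as one label
    return(label_components(fg, v$spacing))
  }
  lab <- array(cpp_watershed(as.numeric(-d), seeds$labels, as.logical(fg), dims),
               dim = dims)
  new_label_mask(lab, v$spacing)
}
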