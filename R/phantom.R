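#' Phantom specification
#'
#' Parameters of a synthetic one-nucleus confocal stack with known ground
#' truth. Defaults emulate an early-embryo nucleus: an ellipsoidal, mildly
#' deformed nucleus of ~1200 um^3 (the observed range across stages is
#' ~1150-2800 um^3), 24 spots in channel A and 12 in channel B (the
#' expected metaphase counts of the two pericentromeric satellite families),
#' a few dark spherical NPBs, 8-bit intensities, and anisotropic voxels
#' with the acquisition z-step of 0.37 um.
#'
#' The radial law of spot centers is a Beta(a, b) distribution on the
#' target eroded volume fraction: (1, 1) is uniform over the nucleus,
#' Beta(a > 1, 1) loads the center, Beta(1, b > 1) the periphery. Polarity
#' is an exponential half-space weighting exp(lambda * cos(theta)) toward
#' `pole`; lambda = 0 is the unpolarized null.
#'
#' @param grid_shape voxel counts (nx, ny, nz).
#' @param spacing voxel spacing in um; default z-step 0.37.
#' @param nucleus_semiaxes ellipsoid semiaxes in um.
#' @param deform_amplitude relative radial deformation in [0, 0.3].
#' @param n_spots_a,n_spots_b spot counts for the two signal channels.
#' @param spot_radius quarter-maximum radius of rendered spots (um).
#' @param spot_min_separation minimum distance between spot centers (um);
#'   default 3 * spot_radius keeps rendered spots resolvable as distinct
#'   objects (chromocenters are compact, separate bodies). Set 0 for pure
#'   point-process sampling.
#' @param radial_bias Beta(a, b) parameters of the spot-center EVF law.
#' @param polarity_strength half-space weighting exponent lambda (>= 0).
#' @param pole polarity direction (any nonzero 3-vector).
#' @param n_npb number of nucleolar precursor bodies (dark voids).
#' @param npb_radius NPB radius in um.
#' @param intensities list: `background`, `nucleoplasm`, `spot_amplitude`
#'   (8-bit levels) and `npb_dimming` in [0, 1) (NPBs are darker than
#'   nucleoplasm).
#' @param noise list: `gaussian_sd` (read noise, 8-bit units) and
#'   `poisson_gain` (photons per intensity unit for shot noise; 0 = off).
#' @param seed integer; the phantom is a pure function of (spec, seed).
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 48),
                         spacing = c(0.14, 0.14, 0.37),
                         nucleus_semiaxes = c(7.2, 6.5, 6.0),
                         deform_amplitude = 0.1,
                         n_spots_a = 24, n_spots_b = 12,
                         spot_radius = 0.4,
                         spot_min_separation = NULL,
                         radial_bias = c(1, 1),
                         polarity_strength = 0,
                         pole = c(0, 0, 1),
                         n_npb = 3, npb_radius = 1.2,
                         intensities = list(background = 8, nucleoplasm = 90,
                                            spot_amplitude = 160,
                                            npb_dimming = 0.35),
                         noise = list(gaussian_sd = 0, poisson_gain = 0),
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               nucleus_semiaxes = as.numeric(nucleus_semiaxes),
               deform_amplitude = deform_amplitude,
               n_spots_a = as.integer(n_spots_a), n_spots_b = as.integer(n_spots_b),
               spot_radius = spot_radius,
               spot_min_separation = if (is.null(spot_min_separation))
                 3 * spot_radius else spot_min_separation,
               radial_bias = as.numeric(radial_bias),
               polarity_strength = polarity_strength, pole = as.numeric(pole),
               n_npb = as.integer(n_npb), npb_radius = npb_radius,
               intensities = intensities, noise = noise, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 8L))
    stop("grid_shape must be 3 counts of at least 8 voxels")
  if (any(spec$spacing <= 0)) stop("all spacings must be > 0")
  if (length(spec$nucleus_semiaxes) != 3L || any(spec$nucleus_semiaxes <= 0))
    stop("nucleus_semiaxes must be 3 positive lengths (um)")
  if (spec$deform_amplitude < 0 || spec$deform_amplitude > 0.3)
    stop("deform_amplitude must lie in [0, 0.3]")
  extent <- spec$grid_shape * spec$spacing
  need <- spec$nucleus_semiaxes * (1 + spec$deform_amplitude)
  if (any(need >= extent / 2 - spec$spacing))
    stop(sprintf(paste0("nucleus semiaxes too large for grid: deformed ",
                        "semi-extent (%.2f, %.2f, %.2f) um must fit inside ",
                        "half the grid extent (%.2f, %.2f, %.2f) um with a ",
                        "one-voxel margin"),
                 need[1], need[2], need[3],
                 extent[1] / 2, extent[2] / 2, extent[3] / 2))
  if (length(spec$radial_bias) != 2L || any(spec$radial_bias <= 0))
    stop("radial_bias must be two positive Beta parameters")
  if (spec$polarity_strength < 0) stop("polarity_strength must be >= 0")
  if (sum(spec$pole^2) == 0) stop("pole must be a nonzero vector")
  dimming <- spec$intensities$npb_dimming
  if (is.null(dimming) || dimming < 0 || dimming >= 1)
    stop("intensities$npb_dimming must lie in [0, 1): NPBs are darker than nucleoplasm")
  invisible(spec)
}

# Smooth direction field g(u) in [-1, 1] built from random quadratic forms;
# drives the radial deformation of the nucleus boundary.
deformation_field <- function(seed) {
  with_seed(seed, {
    m <- 4L
    a <- matrix(rnorm(3 * m), 3); a <- sweep(a, 2, sqrt(colSums(a^2)), "/")
    b <- matrix(rnorm(3 * m), 3); b <- sweep(b, 2, sqrt(colSums(b^2)), "/")
    cf <- runif(m, -1, 1)
    list(a = a, b = b, cf = cf, norm = sum(abs(cf)))
  })
}

eval_deformation <- function(field, u) {
  # u: n x 3 unit directions
  g <- rep(0, nrow(u))
  for (m in seq_along(field$cf))
    g <- g + field$cf[m] * (u %*% field$a[, m]) * (u %*% field$b[, m])
  as.numeric(g) / field$norm
}

#' Generate the nucleus mask of a phantom
#'
#' Builds a deformed ellipsoid: the base ellipsoid boundary is displaced
#' radially by `deform_amplitude` times a smooth random direction field
#' (drawn from the phantom seed), so the shape is star-shaped about its
#' center and stays 6-connected. The analytic volume of the continuous
#' shape is attached as attribute `analytic_volume` (um^3).
#'
#' @param spec a `phantom_spec`.
#' @return A binary `label_mask` (single label).
#' @export
make_nucleus_mask <- function(spec) {
  validate_phantom_spec(spec)
  dims <- spec$grid_shape; sp <- spec$spacing
  ax <- spec$nucleus_semiaxes; A <- spec$deform_amplitude
  center <- dims * sp / 2
  x <- ((seq_len(dims[1]) - 0.5) * sp[1] - center[1]) / ax[1]
  y <- ((seq_len(dims[2]) - 0.5) * sp[2] - center[2]) / ax[2]
  z <- ((seq_len(dims[3]) - 0.5) * sp[3] - center[3]) / ax[3]
  vx <- array(rep(x, times = dims[2] * dims[3]), dim = dims)
  vy <- array(rep(rep(y, each = dims[1]), times = dims[3]), dim = dims)
  vz <- array(rep(z, each = dims[1] * dims[2]), dim = dims)
  r <- sqrt(vx^2 + vy^2 + vz^2)

  if (A > 0) {
    field <- deformation_field(spec$seed + 101L)
    rs <- pmax(r, 1e-12)
    u <- cbind(as.numeric(vx / rs), as.numeric(vy / rs), as.numeric(vz / rs))
    lim <- 1 + A * eval_deformation(field, u)
    inside <- array(as.numeric(r) <= lim, dim = dims)
    # analytic volume by spherical quadrature over the star-shaped boundary
    ud <- fibonacci_sphere(4000L)
    vol <- prod(ax) * mean((1 + A * eval_deformation(field, ud))^3) * 4 * pi / 3
  } else {
    inside <- r <= 1
    vol <- prod(ax) * 4 * pi / 3
  }

  cc <- label_components(inside, sp)
  if (n_labels(cc) > 1L) {
    keep <- which.max(cc$counts)
    inside <- cc$labels == keep
  }
  out <- new_label_mask(array(as.integer(inside), dim = dims), sp)
  attr(out, "analytic_volume") <- vol
  attr(out, "center") <- center
  out
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Sample spot centers with a radial law and optional polarity
#'
#' Draws a target EVF value u ~ Beta(a, b) per spot and places the spot at
#' the candidate voxel whose EVF is nearest in rank, so the generated
#' radial bias is exact under the same EVF definition the analysis uses.
#' Polarity is imposed by rejection with weight exp(lambda * cos(theta)),
#' theta measured from `pole` through the nuclear centroid. With
#' (a, b) = (1, 1) and lambda = 0 the sampler is uniform over the mask.
#'
#' @param mask nucleus mask (`label_mask` or logical array with spacing).
#' @param n number of spots (>= 1).
#' @param radial_bias Beta(a, b) parameters of the target EVF law.
#' @param polarity_strength lambda >= 0.
#' @param pole polarity direction.
#' @param seed RNG seed.
#' @param exclude optional logical array of voxels to avoid (e.g. NPBs).
#' @param min_separation minimum pairwise distance between accepted
#'   centers (um); 0 disables the constraint.
#' @param spacing spacing for bare-array masks.
#' @return List: `centers` (n x 3 um), `evf` (generation EVF per spot),
#'   `index` (voxel linear indices).
#' @export
sample_spot_centers <- function(mask, n, radial_bias = c(1, 1),
                                polarity_strength = 0, pole = c(0, 0, 1),
                                seed = 1L, exclude = NULL,
                                min_separation = 0, spacing = NULL) {
  stopifnot(n >= 1)
  v <- as_volume(mask, spacing)
  fg <- v$values != 0
  if (!any(fg)) stop("mask is empty")
  ev <- evf_map(mask, spacing = spacing)
  cand <- fg
  if (!is.null(exclude)) cand <- cand & !exclude
  cand_idx <- which(cand)
  if (n > length(cand_idx))
    stop(sprintf("requested %d spots but only %d candidate voxels", n,
                 length(cand_idx)))
  ev_cand <- ev$values[cand_idx]
  dims <- dim(fg)
  centroid <- colMeans(voxel_coords(which(fg), dims, v$spacing))
  pole <- pole / sqrt(sum(pole^2))
  a <- radial_bias[1]; b <- radial_bias[2]
  lambda <- polarity_strength

  with_seed(seed, {
    ord <- order(ev_cand, runif(length(ev_cand)))
    sev <- ev_cand[ord]
    sidx <- cand_idx[ord]
    ncand <- length(sidx)
    centers <- matrix(NA_real_, n, 3)
    evs <- numeric(n)
    idxs <- integer(n)
    for (s in seq_len(n)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 100000L) stop("polarity rejection sampling failed to accept")
        u <- if (a == 1 && b == 1) runif(1) else rbeta(1, a, b)
        j <- findInterval(u, sev)
        j <- if (j < 1L) 1L
             else if (j >= ncand) ncand
             else if (u - sev[j] <= sev[j + 1L] - u) j else j + 1L
        pos <- voxel_coords(sidx[j], dims, v$spacing)[1, ]
        if (lambda > 0) {
          d <- pos - centroid
          nd <- sqrt(sum(d^2))
          cth <- if (nd < 1e-12) 1 else sum(d * pole) / nd
          if (runif(1) >= exp(lambda * (cth - 1))) next
        }
        if (min_separation > 0 && s > 1L) {
          prev <- centers[seq_len(s - 1L), , drop = FALSE]
          if (min(sqrt(colSums((t(prev) - pos)^2))) < min_separation) next
        }
        centers[s, ] <- pos
        evs[s] <- sev[j]
        idxs[s] <- sidx[j]
        break
      }
    }
    list(centers = centers, evf = evs, index = idxs)
  })
}

#' Place non-overlapping spherical NPBs inside the nucleus
#'
#' Rejection-samples NPB centers among voxels deeper than `radius` from the
#' nuclear surface, enforcing pairwise center distances > 2 * radius so the
#' voxelized spheres are disjoint.
#'
#' @param mask nucleus mask.
#' @param n_npb number of NPBs (0 allowed).
#' @param radius NPB radius (um).
#' @param seed RNG seed.
#' @param max_retries placement attempts before giving up.
#' @param spacing spacing for bare-array masks.
#' @return List: `centers` (n x 3 um), `radius`, `labels` (`label_mask`,
#'   one label per NPB, 0 elsewhere).
#' @export
place_npbs <- function(mask, n_npb, radius, seed = 1L, max_retries = 2000L,
                       spacing = NULL) {
  v <- as_volume(mask, spacing)
  dims <- dim(v$values)
  lab <- array(0L, dim = dims)
  if (n_npb == 0)
    return(list(centers = matrix(numeric(0), 0, 3), radius = radius,
                labels = new_label_mask(lab, v$spacing)))
  dmap <- distance_map(v$values != 0, v$spacing)
  cand <- which(dmap > radius)
  if (length(cand) == 0)
    stop(sprintf("placed 0 of %d NPBs: no voxel lies deeper than %.2f um from the surface",
                 n_npb, radius))
  coords <- voxel_coords(cand, dims, v$spacing)
  # two-voxel clearance so voxelized, then smoothed, spheres never merge
  min_sep <- 2 * radius + 2 * max(v$spacing)
  centers <- with_seed(seed, {
    placed <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(placed) < n_npb && tries < max_retries) {
      tries <- tries + 1L
      p <- coords[sample.int(length(cand), 1L), ]
      if (nrow(placed) == 0 ||
          all(sqrt(colSums((t(placed) - p)^2)) > min_sep))
        placed <- rbind(placed, p)
    }
    placed
  })
  if (nrow(centers) < n_npb)
    stop(sprintf("placed %d of %d NPBs after %d retries; reduce n_npb or radius",
                 nrow(centers), n_npb, max_retries))
  for (s in seq_len(nrow(centers)))
    lab <- paint_ball(lab, centers[s, ], radius, v$spacing, s)
  list(centers = centers, radius = radius,
       labels = new_label_mask(lab, v$spacing))
}

# Set voxels within `radius` um of `center` to `value` (bounding-box scan).
paint_ball <- function(lab, center, radius, spacing, value) {
  dims <- dim(lab)
  lo <- pmax(1L, floor((center - radius) / spacing - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center + radius) / spacing + 0.5))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  px <- (ii - 0.5) * spacing[1] - center[1]
  py <- (jj - 0.5) * spacing[2] - center[2]
  pz <- (kk - 0.5) * spacing[3] - center[3]
  sub <- array(rep(px^2, times = length(jj) * length(kk)),
               dim = c(length(ii), length(jj), length(kk))) +
         array(rep(rep(py^2, each = length(ii)), times = length(kk)),
               dim = c(length(ii), length(jj), length(kk))) +
         array(rep(pz^2, each = length(ii) * length(jj)),
               dim = c(length(ii), length(jj), length(kk)))
  block <- lab[ii, jj, kk, drop = FALSE]
  block[sub <= radius^2] <- value
  lab[ii, jj, kk] <- block
  lab
}

#' Render a phantom into multi-channel 8-bit stacks
#'
#' DNA channel: background outside the nucleus, nucleoplasm level inside,
#' dimmed inside NPBs. Signal channels: isotropic Gaussian blobs at the
#' spot centers, scaled so the quarter-maximum radius equals
#' `spot_radius`. Optional Poisson shot noise then Gaussian read noise;
#' values are clipped to [0, 255] and quantized.
#'
#' @param spec a `phantom_spec`.
#' @param mask nucleus mask from [make_nucleus_mask()].
#' @param spots named list of spot-center results (e.g. `a`, `b`), each as
#'   returned by [sample_spot_centers()].
#' @param npbs NPB placement from [place_npbs()], or NULL.
#' @return Named list of `image_stack` objects: `dna` plus one per spot
#'   channel.
#' @export
render_stack <- function(spec, mask, spots = list(), npbs = NULL) {
  v <- as_volume(mask)
  dims <- dim(v$values); sp <- v$spacing
  ints <- spec$intensities
  fg <- v$values != 0
  dna <- array(ints$background, dim = dims)
  dna[fg] <- ints$nucleoplasm
  if (!is.null(npbs) && n_labels(npbs$labels) > 0)
    dna[npbs$labels$labels > 0] <- ints$nucleoplasm * ints$npb_dimming
  out <- list(dna = dna)
  sigma <- spec$spot_radius / sqrt(2 * log(4))  # quarter-max radius = spot_radius
  for (ch in names(spots)) {
    img <- array(ints$background, dim = dims)
    for (s in seq_len(nrow(spots[[ch]]$centers)))
      img <- add_blob(img, spots[[ch]]$centers[s, ], sigma,
                      ints$spot_amplitude, sp)
    out[[ch]] <- img
  }
  noise_seed <- spec$seed + 300L
  for (ci in seq_along(out)) {
    x <- out[[ci]]
    if (spec$noise$poisson_gain > 0) {
      gain <- spec$noise$poisson_gain
      x <- with_seed(noise_seed + 7L * ci,
                     array(rpois(length(x), pmax(x, 0) * gain) / gain, dim = dims))
    }
    if (spec$noise$gaussian_sd > 0)
      x <- x + with_seed(noise_seed + 7L * ci + 1L,
                         array(rnorm(length(x), 0, spec$noise$gaussian_sd),
                               dim = dims))
    x <- round(pmin(pmax(x, 0), 255))
    out[[ci]] <- image_stack(x, sp, channel = names(out)[ci])
  }
  out
}

add_blob <- function(img, center, sigma, amplitude, spacing) {
  dims <- dim(img)
  r <- 3.5 * sigma
  lo <- pmax(1L, floor((center - r) / spacing - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center + r) / spacing + 0.5))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  px <- (ii - 0.5) * spacing[1] - center[1]
  py <- (jj - 0.5) * spacing[2] - center[2]
  pz <- (kk - 0.5) * spacing[3] - center[3]
  d2 <- array(rep(px^2, times = length(jj) * length(kk)),
              dim = c(length(ii), length(jj), length(kk))) +
        array(rep(rep(py^2, each = length(ii)), times = length(kk)),
              dim = c(length(ii), length(jj), length(kk))) +
        array(rep(pz^2, each = length(ii) * length(jj)),
              dim = c(length(ii), length(jj), length(kk)))
  img[ii, jj, kk] <- img[ii, jj, kk] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

#' Simulate a complete phantom with ground truth
#'
#' One-call generator: nucleus mask, NPB placement, spot centers for both
#' channels (sampled outside the NPB regions dilated by the spot radius, so
#' rendered spots stay disjoint from NPBs), and rendered 8-bit channels.
#'
#' @param spec a `phantom_spec`.
#' @return An object of class `phantom`: `channels` (list of
#'   `image_stack`: dna, a, b), `mask` (ground-truth nucleus), `spots_a`,
#'   `spots_b` (centers + generation EVFs), `npbs`, `spec`.
#' @export
simulate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  mask <- make_nucleus_mask(spec)
  npbs <- place_npbs(mask, spec$n_npb, spec$npb_radius, seed = spec$seed + 11L)
  exclude <- NULL
  if (n_labels(npbs$labels) > 0) {
    dnpb <- sqrt(array(cpp_edt_sq(npbs$labels$labels == 0,
                                  dim(npbs$labels$labels), mask$spacing),
                       dim = dim(npbs$labels$labels)))
    exclude <- dnpb <= spec$spot_radius + max(mask$spacing)
  }
  spots_a <- sample_spot_centers(mask, spec$n_spots_a, spec$radial_bias,
                                 spec$polarity_strength, spec$pole,
                                 seed = spec$seed + 21L, exclude = exclude,
                                 min_separation = spec$spot_min_separation)
  spots_b <- sample_spot_centers(mask, spec$n_spots_b, spec$radial_bias,
                                 spec$polarity_strength, spec$pole,
                                 seed = spec$seed + 22L, exclude = exclude,
                                 min_separation = spec$spot_min_separation)
  channels <- render_stack(spec, mask, list(a = spots_a, b = spots_b), npbs)
  structure(list(channels = channels, mask = mask, spots_a = spots_a,
                 spots_b = spots_b, npbs = npbs, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, %d + %d spots, %d NPB(s), seed %d\n",
              paste(x$spec$grid_shape, collapse = " x "),
              x$spec$n_spots_a, x$spec$n_spots_b,
              nrow(x$npbs$centers), x$spec$seed))
  invisible(x)
}

#' Spot centers decorating NPB surfaces
#'
#' Returns one point per requested NPB, sitting on the NPB surface along a
#' fixed direction; used to construct phantoms where exactly k of n NPBs
#' carry an adjacent signal.
#'
#' @param npbs result of [place_npbs()].
#' @param which_npbs integer indices of the NPBs to decorate.
#' @param offset extra distance beyond the NPB surface (um; default 0 =
#'   touching).
#' @param toward optional point (um); each direction then points from the
#'   NPB center toward it (e.g. the nuclear center, keeping decorated
#'   points interior). Default: +x.
#' @return Matrix (k x 3) of points (um).
#' @export
npb_surface_points <- function(npbs, which_npbs, offset = 0, toward = NULL) {
  t(vapply(which_npbs, function(s) {
    dir <- if (is.null(toward)) c(1, 0, 0) else toward - npbs$centers[s, ]
    if (sqrt(sum(dir^2)) < 1e-9) dir <- c(1, 0, 0)
    dir <- dir / sqrt(sum(dir^2))
    npbs$centers[s, ] + (npbs$radius + offset) * dir
  }, numeric(3)))
}
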