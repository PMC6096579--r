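test_that("nucleus mask reproduces the analytic sphere volume", {
  m <- iso_sphere_mask(radius = 5, n = 48, s = 0.25)
  vol <- sum(m$labels) * prod(m$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.05)
  expect_equal(n_labels(m), 1L)
  # boundary does not touch the grid border
  expect_true(all(m$labels[1, , ] == 0) && all(m$labels[, , 1] == 0) &&
              all(m$labels[dim(m$labels)[1], , ] == 0))
})

test_that("deformed masks are deterministic in the seed and match the analytic volume", {
  spec <- tiny_spec(seed = 7, deform_amplitude = 0.2)
  m1 <- make_nucleus_mask(spec)
  m2 <- make_nucleus_mask(spec)
  expect_identical(m1$labels, m2$labels)
  vol <- sum(m1$labels) * prod(m1$spacing)
  expect_lt(abs(vol - attr(m1, "analytic_volume")) / attr(m1, "analytic_volume"),
            0.10)
  # still one connected component
  expect_equal(n_labels(label_components(m1$labels > 0, m1$spacing)), 1L)
})

test_that("oversized semiaxes are rejected with an explicit message", {
  expect_error(phantom_spec(grid_shape = c(64, 64, 64),
                            spacing = c(0.25, 0.25, 0.25),
                            nucleus_semiaxes = c(50, 50, 50)),
               "too large")
})

test_that("uniform sampler matches U(0,1) in EVF and Beta laws shift the mean", {
  m <- make_nucleus_mask(tiny_spec(3))
  sc <- sample_spot_centers(m, 10000, c(1, 1), seed = 7)
  expect_lte(ks_stat_unif(sc$evf), 0.03)
  # every center lies inside the mask
  expect_true(all(m$labels[sc$index] > 0))
  m5 <- sample_spot_centers(m, 2000, c(5, 1), seed = 8)
  expect_gt(mean(m5$evf), 0.7)  # Beta(5,1) mean 5/6, discretization slack
  # monotonicity of the radial law in a
  means <- vapply(c(1, 2, 5), function(a)
    mean(sample_spot_centers(m, 1500, c(a, 1), seed = 9)$evf), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("polarized sampling displaces the centroid toward the pole", {
  m <- make_nucleus_mask(tiny_spec(4))
  pole <- c(0, 0, 1)
  sc <- sample_spot_centers(m, 200, c(1, 1), polarity_strength = 5,
                            pole = pole, seed = 11)
  centroid <- colMeans(nucradial:::voxel_coords(which(m$labels > 0),
                                                dim(m$labels), m$spacing))
  proj <- sum((colMeans(sc$centers) - centroid) * pole)
  expect_gt(proj, 0)
})

test_that("NPB placement yields disjoint interior spheres or a clear error", {
  m <- iso_sphere_mask(radius = 5, n = 48, s = 0.25)
  empty <- place_npbs(m, 0, 1)
  expect_equal(nrow(empty$centers), 0)
  expect_equal(n_labels(empty$labels), 0L)

  np <- place_npbs(m, 3, 1, seed = 2)
  expect_equal(nrow(np$centers), 3)
  dists <- as.matrix(dist(np$centers))
  expect_true(all(dists[upper.tri(dists)] > 2))
  # spheres fully inside the nucleus
  expect_true(all(m$labels[np$labels$labels > 0] > 0))
  # NPB radius at or above the smallest semiaxis cannot be placed
  expect_error(place_npbs(m, 1, 5.5, seed = 1), "placed 0")
})

test_that("rendering is piecewise-constant without noise and seed-reproducible", {
  spec <- tiny_spec(5, n_npb = 2, npb_radius = 0.8)
  ph1 <- simulate_phantom(spec)
  ph2 <- simulate_phantom(spec)
  expect_identical(ph1$channels$dna$values, ph2$channels$dna$values)
  expect_identical(ph1$channels$a$values, ph2$channels$a$values)
  # DNA channel: background, nucleoplasm, dimmed NPB level only
  expect_equal(sort(unique(as.numeric(ph1$channels$dna$values))),
               sort(c(spec$intensities$background,
                      spec$intensities$nucleoplasm,
                      round(spec$intensities$nucleoplasm *
                            spec$intensities$npb_dimming))))
  # spot channel maximum sits within one voxel pitch of a generated center
  am <- which.max(ph1$channels$a$values)
  pos <- nucradial:::voxel_coords(am, dim(ph1$channels$a$values), spec$spacing)
  dmin <- min(sqrt(colSums((t(ph1$spots_a$centers) - pos[1, ])^2)))
  expect_lte(dmin, max(spec$spacing) + 1e-9)
  # NPB voxels never overlap spot-center voxels
  expect_true(all(ph1$npbs$labels$labels[ph1$spots_a$index] == 0))
})
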