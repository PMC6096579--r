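test_that("shape normalization is the identity scale on a sphere", {
  m <- iso_sphere_mask(radius = 5, n = 48, s = 0.25)
  tr <- normalize_shape(m)
  expect_lt(abs(tr$radius - 5) / 5, 0.02)
  expect_equal(tr$whitening, diag(3), tolerance = 0.02)
})

test_that("whitening makes a 2:1 ellipsoid's second moments isotropic", {
  m <- make_nucleus_mask(phantom_spec(
    grid_shape = c(72, 48, 26), spacing = c(0.25, 0.25, 0.37),
    nucleus_semiaxes = c(8, 4, 4), deform_amplitude = 0, n_npb = 0))
  tr <- normalize_shape(m)
  co <- nucradial:::voxel_coords(which(m$labels > 0), dim(m$labels), m$spacing)
  w <- t(tr$whitening %*% (t(co) - tr$centroid))
  s2 <- crossprod(w) / nrow(w)
  offdiag <- abs(s2[upper.tri(s2)])
  expect_lt(max(offdiag), 0.01 * max(diag(s2)))
  expect_lt(diff(range(diag(s2))) / mean(diag(s2)), 0.01)
  # volume preserving: det(W) = 1
  expect_equal(det(tr$whitening), 1, tolerance = 1e-9)
})

test_that("normalized distances are invariant to 90-degree rotation", {
  m <- make_nucleus_mask(tiny_spec(61, deform_amplitude = 0.15))
  sc <- sample_spot_centers(m, 24, c(1, 1), polarity_strength = 3, seed = 2)
  d0 <- as.numeric(centroid_distance(sc$centers, normalize_shape(m)))
  rot <- aperm(m$labels, c(2, 1, 3))
  trr <- normalize_shape(rot, spacing = m$spacing[c(2, 1, 3)])
  centers_rot <- sc$centers[, c(2, 1, 3)]
  d1 <- as.numeric(centroid_distance(centers_rot, trr))
  expect_lt(abs(d1 - d0), 0.01)
})

test_that("centroid distance hits its geometric anchors", {
  m <- iso_sphere_mask(radius = 5, n = 48, s = 0.25)
  tr <- normalize_shape(m)
  ctr <- dim(m$labels) * m$spacing / 2
  # symmetric pair about the center
  expect_lt(as.numeric(centroid_distance(rbind(ctr + c(2, 1, 0),
                                               ctr - c(2, 1, 0)), tr)), 0.01)
  # single spot at the boundary pole
  db <- centroid_distance(rbind(ctr + c(4.9, 0, 0)), tr)
  expect_gt(as.numeric(db), 0.95)
  expect_error(centroid_distance(matrix(numeric(0), 0, 3), tr), "empty")
})

test_that("null simulation matches the uniform-ball mean distance for one spot", {
  m <- iso_sphere_mask(radius = 5, n = 48, s = 0.25)
  tr <- normalize_shape(m)
  null1 <- simulate_null(m, 1, n_sim = 500, transform = tr, seed = 4)
  expect_length(null1, 500)
  expect_lt(abs(mean(null1) - 0.75), 0.03)  # E(r)/R = 3/4 for a uniform ball
  # determinism and spot-count effect
  expect_identical(null1, simulate_null(m, 1, 500, tr, seed = 4))
  null24 <- simulate_null(m, 24, n_sim = 300, transform = tr, seed = 5)
  expect_gt(mean(null24), 0)
  expect_lt(mean(null24), mean(null1))
})

test_that("polarity p values follow the calibrated convention", {
  set.seed(8)
  null <- abs(rnorm(500, 0.15, 0.04))
  expect_equal(polarity_pvalue(mean(null), null)$p, 0.5, tolerance = 1e-6)
  # observed far beyond every null value
  expect_lt(polarity_pvalue(mean(null) + 10 * sd(null), null)$p, 1e-6)
  # observed at zero: p close to 1 (null mean is a few sd above zero)
  expect_gt(polarity_pvalue(0, null)$p, 0.98)
  # empirical method brackets the same direction
  expect_lt(polarity_pvalue(max(null) + 1, null, method = "empirical")$p, 0.01)
  expect_error(polarity_pvalue(0.5, rep(0.2, 100)), "zero-variance")
})

test_that("the polarity test is calibrated under the null and powered at lambda 5", {
  masks <- lapply(1:5, function(i) make_nucleus_mask(tiny_spec(70 + i)))
  trs <- lapply(masks, normalize_shape)
  nrep <- 60
  ps <- vapply(seq_len(nrep), function(r) {
    i <- (r - 1) %% 5 + 1
    sc <- sample_spot_centers(masks[[i]], 24, c(1, 1), seed = 900 + r)
    null <- simulate_null(masks[[i]], 24, 300, trs[[i]], seed = 4000 + r)
    polarity_pvalue(centroid_distance(sc$centers, trs[[i]]), null)$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)   # near-nominal type I at this replicate count
  pw <- vapply(seq_len(20), function(r) {
    i <- (r - 1) %% 5 + 1
    sc <- sample_spot_centers(masks[[i]], 24, c(1, 1), polarity_strength = 5,
                              seed = 1900 + r)
    null <- simulate_null(masks[[i]], 24, 300, trs[[i]], seed = 5000 + r)
    polarity_pvalue(centroid_distance(sc$centers, trs[[i]]), null)$p
  }, numeric(1))
  expect_gte(mean(pw < 0.05), 0.8)
})
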