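test_that("all threshold methods isolate the bright phase of a two-valued image", {
  set.seed(5)
  img <- array(10, c(12, 12, 8))
  img[sample(length(img), 300)] <- 200
  for (m in c("otsu", "max_entropy", "rats")) {
    t0 <- compute_threshold(img, m, spacing = c(1, 1, 1))
    expect_gt(t0, 10)
    expect_lte(t0, 200)
    expect_identical(img >= t0, img == 200)
  }
  expect_error(compute_threshold(array(7, c(5, 5, 5)), "otsu",
                                 spacing = c(1, 1, 1)), "degenerate")
})

test_that("maximum-entropy threshold matches a brute-force Kapur scan", {
  set.seed(9)
  img <- array(pmin(255, pmax(0, round(c(rnorm(600, 40, 12),
                                         rnorm(400, 170, 20))))),
               c(10, 10, 10))
  t_pkg <- compute_threshold(img, "max_entropy", spacing = c(1, 1, 1))
  # oracle: scan all 256 candidate cuts, maximize class-entropy sum
  p <- tabulate(as.integer(img) + 1L, 256) / length(img)
  best <- -Inf; kbest <- NA
  for (k in 1:255) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    p0 <- p[1:k] / w0; p1 <- p[(k + 1):256] / w1
    h <- -sum(p0[p0 > 0] * log(p0[p0 > 0])) - sum(p1[p1 > 0] * log(p1[p1 > 0]))
    if (h > best) { best <- h; kbest <- k }
  }
  # same foreground set as the oracle cut (foreground = intensity >= k)
  expect_identical(img >= t_pkg, img >= kbest)
})

test_that("RATS equals the explicit gradient-weighted mean on a sharp sphere", {
  dims <- c(32, 32, 32)
  img <- array(10, dims)
  img[geom_mask(dims, c(1, 1, 1), dims / 2, c(8, 8, 8))] <- 200
  t_pkg <- compute_threshold(img, "rats", spacing = c(1, 1, 1))
  # oracle: central differences, squared gradient magnitude weights
  gx <- gy <- gz <- array(0, dims)
  gx[2:31, , ] <- (img[3:32, , ] - img[1:30, , ]) / 2
  gy[, 2:31, ] <- (img[, 3:32, ] - img[, 1:30, ]) / 2
  gz[, , 2:31] <- (img[, , 3:32] - img[, , 1:30]) / 2
  w <- gx^2 + gy^2 + gz^2
  expect_equal(t_pkg, sum(w * img) / sum(w), tolerance = 1e-10)
  expect_gt(t_pkg, 80); expect_lt(t_pkg, 130)  # straddles the edge
})

test_that("nucleus segmentation recovers phantom volume and separates tiled nuclei", {
  spec <- tiny_spec(21)
  ph <- simulate_phantom(spec)
  nuc <- segment_nuclei(ph$channels$dna, "otsu", min_volume = 50)
  expect_equal(n_labels(nuc), 1L)
  vol_err <- abs(sum(nuc$labels > 0) - sum(ph$mask$labels)) / sum(ph$mask$labels)
  expect_lt(vol_err, 0.05)

  # two nuclei tiled side by side in one field
  two <- array(spec$intensities$background,
               dim = dim(ph$mask$labels) * c(2, 1, 1))
  d <- dim(ph$mask$labels)
  two[1:d[1], , ] <- ph$channels$dna$values
  two[(d[1] + 1):(2 * d[1]), , ] <- ph$channels$dna$values
  nuc2 <- segment_nuclei(two, "otsu", min_volume = 50, spacing = spec$spacing)
  expect_equal(n_labels(nuc2), 2L)
})

test_that("over-truncated components are removed by the border filter", {
  dims <- c(40, 40, 20); sp <- c(0.25, 0.25, 0.37)
  # sphere clipped by the x = 0 face: center on the border
  img <- array(10, dims)
  img[geom_mask(dims, sp, c(0, 5, 3.7), c(3, 3, 3))] <- 200
  expect_warning(
    nuc <- segment_nuclei(img, "otsu", min_volume = 1,
                          max_border_fraction = 0.3, spacing = sp),
    "no component survived")
  expect_equal(n_labels(nuc), 0L)
  # same sphere well inside survives
  img2 <- array(10, dims)
  img2[geom_mask(dims, sp, c(5, 5, 3.7), c(3, 3, 3))] <- 200
  nuc2 <- segment_nuclei(img2, "otsu", min_volume = 1,
                         max_border_fraction = 0.3, spacing = sp)
  expect_equal(n_labels(nuc2), 1L)
})

test_that("watershed splits merged spheres, conserves voxels, and is idempotent", {
  dims <- c(96, 96, 48); sp <- c(0.25, 0.25, 0.37)
  ctr <- dims * sp / 2
  mk <- geom_mask(dims, sp, rbind(ctr + c(-4, 0, 0), ctr + c(4, 0, 0)),
                  rbind(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(n_labels(label_components(mk, sp)), 1L)  # merged
  sw <- split_touching(mk, h = 1, spacing = sp)
  expect_equal(n_labels(sw), 2L)
  expect_equal(sum(sw$labels > 0), sum(mk))  # conservation
  i1 <- sw$labels[nucradial:::coords_to_index(rbind(ctr + c(-4, 0, 0)), dims, sp)]
  i2 <- sw$labels[nucradial:::coords_to_index(rbind(ctr + c(4, 0, 0)), dims, sp)]
  expect_true(i1 != i2 && i1 > 0 && i2 > 0)
  # idempotent and harmless on a single sphere
  sw2 <- split_touching(sw, h = 1)
  expect_identical(sw2$labels, sw$labels)
  single <- geom_mask(dims, sp, ctr, c(5, 5, 5))
  expect_equal(n_labels(split_touching(single, h = 1, spacing = sp)), 1L)
})
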