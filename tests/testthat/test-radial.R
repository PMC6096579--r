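test_that("EVF is bounded, depth-monotone, and follows the ball closed form", {
  m <- iso_sphere_mask(radius = 5, n = 64, s = 0.18)
  ev <- evf_map(m)
  vals <- ev$values[!is.na(ev$values)]
  expect_gte(min(vals), 0)
  expect_lte(max(vals), 1)
  # monotone in depth: deeper voxels never have smaller EVF
  d <- ev$depth[!is.na(ev$depth)]
  o <- order(d)
  expect_true(all(diff(ev$values[!is.na(ev$values)][o]) >= -1e-12))
  # closed form 1 - (r/R)^3 at r = R/2; thin boundary shell stays low
  ctr <- dim(m$labels) * m$spacing / 2
  mid <- spot_evf(ev, cbind(ctr[1] + 2.5, ctr[2], ctr[3]))
  expect_lt(abs(mid - 0.875), 0.02)
  # an outermost-shell voxel
  surf_idx <- which(!is.na(ev$depth) & ev$depth <= min(d) + 1e-9)[1]
  expect_lt(ev$values[surf_idx], 0.2)
})

test_that("EVF of uniform points is uniform for any nuclear shape", {
  shapes <- list(
    sphere = iso_sphere_mask(4, 48, 0.25),
    ellipsoid = make_nucleus_mask(phantom_spec(
      grid_shape = c(72, 48, 26), spacing = c(0.25, 0.25, 0.37),
      nucleus_semiaxes = c(8, 4, 4), deform_amplitude = 0, n_npb = 0)),
    deformed = make_nucleus_mask(tiny_spec(13, deform_amplitude = 0.25)))
  for (nm in names(shapes)) {
    ev <- evf_map(shapes[[nm]])
    idx <- which(!is.na(ev$values))
    set.seed(99)
    s <- sample(idx, 10000, replace = TRUE)
    expect_lte(ks_stat_unif(ev$values[s]), 0.03)
  }
})

test_that("equal-volume fractions have near-equal sizes and linear mean EVF", {
  m <- iso_sphere_mask(4, 48, 0.25)
  ev <- evf_map(m)
  n <- ev$n_voxels
  fr <- equal_volume_fractions(ev, 10)
  sizes <- tabulate(fr[fr > 0], 10)
  expect_lte(diff(range(sizes)), 1)
  means <- tapply(ev$values[fr > 0], fr[fr > 0], mean)
  expect_true(all(diff(means) > 0))
  # oracle: sort-and-chunk of the EVF values
  expected <- tapply(sort(ev$values[fr > 0]),
                     ceiling(seq_len(n) * 10 / n), mean)
  expect_equal(as.numeric(means), as.numeric(expected), tolerance = 1e-12)
  expect_lt(max(abs(means - (seq_len(10) - 0.5) / 10)), 1 / 10)
  # clamping when F exceeds the voxel count
  tiny <- array(FALSE, c(8, 8, 8)); tiny[3:5, 3:5, 3:5] <- TRUE
  evt <- evf_map(tiny, spacing = c(1, 1, 1))
  expect_warning(frt <- equal_volume_fractions(evt, 1000), "clamped")
  expect_equal(max(frt), sum(tiny))
})

test_that("radial profiles behave on constant, concentrated, and biased signals", {
  m <- iso_sphere_mask(4, 48, 0.25)
  ev <- evf_map(m)
  fr <- equal_volume_fractions(ev, 20)
  # constant intensity -> p_k = 1/F up to one voxel
  const <- array(5, dim(m$labels))
  pr <- radial_profile(fr, const, mode = "intensity")
  expect_lte(max(abs(pr$p - 1 / 20)), 1 / ev$n_voxels + 1e-12)
  expect_equal(sum(pr$p), 1, tolerance = 1e-9)
  expect_lte(abs(pr$d_max), 0.02)
  # all signal in the innermost fraction
  inner <- array(0, dim(m$labels)); inner[fr == 20] <- 1
  pri <- radial_profile(fr, inner, mode = "intensity")
  expect_equal(pri$cdf[20], 1)
  expect_true(all(pri$cdf[1:19] == 0))
  expect_equal(pri$d_max, -(19) / 20)
  # center-loaded Beta(5,1) spots dip below the diagonal at the periphery
  sc <- sample_spot_centers(m, 2000, c(5, 1), seed = 17)
  sig <- array(0, dim(m$labels)); sig[sc$index] <- 1
  prb <- radial_profile(fr, sig, mode = "spots")
  expect_true(all(prb$cdf[1:5] < (1:5) / 20))
  expect_lt(prb$d_max, 0)
  # zero signal errors
  expect_error(radial_profile(fr, array(0, dim(m$labels))), "zero")
})

test_that("d_max hand-computed examples and bounds", {
  expect_equal(dmax(c(1, 0, 0, 0)), 0.75)
  expect_equal(dmax(c(0, 0, 0, 1)), -0.75)
  expect_equal(dmax(rep(0.25, 4)), 0)
  # max_signed convention differs for centrally loaded profiles
  expect_equal(dmax(c(0, 0, 0, 1), convention = "max_signed"), 0)
  expect_error(dmax(c(0.5, 0.2)), "sum to 1")
})

test_that("d_max is invariant under axis permutation and uniform rescaling", {
  m <- make_nucleus_mask(tiny_spec(41, deform_amplitude = 0.15))
  sc <- sample_spot_centers(m, 500, c(1, 5), seed = 3)
  sig <- array(0, dim(m$labels)); sig[sc$index] <- 1
  prof <- function(mask_arr, sig_arr, sp) {
    ev <- evf_map(mask_arr, spacing = sp)
    fr <- equal_volume_fractions(ev, 100)
    radial_profile(fr, sig_arr, mode = "spots")$d_max
  }
  d0 <- prof(m$labels, sig, m$spacing)
  # 90 degree rotation in the xy plane (spacing symmetric there)
  d1 <- prof(aperm(m$labels, c(2, 1, 3)), aperm(sig, c(2, 1, 3)),
             m$spacing[c(2, 1, 3)])
  # uniform rescaling of all physical dimensions
  d2 <- prof(m$labels, sig, m$spacing * 3)
  expect_lt(abs(d1 - d0), 0.01)
  expect_lt(abs(d2 - d0), 0.01)
  expect_gt(d0, 0)  # Beta(1,5) is peripheral
  expect_lte(abs(d0), 1)
})

test_that("per-spot EVF recovers generation values and flags outside centroids", {
  m <- make_nucleus_mask(tiny_spec(51))
  ev <- evf_map(m)
  sc <- sample_spot_centers(m, 200, c(1, 1), seed = 5)
  rec <- spot_evf(ev, sc$centers)
  expect_lt(sqrt(mean((rec - sc$evf)^2)), 0.05)
  # nuclear center -> EVF ~ 1; far outside point -> mapped to nearest, flagged
  ctr <- dim(m$labels) * m$spacing / 2
  expect_gte(spot_evf(ev, rbind(ctr))[1], 0.99)
  out <- spot_evf(ev, rbind(c(0.1, 0.1, 0.1)))
  expect_true(attr(out, "outside")[1])
  expect_lte(out[1], 0.05)  # nearest mask voxel is at the boundary
})
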