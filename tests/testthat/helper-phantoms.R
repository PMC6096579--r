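# Shared fixture builders. All fixtures are generated in code; grids are
# kept small so the full suite stays fast.

# small anisotropic embryo-like phantom spec; ... overrides any default
tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(64, 64, 28), spacing = c(0.2, 0.2, 0.37),
         nucleus_semiaxes = c(4.8, 4.2, 3.8), deform_amplitude = 0.1,
         n_npb = 0, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# isotropic sphere mask (radius um) for closed-form radial checks
iso_sphere_mask <- function(radius = 4, n = 48, s = 0.25, seed = 1L) {
  make_nucleus_mask(phantom_spec(grid_shape = c(n, n, n), spacing = c(s, s, s),
                                 nucleus_semiaxes = rep(radius, 3),
                                 deform_amplitude = 0, n_npb = 0,
                                 seed = seed))
}

# explicit geometric ball/ellipsoid union on a grid (fixture oracle,
# independent of make_nucleus_mask)
geom_mask <- function(dims, spacing, centers, semiaxes) {
  x <- (seq_len(dims[1]) - 0.5) * spacing[1]
  y <- (seq_len(dims[2]) - 0.5) * spacing[2]
  z <- (seq_len(dims[3]) - 0.5) * spacing[3]
  X <- array(rep(x, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(y, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  out <- array(FALSE, dims)
  centers <- matrix(centers, ncol = 3)
  semiaxes <- matrix(semiaxes, ncol = 3)
  for (i in seq_len(nrow(centers)))
    out <- out | (((X - centers[i, 1]) / semiaxes[i, 1])^2 +
                  ((Y - centers[i, 2]) / semiaxes[i, 2])^2 +
                  ((Z - centers[i, 3]) / semiaxes[i, 3])^2 <= 1)
  out
}

ks_stat_unif <- function(x) {
  suppressWarnings(unname(stats::ks.test(x, "punif")$statistic))
}
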