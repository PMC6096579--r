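test_that("per-nucleus records assemble volumes and tolerate missing parts", {
  mask <- array(0L, c(20, 20, 10))
  mask[which(array(TRUE, c(20, 20, 10)))[1:1000]] <- 1L
  rec <- measure_nucleus(mask, stage = "2-cell", spacing = c(0.1, 0.1, 0.37))
  expect_equal(rec$nuclear_volume, 1000 * 0.1 * 0.1 * 0.37)
  expect_equal(rec$stage, "2-cell")
  expect_true(is.na(rec$n_npb))

  # with spots but no polarity: polarity fields NA, record still emitted
  spec <- tiny_spec(91)
  ph <- simulate_phantom(spec)
  ss <- segment_spots(denoise_spots(ph$channels$a, 0.15, 1), ph$mask,
                      channel = "a")
  rec2 <- measure_nucleus(ph$mask, spots = list(a = ss), stage = "4-cell")
  expect_equal(rec2$n_spots_a, n_spots(ss))
  expect_true(is.na(rec2$polarity_p_a))
  vol_truth <- sum(ph$mask$labels) * prod(ph$mask$spacing)
  expect_equal(rec2$nuclear_volume, vol_truth)
})

test_that("one-sample t test agrees between raw and summary forms", {
  expect_equal(one_sample_t(c(22, 24, 26), mu0 = 24)$t, 0)
  expect_equal(one_sample_t(c(22, 24, 26), mu0 = 24)$p, 1)
  set.seed(3)
  x <- rnorm(24, 25, 5)
  raw <- one_sample_t(x, mu0 = 24)
  summ <- one_sample_t(mu0 = 24, n = length(x), mean = mean(x), sd = sd(x))
  expect_equal(raw$t, summ$t, tolerance = 1e-10)
  expect_equal(raw$p, summ$p, tolerance = 1e-10)
  expect_error(one_sample_t(rep(5, 10), mu0 = 4), "variance")
})

test_that("spot-count t tests reproduce the published 2-cell stage p values", {
  # channel A: n = 24, 26.17 +/- 5.08 vs the 24 metaphase spots
  pa <- one_sample_t(mu0 = 24, n = 24, mean = 26.17, sd = 5.08)$p
  expect_lt(abs(pa - 0.04788), 0.002)
  # channel B: n = 24, 16.96 +/- 6.10 vs 12
  pb <- one_sample_t(mu0 = 12, n = 24, mean = 16.96, sd = 6.10)$p
  expect_lt(abs(pb - 0.00059), 2e-4)
})

test_that("two-sample KS matches a brute-force CDF-difference oracle", {
  ident <- ks_two_sample(1:10, 1:10)
  expect_equal(ident$D, 0)
  expect_equal(ident$p, 1)
  expect_equal(ks_two_sample(1:5, 101:105)$D, 1)
  set.seed(11)
  a <- rnorm(5); b <- rnorm(5, 1)
  pool <- sort(c(a, b))
  d_oracle <- max(abs(vapply(pool, function(t)
    mean(a <= t) - mean(b <= t), numeric(1))))
  expect_equal(ks_two_sample(a, b)$D, d_oracle, tolerance = 1e-12)
})

test_that("stage linear model recovers coefficients and rejects one level", {
  set.seed(21)
  n <- 30
  stages <- rep(c("2-cell", "4-cell", "8-cell"), each = n)
  covar <- runif(3 * n, 0, 10)
  shift <- ifelse(stages == "4-cell", 2, 0)
  resp <- covar + shift + rnorm(3 * n, 0, 0.1)
  rec <- data.frame(stage = stages, covar = covar, resp = resp)
  ms <- fit_group_model(rec, "resp", "covar")
  est <- setNames(ms$coefficients$estimate, ms$coefficients$term)
  expect_lt(abs(est[["covar"]] - 1), 0.02)
  expect_lt(abs(est[["stage4-cell"]] - 2), 0.15)
  expect_lt(abs(est[["stage8-cell"]]), 0.15)
  expect_true(ms$normality_p > 0.001)
  # pure identity: no stage effect at all
  rec2 <- data.frame(stage = stages, covar = covar, resp = covar)
  ms2 <- suppressWarnings(fit_group_model(rec2, "resp", "covar"))  # exact fit
  est2 <- setNames(ms2$coefficients$estimate, ms2$coefficients$term)
  expect_equal(est2[["covar"]], 1, tolerance = 1e-10)
  expect_lt(max(abs(est2[c("stage4-cell", "stage8-cell")])), 1e-10)
  expect_error(fit_group_model(rec[rec$stage == "2-cell", ], "resp", "covar"),
               "stage levels")
})

test_that("binary-frequency comparison is exact, symmetric, and strict on inputs", {
  ann <- data.frame(stage = rep(c("2-cell", "4-cell"), each = 20),
                    necklace = c(rep(1, 18), rep(0, 2), rep(1, 2), rep(0, 18)))
  r <- compare_binary_frequencies(ann, "necklace", "2-cell", "4-cell")
  expect_lt(r$p, 1e-4)
  # oracle: exact hypergeometric sum over tables no more probable than
  # the observed one (margins 20/20, 20 successes)
  probs <- dhyper(0:20, 20, 20, 20)
  p_oracle <- sum(probs[probs <= probs[18 + 1] * (1 + 1e-7)])
  expect_equal(r$p, p_oracle, tolerance = 1e-10)
  # symmetry in stage order and label flipping
  r2 <- compare_binary_frequencies(ann, "necklace", "4-cell", "2-cell")
  expect_equal(r$p, r2$p)
  ann_flip <- ann; ann_flip$necklace <- 1 - ann_flip$necklace
  expect_equal(compare_binary_frequencies(ann_flip, "necklace", "2-cell",
                                          "4-cell")$p, r$p)
  # identical frequencies are not significant
  ann_same <- data.frame(stage = rep(c("a", "b"), each = 20),
                         agg = rep(c(rep(1, 10), rep(0, 10)), 2))
  expect_equal(compare_binary_frequencies(ann_same, "agg", "a", "b")$p, 1)
  expect_error(compare_binary_frequencies(ann, "missing_param", "2-cell",
                                          "4-cell"), "not found")
})

test_that("stage tables order counts and volumes as generated", {
  # synthetic cohort: stage-dependent nuclear size and spot count
  set.seed(31)
  stages <- c("2-cell", "4-cell", "8-cell")
  recs <- do.call(rbind, lapply(seq_along(stages), function(i)
    data.frame(stage = stages[i],
               nuclear_volume = rnorm(20, 2800 - 600 * (i - 1), 150),
               n_spots_a = round(rnorm(20, 26 - 2 * (i - 1), 3)))))
  tab <- stage_count_table(recs, "n_spots_a", mu0 = 24)
  expect_equal(tab$stage, stages)
  expect_true(all(diff(tab$mean) < 0))
  vols <- tapply(recs$nuclear_volume, recs$stage, mean)[stages]
  expect_true(all(diff(vols) < 0))
})
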