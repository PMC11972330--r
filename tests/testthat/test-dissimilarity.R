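# Per-pair metric behaviour: closed forms, invariances, and agreement with
# the independent oracles in helper-oracles.R.

pd <- function(x, y, metric, ...) profile_distance(x, y, metric, ...)

test_that("euclidean, cid and cor match their closed forms", {
  expect_equal(pd(c(0, 0, 0), c(1, 1, 1), "euclidean"), sqrt(3))
  set.seed(41)
  for (i in 1:10) {
    p <- random_pair(7)
    expect_equal(pd(p$x, p$y, "euclidean"), oracle_euclidean(p$x, p$y),
                 tolerance = 1e-12)
  }
  # CE((0,1,0)) = sqrt(2); equal-complexity pairs reduce cid to euclidean
  x <- c(0, 1, 0); y <- c(1, 0, 1)
  expect_equal(pd(x, y, "cid"), pd(x, y, "euclidean"), tolerance = 1e-9)
  # cor: positive affine relation -> 0; sign flip -> 2; constant -> sqrt(2)
  z <- c(0.1, 0.5, 0.9, 0.2, 0.8)
  tv <- 0:4
  expect_equal(pd(z, 3 * z + 1, "cor", time = tv), 0, tolerance = 1e-7)
  zc <- z - mean(z)
  expect_equal(pd(zc, -zc, "cor", time = tv), 2)
  expect_equal(pd(rep(0.5, 5), z, "cor", time = tv), sqrt(2))
})

test_that("sts compares slopes on the true time grid", {
  expect_equal(pd(c(0, 1), c(0, 0), "sts", time = c(0, 1)), 1)
  z <- c(0, 0.2, 0.9, 1, 0.4, 0.3, 0)
  expect_equal(pd(z, z + 0.37, "sts", time = c(0, 2, 4, 6, 9, 11, 14)), 0)
  set.seed(42)
  tv <- c(0, 2, 4, 6, 9, 11, 14)
  for (i in 1:10) {
    p <- random_pair(7)
    expect_equal(pd(p$x, p$y, "sts", time = tv),
                 oracle_sts(p$x, p$y, tv), tolerance = 1e-12)
  }
})

test_that("dtw matches brute-force path enumeration and its bounds", {
  expect_equal(pd(c(0, 0, 1), c(0, 1, 1), "dtw"), 0)
  set.seed(43)
  for (i in 1:30) {
    t_len <- sample(2:5, 1)
    p <- random_pair(t_len)
    expect_equal(pd(p$x, p$y, "dtw", time = seq_len(t_len) - 1),
                 oracle_dtw(p$x, p$y), tolerance = 1e-12)
    expect_lte(pd(p$x, p$y, "dtw", time = seq_len(t_len) - 1),
               sum(abs(p$x - p$y)) + 1e-12)
  }
})

test_that("tam matches the exhaustive optimal-path oracle with the stated tie-break", {
  z <- c(0.4, 0.1, 0.8, 0.2)
  expect_equal(pd(z, z, "tam"), 0)
  expect_equal(pd(c(0, 1, 0), c(1, 0, 1), "tam"),
               oracle_tam(c(0, 1, 0), c(1, 0, 1)))
  set.seed(44)
  for (i in 1:25) {
    t_len <- sample(3:5, 1)
    p <- random_pair(t_len)
    d <- pd(p$x, p$y, "tam", time = seq_len(t_len) - 1)
    expect_equal(d, oracle_tam(p$x, p$y), tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("acf distance uses the biased estimator and ignores level shifts", {
  tv <- c(0, 2, 4, 6, 9, 11, 14)
  x <- sin(seq(0, 2 * pi, length.out = 7))
  set.seed(45)
  y <- runif(7)
  expect_equal(pd(x, y, "acf", time = tv),
               sqrt(sum((oracle_acf_vec(x, 5) - oracle_acf_vec(y, 5))^2)),
               tolerance = 1e-12)
  expect_equal(pd(x, x + 5, "acf", time = tv), 0, tolerance = 1e-12)
  expect_equal(pd(rep(1, 7), rep(2, 7), "acf", time = tv), 0)
})

test_that("fourier distance obeys the DC and Parseval identities", {
  set.seed(46)
  p <- random_pair(7)
  full <- metric_params(fourier_n_coef = 7L)
  expect_equal(pd(p$x, p$y, "fourier", params = full),
               sqrt(7) * pd(p$x, p$y, "euclidean"), tolerance = 1e-9)
  dc <- metric_params(fourier_n_coef = 1L)
  expect_equal(pd(p$x, p$y, "fourier", params = dc),
               abs(sum(p$x) - sum(p$y)), tolerance = 1e-12)
})

test_that("periodogram distances match the direct DFT oracle", {
  set.seed(47)
  p <- random_pair(7)
  tv <- c(0, 2, 4, 6, 9, 11, 14)
  expect_equal(pd(p$x, p$y, "per", time = tv), oracle_per(p$x, p$y, 3),
               tolerance = 1e-12)
  expect_equal(pd(p$x, p$x + 0.4, "per", time = tv), 0, tolerance = 1e-12)
  # int.per: cumulative spectra are distributions; constants use the ramp
  expect_equal(pd(rep(0.2, 7), rep(0.9, 7), "int.per", time = tv), 0)
  Px <- oracle_periodogram(p$x, 3)
  Fx <- cumsum(Px) / sum(Px)
  expect_true(all(diff(Fx) >= -1e-15) && abs(Fx[3] - 1) < 1e-12)
  Py <- oracle_periodogram(p$y, 3)
  expect_equal(pd(p$x, p$y, "int.per", time = tv),
               sum(abs(Fx - cumsum(Py) / sum(Py))), tolerance = 1e-12)
})

test_that("cdm quantizes to the declared bins and is symmetric and deterministic", {
  q <- tempodiff:::quantize_series
  expect_identical(as.integer(q(c(0, 1), 8L)), c(0L, 7L))
  expect_identical(as.integer(q(c(0.124, 0.126), 8L)), c(0L, 1L))
  set.seed(48)
  p <- random_pair(7)
  d1 <- pd(p$x, p$y, "cdm")
  expect_identical(d1, pd(p$y, p$x, "cdm"))
  expect_identical(d1, pd(p$x, p$y, "cdm"))
  expect_gt(d1, 0)
  # deflate option also runs
  expect_true(is.finite(pd(p$x, p$y, "cdm",
                           params = metric_params(cdm_compressor = "deflate"))))
})

test_that("frechet matches exhaustive couplings and respects its bounds", {
  grid <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  set.seed(49)
  take <- grid[sample(nrow(grid), 8), ]
  for (i in seq_len(nrow(take))) for (j in seq_len(nrow(take))) {
    x <- as.numeric(take[i, ]) / 2
    y <- as.numeric(take[j, ]) / 2
    d <- pd(x, y, "frechet")
    expect_equal(d, oracle_frechet(x, y), tolerance = 1e-12)
    expect_gte(d, max(abs(x[1] - y[1]), abs(x[3] - y[3])) - 1e-12)
    expect_lte(d, max(abs(x - y)) + 1e-12)
  }
  # the 2-D embedding includes the time axis in the ground cost
  p <- random_pair(4)
  d2 <- pd(p$x, p$y, "frechet", time = c(0, 2, 4, 6),
           params = metric_params(frechet_embedding = "time_value"))
  expect_gte(d2, pd(p$x, p$y, "frechet", time = c(0, 2, 4, 6)))
})

test_that("all metrics are symmetric, non-negative, and zero at identity (cdm excepted)", {
  set.seed(50)
  tv <- c(0, 2, 4, 6, 9, 11, 14)
  for (i in 1:20) {
    p <- random_pair(7)
    for (mm in tempo_metrics()) {
      d <- pd(p$x, p$y, mm, time = tv)
      expect_gte(d, 0)
      expect_equal(d, pd(p$y, p$x, mm, time = tv), tolerance = 1e-12)
      if (mm != "cdm")
        expect_equal(pd(p$x, p$x, mm, time = tv), 0, tolerance = 1e-12)
    }
  }
})

test_that("vectorized distance tables agree with the per-pair interface", {
  set.seed(51)
  sim <- simulate_timecourse(sim_config(
    n_genes = 60, n_differential = 10, emission = "expression", seed = 6))
  pairs <- scale_profile_pairs(filter_by_variance(
    build_profile_pairs(sim$expression, sim$sample_sheet)))
  d <- suppressMessages(compute_distances(pairs))
  tv <- attr(pairs, "time_vector")
  idx <- sample(nrow(pairs), 8)
  for (g in idx) for (mm in tempo_metrics()) {
    expect_equal(d[[mm]][match(pairs$gene_id[g], d$gene_id)],
                 pd(pairs$wt[g, ], pairs$ko[g, ], mm, time = tv),
                 tolerance = 1e-12)
  }
  expect_false(any(is.na(as.matrix(d[, -1]))))
})

test_that("unknown metric names and bad inputs are rejected", {
  expect_error(profile_distance(1:3, 1:3, "mahalanobis"),
               regexp = "euclidean", class = "tempodiff_config_error")
  expect_error(profile_distance(c(0, NA, 1), c(0, 1, 1), "euclidean"),
               class = "tempodiff_data_error")
  expect_error(profile_distance(1:3, 1:4, "euclidean"),
               class = "tempodiff_data_error")
})
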