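toy_counts <- function() {
  tibble::tibble(gene_id = c("a", "b"), s1 = c(10, 20), s2 = c(5, 5))
}
toy_lengths <- function() {
  tibble::tibble(gene_id = c("a", "b"), length_bp = c(1000, 2000))
}

test_that("TPM normalization matches hand arithmetic and its invariances", {
  tpm <- counts_to_tpm(toy_counts(), toy_lengths())
  # rates 10/1 and 20/2 are equal, so both genes get half the million
  expect_equal(tpm$s1, c(5e5, 5e5))

  one <- counts_to_tpm(tibble::tibble(gene_id = "a", s1 = 7),
                       toy_lengths()[1, ])
  expect_equal(one$s1, 1e6)

  doubled <- toy_counts()
  doubled$s1 <- doubled$s1 * 2
  expect_equal(counts_to_tpm(doubled, toy_lengths())$s1, tpm$s1)

  set.seed(1)
  big <- tibble::tibble(gene_id = sprintf("g%d", 1:50),
                        s1 = rpois(50, 100) + 1, s2 = rpois(50, 10) + 1)
  lens <- tibble::tibble(gene_id = big$gene_id,
                         length_bp = sample(500:5000, 50))
  cs <- colSums(counts_to_tpm(big, lens)[, -1])
  expect_equal(unname(cs), rep(1e6, 2), tolerance = 1e-6)
})

test_that("TPM normalization rejects bad lengths and empty samples", {
  expect_error(counts_to_tpm(toy_counts(), toy_lengths()[1, ]),
               class = "tempodiff_data_error")
  bad_len <- toy_lengths(); bad_len$length_bp[1] <- 0
  expect_error(counts_to_tpm(toy_counts(), bad_len),
               class = "tempodiff_data_error")
  zero <- toy_counts(); zero$s2 <- c(0, 0)
  expect_error(counts_to_tpm(zero, toy_lengths()), regexp = "s2",
               class = "tempodiff_data_error")
})

test_that("log transform is log2(x + 1) and rejects negatives", {
  x <- tibble::tibble(gene_id = c("a", "b", "c"), s1 = c(0, 1, 7))
  expect_equal(log_tpm(x)$s1, c(0, 1, 3))
  x$s1[1] <- -1
  expect_error(log_tpm(x), class = "tempodiff_data_error")
})

# 2 genes x (2 conditions x 2 timepoints x 2 replicates)
mini_expr <- function(values) {
  sheet <- tibble::tibble(
    sample_id = c("w1a", "w1b", "w2a", "w2b", "k1a", "k1b", "k2a", "k2b"),
    condition = rep(c("WT", "KO"), each = 4),
    timepoint = rep(c(0, 0, 5, 5), 2),
    replicate = rep(c(1, 2), 4))
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = c("g1", "g2")),
                           tibble::as_tibble(as.data.frame(values)))
  names(expr)[-1] <- sheet$sample_id
  list(expr = expr, sheet = sheet)
}

test_that("profile pairs aggregate replicates and compute pooled variance", {
  vals <- rbind(c(1, 3, 5, 7, 2, 2, 6, 6),   # means: WT (2,6), KO (2,6)
                c(4, 4, 4, 4, 4, 4, 4, 4))   # constant
  d <- mini_expr(vals)
  pairs <- build_profile_pairs(d$expr, d$sheet)
  expect_equal(unname(pairs$wt[1, ]), c(2, 6))
  expect_equal(unname(pairs$ko[1, ]), c(2, 6))
  expect_equal(pairs$variance[1], var(c(2, 6, 2, 6)))
  expect_equal(unname(pairs$wt[2, ]), c(4, 4))
  expect_equal(pairs$variance[2], 0)
  expect_equal(attr(pairs, "time_vector"), c(0, 5))

  med <- build_profile_pairs(d$expr, d$sheet, aggregate = "median")
  expect_equal(unname(med$wt[1, ]), c(2, 6))
})

test_that("a timepoint observed in one condition only is a design error", {
  d <- mini_expr(rbind(1:8, 1:8))
  d$sheet$timepoint[d$sheet$sample_id %in% c("k2a", "k2b")] <- 9
  expect_error(build_profile_pairs(d$expr, d$sheet),
               class = "tempodiff_design_error")
})

test_that("variance filtering is strict and matches the direct formula", {
  # pooled values (0, ..., 0, 1) over 14 slots: sample variance is
  # ((1 - 1/14)^2 + 13 * (1/14)^2) / 13 = 1/14 < 0.1 -> removed
  sheet <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:14),
    condition = rep(c("WT", "KO"), each = 7),
    timepoint = rep(0:6, 2),
    replicate = 1)
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = "g1"),
    tibble::as_tibble(as.data.frame(matrix(c(rep(0, 13), 1), 1))))
  names(expr)[-1] <- sheet$sample_id
  pairs <- build_profile_pairs(expr, sheet)
  expect_equal(pairs$variance, 1 / 14)
  expect_identical(nrow(filter_by_variance(pairs, 0.1)), 0L)
  expect_identical(nrow(filter_by_variance(pairs, 0)), 1L)
  expect_identical(nrow(filter_by_variance(pairs, -Inf)), 1L)
  expect_identical(nrow(filter_by_variance(pairs, Inf)), 0L)
  # strictness at the boundary
  expect_identical(nrow(filter_by_variance(pairs, 1 / 14)), 0L)
})

test_that("joint minmax scaling matches hand arithmetic and is exact at the extrema", {
  d <- mini_expr(rbind(c(0, 0, 1, 1, 2, 2, 3, 3),
                       c(5, 5, 5, 5, 5, 5, 5, 5)))
  pairs <- build_profile_pairs(d$expr, d$sheet)
  scaled <- scale_profile_pairs(pairs)
  # wt = (0, 1), ko = (2, 3), pooled range 0..3
  expect_equal(unname(scaled$wt[1, ]), c(0, 1 / 3))
  expect_equal(unname(scaled$ko[1, ]), c(2 / 3, 1))
  expect_identical(min(scaled$wt[1, ], scaled$ko[1, ]), 0)
  expect_identical(max(scaled$wt[1, ], scaled$ko[1, ]), 1)
  expect_equal(scaled$e_min[1], 0)
  expect_equal(scaled$e_max[1], 3)
  # constant pair: degenerate, zeroed, not scaled to NaN
  expect_true(scaled$degenerate[2])
  expect_true(all(scaled$wt[2, ] == 0) && all(scaled$ko[2, ] == 0))
  expect_error(scale_profile_pairs(scaled),
               class = "tempodiff_config_error")
})

test_that("scaling removes joint positive affine transforms", {
  d <- mini_expr(rbind(c(0.3, 0.5, 1.2, 1.0, 0.8, 0.6, 2.0, 1.8),
                       c(1, 2, 3, 4, 5, 6, 7, 8)))
  base <- scale_profile_pairs(build_profile_pairs(d$expr, d$sheet))
  shifted <- mini_expr(2.5 * rbind(c(0.3, 0.5, 1.2, 1.0, 0.8, 0.6, 2.0, 1.8),
                                   c(1, 2, 3, 4, 5, 6, 7, 8)) + 7)
  aff <- scale_profile_pairs(build_profile_pairs(shifted$expr, shifted$sheet))
  expect_equal(aff$wt, base$wt)
  expect_equal(aff$ko, base$ko)
  # a pair already spanning [0, 1] is unchanged
  again <- scale_profile_pairs(restore_canonical <- build_profile_pairs(
    mini_expr(rbind(c(0, 0, 1, 1, 0.25, 0.25, 0.5, 0.5),
                    c(0, 0, 1, 1, 1, 1, 0, 0)))$expr,
    mini_expr(rbind(1:8, 1:8))$sheet))
  expect_equal(unname(again$wt[1, ]), c(0, 1))
  expect_equal(unname(again$ko[1, ]), c(0.25, 0.5))
})
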