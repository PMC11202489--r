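test_that("dispersion estimates recover the generating model", {
  d <- make_design()
  pois <- simulate_counts(d, 500, baseline_mean = 100, dispersion = 1e-13,
                          seed = 51)
  phi_pois <- estimate_dispersion(pois, d)
  expect_lt(median(phi_pois), 0.02)

  nb <- simulate_counts(d, 500, baseline_mean = 100, dispersion = 0.2,
                        seed = 52)
  phi_nb <- estimate_dispersion(nb, d)
  expect_gt(median(phi_nb), 0.1)
  expect_lt(median(phi_nb), 0.3)

  const <- matrix(5L, 3, 13, dimnames = list(paste0("f", 1:3), d$sample))
  raw <- estimate_dispersion(const, d, shrink = 0)
  expect_equal(unname(raw), rep(0, 3))
  expect_error(estimate_dispersion(pois, make_design()[-(1:2), ]))
})

test_that("the exact NB test behaves at its boundary cases", {
  expect_equal(nb_test(c(5, 5, 5), c(5, 5, 5), 0.1), 1)
  expect_equal(nb_test(c(0, 0, 0), c(0, 0, 0), 0.1), 1)
  # Strong planted signal at depth 100, 3 vs 3: significant for >= 90%
  # of simulated features.
  set.seed(53)
  p <- replicate(200, {
    a <- rnbinom(3, mu = 800, size = 10)
    b <- rnbinom(3, mu = 100, size = 10)
    nb_test(a, b, 0.1)
  })
  expect_gte(mean(p < 0.05), 0.9)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(54)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # Permutation invariance.
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("status classification applies the fold and significance rules", {
  expect_equal(classify_de(5.91, 0.001, 0.001), "up")
  expect_equal(classify_de(-6.51, 0.001, 0.001), "down")
  expect_equal(classify_de(0.5, 0.001, 0.001), "ns")
  expect_equal(classify_de(2, 0.2, 0.4), "ns")
  # fdr mode is strict at the threshold, pvalue mode is not.
  expect_equal(classify_de(2, 0.01, 0.05, mode = "fdr"), "ns")
  expect_equal(classify_de(2, 0.05, 0.5, mode = "pvalue"), "up")
  # The fold cutoff reads as |log2FC| > 1: exactly 1 is not enough.
  expect_equal(classify_de(1, 1e-8, 1e-8), "ns")
})

test_that("de_test recovers planted direction and keeps nulls quiet", {
  d <- make_design()
  tr <- data.frame(feature = sprintf("feat_%04d", 1:40),
                   comparison = "LB_vs_PK", log2fc = rep(c(3, -3), 20))
  m <- simulate_counts(d, 400, truth = tr, baseline_mean = 100,
                       dispersion = 0.1, seed = 55)
  res <- de_test(m, d, c("LB", "PK"))
  planted <- res[match(tr$feature, res$feature), ]
  expect_true(all(planted$status[tr$log2fc > 0] == "up"))
  expect_true(all(planted$status[tr$log2fc < 0] == "down"))
  nulls <- res[-match(tr$feature, res$feature), ]
  expect_lt(mean(nulls$status != "ns"), 0.02)
  # FDR column is a valid BH adjustment of the p column.
  expect_equal(res$fdr, bh_oracle(res$p))
  # Sign of the fold change matches the sign of the mean difference.
  norm <- cernet:::normalize_counts(m, d)
  diffs <- rowMeans(norm[, paste0("LB", 1:3)]) -
    rowMeans(norm[, paste0("PK", 1:3)])
  expect_true(all(sign(res$log2fc[res$log2fc != 0]) ==
                    sign(diffs[res$log2fc != 0])))
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  d <- make_design()
  m <- simulate_counts(d, 300, baseline_mean = 200, dispersion = 0.1,
                       seed = 56)
  ours <- cernet:::size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})
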