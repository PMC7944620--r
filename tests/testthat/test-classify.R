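test_that("within-triad normalization and the modification filter", {
  expect_equal(unname(normalize_triad(3, 1)[1, ]), c(0.75, 0.25))
  expect_equal(unname(normalize_triad(2.5, 2.5)[1, ]), c(0.5, 0.5))
  expect_true(all(is.na(normalize_triad(0, 0))))

  expect_true(is_modified(0.6, 0.1))
  expect_false(is_modified(0.5, 0.5))   # threshold is strict
  expect_true(is_modified(0, 0.51))
  expect_false(is_modified(0.4, 0.4))
})

test_that("nearest-anchor classification reproduces hand-computed distances", {
  expect_equal(classify_bias(0.5, 0.5)$category, "A_eq_B")
  expect_equal(classify_bias(0.5, 0.5)$d_eq, 0)
  expect_equal(classify_bias(1, 0)$category, "A_gt_B")
  expect_equal(classify_bias(1, 0)$d_gt, 0)
  expect_equal(classify_bias(0, 1)$category, "A_lt_B")

  cl <- classify_bias(0.8, 0.2)
  expect_equal(cl$category, "A_gt_B")
  expect_equal(c(cl$d_eq, cl$d_gt, cl$d_lt),
               sqrt(c(0.18, 0.08, 1.28)), tolerance = 1e-12)
  expect_equal(c(cl$d_eq, cl$d_gt, cl$d_lt),
               c(0.42426, 0.28284, 1.13137), tolerance = 1e-4)

  # exact equidistance at rel_A = 0.75 resolves to the balanced category
  tie <- classify_bias(0.75, 0.25)
  expect_equal(tie$category, "A_eq_B")
  expect_equal(tie$d_eq, tie$d_gt, tolerance = 1e-12)
  expect_equal(tie$d_eq, 0.35355, tolerance = 1e-4)
  expect_equal(classify_bias(0.25, 0.75)$category, "A_eq_B")

  expect_error(classify_bias(0.6, 0.6), "equal 1")
})

test_that("classification matches a brute-force oracle on a fine grid", {
  rel_A <- seq(0, 1, by = 1e-3)
  got <- classify_bias(rel_A, 1 - rel_A)$category
  # independent oracle: explicit distance minimum with the same tie rule
  anchors <- list(A_eq_B = c(0.5, 0.5), A_gt_B = c(1, 0), A_lt_B = c(0, 1))
  oracle <- vapply(rel_A, function(a) {
    d <- vapply(anchors, function(an)
      sqrt((a - an[1])^2 + ((1 - a) - an[2])^2), 0)
    names(d)[d <= min(d) + 1e-12][1]
  }, "")
  expect_identical(got, unname(oracle))
  # closed-form boundary: biased exactly when |rel_A - 0.5| > 0.25
  expect_identical(got == "A_eq_B", abs(rel_A - 0.5) <= 0.25 + 1e-15)
})

test_that("category is scale-invariant but the filter is not; A/B symmetry", {
  set.seed(5)
  a <- runif(50, 0.1, 60); b <- runif(50, 0.1, 60)
  base_cat <- classify_bias(a / (a + b), b / (a + b))$category
  for (k in c(0.01, 1, 250)) {
    rel <- normalize_triad(k * a, k * b)
    expect_identical(classify_bias(rel[, 1], rel[, 2])$category, base_cat)
  }
  # the absolute filter is not scale-invariant
  expect_true(is_modified(0.6, 0.1))
  expect_false(is_modified(0.6 * 0.1, 0.1 * 0.1))
  # swapping A and B swaps the biased categories and keeps balance
  swapped <- classify_bias(b / (a + b), a / (a + b))$category
  map <- c(A_eq_B = "A_eq_B", A_gt_B = "A_lt_B", A_lt_B = "A_gt_B")
  expect_identical(swapped, unname(map[base_cat]))
})

test_that("dataset classification recovers planted categories and summaries", {
  # noiseless planted recovery with known proportions
  cfg <- sim_config(500, genotypes = "WTW", assays = "H3K4me3",
                    category_props = list(H3K4me3 = c(
                      A_eq_B = 0.9, A_gt_B = 0.06, A_lt_B = 0.04,
                      unmodified = 0)),
                    dispersion = c(H3K4me3 = Inf), seed = 2)
  sim <- simulate_dataset(cfg)
  calls <- classify_dataset(signal_matrix_from_sim(sim), sim$triads)
  s <- summary(calls)
  expect_equal(s$n_modified, 500L)
  expect_equal(c(s$pct_eq, s$pct_gt, s$pct_lt), c(90, 6, 4))
  merged <- merge(as.data.frame(calls), sim$truth,
                  by = c("triad_id", "genotype", "assay"))
  expect_identical(merged$category.x, merged$category.y)

  # all triads below the filter: no categories at all
  tt <- toy_triads(2L)
  tpm <- matrix(0.2, nrow = 6, ncol = 1,
                dimnames = list(tt$genes$gene_id, "WTW.H3K4me3"))
  agg <- toy_aggregated(tpm, "WTW", "H3K4me3")
  low <- classify_dataset(agg, tt)
  expect_true(all(low$category == "unmodified"))
  expect_equal(summary(low)$n_modified, 0L)
})

test_that("union denominators count triads modified in any genotype", {
  tt <- toy_triads(3L)
  mk <- function(vals) matrix(vals, nrow = 9,
                              dimnames = list(tt$genes$gene_id, NULL))
  # t1 modified in WTW only, t2 in DTW only, t3 nowhere
  tpm <- cbind(WTW = c(5, 0, 0, 5, 0, 0, 0, 0, 0),
               DTW = c(0, 5, 0, 0, 5, 0, 0, 0, 0))
  rownames(tpm) <- tt$genes$gene_id
  colnames(tpm) <- c("WTW.H3K4me3", "DTW.H3K4me3")
  agg <- toy_aggregated(tpm, c("WTW", "DTW"), c("H3K4me3", "H3K4me3"))
  calls <- classify_dataset(agg, tt)
  u <- modified_union(calls)
  expect_equal(u$n_modified_union, 2L)
  expect_equal(u$pct_modified_union, 100 * 2 / 3)
  u1 <- modified_union(calls, genotypes = "WTW")
  expect_equal(u1$n_modified_union, 1L)
})
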