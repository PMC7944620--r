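test_that("configuration validates its invariants", {
  expect_error(sim_config(0), "n_triads")
  expect_error(sim_config(10, epsilon = 0.6), "epsilon")
  expect_error(sim_config(10, category_props = list(
    H3K4me3 = c(A_eq_B = 0.5, A_gt_B = 0.2, A_lt_B = 0.2,
                unmodified = 0.2))), "sum to 1")
  expect_error(sim_config(10, dispersion = c(H3K4me3 = -1)), "dispersion")
})

test_that("largest-remainder apportionment plants exact frequencies", {
  rm_ <- triadtrack:::round_multinomial
  expect_equal(rm_(10, c(0.7, 0.1, 0.1, 0.1)), c(7L, 1L, 1L, 1L))
  expect_equal(rm_(7, c(0.5, 0.5)), c(4L, 3L))      # remainder to first
  expect_equal(sum(rm_(113, c(0.883, 0.048, 0.033, 0.036))), 113L)
  set.seed(6)
  for (i in 1:10) {
    p <- as.vector(rmultinom(1, 50, runif(4))) / 50
    k <- rm_(1000, p)
    expect_equal(sum(k), 1000L)
    expect_true(all(abs(k - 1000 * p) < 1))
  }
})

test_that("identical seeds reproduce the dataset byte for byte", {
  cfg <- sim_config(60, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  sums1 <- tools::md5sum(file.path(d1, f1))
  sums2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(sums1), unname(sums2))
  # a different seed changes the counts
  cfg2 <- cfg; cfg2$seed <- 8L
  s3 <- simulate_dataset(cfg2)
  expect_false(identical(s3$counts, simulate_dataset(cfg)$counts))
})

test_that("noiseless planted biases are recovered perfectly", {
  cfg <- sim_config(100, genotypes = "WTW", assays = "H3K4me3",
                    category_props = list(H3K4me3 = c(
                      A_eq_B = 0, A_gt_B = 1, A_lt_B = 0, unmodified = 0)),
                    dispersion = c(H3K4me3 = Inf), seed = 13)
  sim <- simulate_dataset(cfg)
  calls <- classify_dataset(signal_matrix_from_sim(sim), sim$triads)
  expect_equal(sum(calls$category == "A_gt_B"), 100L)
})

test_that("replicate TPM correlation matches the dispersion model", {
  # Monte-Carlo oracle values frozen in advance: linear-TPM replicate r is
  # bounded by phi/(phi+1), about 0.90 at phi = 10 and above 0.95 at
  # phi = 30 under the default log-normal signal spread.
  cfg <- sim_config(2000, genotypes = "WTW", assays = "H3K4me3", mu = 50,
                    dispersion = c(H3K4me3 = 10), seed = 21)
  r10 <- replicate_correlation(
    signal_matrix_from_sim(simulate_dataset(cfg)))$r
  expect_gt(r10, 0.85); expect_lt(r10, 0.95)
  cfg$dispersion <- c(H3K4me3 = 30)
  r30 <- replicate_correlation(
    signal_matrix_from_sim(simulate_dataset(cfg)))$r
  expect_gt(r30, 0.95)
  expect_gt(r30, r10)   # recovery improves with lower dispersion
})

test_that("planted series labels realize requested frequencies exactly", {
  # all conserved
  s1 <- simulate_series(sim_config(50, assays = "H3K4me3", seed = 4),
                        c(1, 0, 0, 0), "domestication")
  tr <- s1$truth
  wide <- split(tr$category, tr$genotype)
  expect_identical(wide$WTW, wide$DTW)
  expect_identical(wide$DTW, wide$ETW)

  # pure Group II: change at the second genotype, maintained at the third
  s2 <- simulate_series(sim_config(50, assays = "H3K4me3",
                                   category_props = list(H3K4me3 = c(
                                     A_eq_B = 0.8, A_gt_B = 0.1,
                                     A_lt_B = 0.1, unmodified = 0)),
                                   seed = 4),
                        c(0, 1, 0, 0), "domestication")
  w <- split(s2$truth$category, s2$truth$genotype)
  expect_true(all(w$WTW != w$DTW))
  expect_identical(w$DTW, w$ETW)

  # frequency recovery through the full pipeline, noiseless
  cfg <- sim_config(1000, assays = "H3K4me3",
                    dispersion = c(H3K4me3 = Inf), seed = 19)
  s3 <- simulate_series(cfg, c(0.7, 0.1, 0.1, 0.1), "domestication")
  calls <- classify_dataset(signal_matrix_from_sim(s3), s3$triads)
  tracks <- track_series(calls, "domestication")
  tab <- tabulate_tracks(tracks)
  expect_equal(tab$proportion, c(0.7, 0.1, 0.1, 0.1), tolerance = 1e-12)
  expect_error(simulate_series(cfg, c(0.5, 0.5)), "length 4")
  expect_error(simulate_series(cfg, c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("recovery degrades monotonically with dispersion", {
  rate <- sapply(c(Inf, 30, 3), function(phi) {
    cfg <- sim_config(400, genotypes = "WTW", assays = "H3K4me3",
                      dispersion = c(H3K4me3 = phi), seed = 17)
    sim <- simulate_dataset(cfg)
    calls <- classify_dataset(signal_matrix_from_sim(sim), sim$triads)
    m <- merge(as.data.frame(calls), sim$truth,
               by = c("triad_id", "genotype", "assay"))
    mean(m$category.x == m$category.y)
  })
  expect_equal(rate[1], 1)                  # noiseless is perfect
  expect_true(all(diff(rate) <= 0.01))      # non-increasing (small slack)
})

test_that("hexaploid genotypes emit D signal, tetraploids none", {
  cfg <- sim_config(80, genotypes = c("ETW", "TAA10", "AeTauschii"),
                    assays = "H3K4me3", seed = 23)
  sim <- simulate_dataset(cfg)
  sh <- subgenome_share(signal_matrix_from_sim(sim), sim$triads)
  sh <- sh[match(c("ETW_H3K4me3_r1", "TAA10_H3K4me3_r1",
                   "AeTauschii_H3K4me3_r1"), sh$sample_id), ]
  expect_equal(sh$D[1], 0)                       # tetraploid: no D reads
  expect_true(sh$D[2] > 0.2 && sh$D[2] < 0.5)    # hexaploid: D present
  expect_equal(sh$A[3] + sh$B[3], 0)             # DD diploid: D only
  expect_equal(sh$D[3], 1)
})
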