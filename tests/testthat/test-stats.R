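test_that("exact binomial asymmetry test matches closed forms and base R", {
  expect_equal(binom_asymmetry(10, 0)$p.value, 2 * 0.5^10)  # 0.001953125
  expect_equal(binom_asymmetry(5, 5)$p.value, 1)
  # brute-force: sum over the 11 outcomes of Binomial(10, 0.5) no more
  # likely than k = 7
  d <- dbinom(0:10, 10, 0.5)
  expect_equal(binom_asymmetry(7, 3)$p.value, sum(d[d <= d[8]]))
  expect_equal(binom_asymmetry(7, 3)$p.value, 0.34375)
  expect_error(binom_asymmetry(0, 0), "no biased triads")
  # symmetry and agreement with stats::binom.test on random cases
  set.seed(30)
  for (i in 1:20) {
    a <- rpois(1, 40); b <- rpois(1, 25)
    if (a + b == 0) next
    expect_equal(binom_asymmetry(a, b)$p.value,
                 binom_asymmetry(b, a)$p.value)
    expect_equal(binom_asymmetry(a, b)$p.value,
                 binom.test(a, a + b, 0.5)$p.value, tolerance = 1e-12)
  }
})

test_that("two-proportion test matches its closed form and prop.test", {
  r <- two_proportion_test(50, 100, 50, 100)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # hand-computed Yates chi-square
  expect_equal(two_proportion_test(30, 100, 10, 100)$statistic,
               (abs(0.3 - 0.1) - 0.01)^2 / (0.2 * 0.8 * 0.02))
  expect_equal(two_proportion_test(30, 100, 10, 100)$statistic, 11.28125)
  expect_warning(deg <- two_proportion_test(0, 10, 0, 10), "undefined")
  expect_equal(deg$p.value, 1)
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- rbinom(1, n1, 0.4); x2 <- rbinom(1, n2, 0.5)
    if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
    ours <- two_proportion_test(x1, n1, x2, n2)
    ref <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2)))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    # correction off equals the squared pooled z statistic
    p1 <- x1 / n1; p2 <- x2 / n2; pb <- (x1 + x2) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
    expect_equal(two_proportion_test(x1, n1, x2, n2, correct = FALSE)$statistic,
                 z^2, tolerance = 1e-12)
  }
})

test_that("Wilcoxon rank-sum: exact enumeration, ties and approximation", {
  r <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 0.1)          # 2/20 rank assignments
  expect_equal(wilcoxon_rank_sum(c(1, 2), 3)$p.value, 2 / 3)
  same <- wilcoxon_rank_sum(rep(c(1, 2, 3), 5), rep(c(1, 2, 3), 5))
  expect_gte(same$p.value, 0.99)        # no shift, approximate path
  expect_equal(wilcoxon_rank_sum(rep(1, 4), rep(1, 4))$p.value, 1)

  # exact path equals the enumeration oracle (= base wilcox.test exact)
  set.seed(32)
  for (i in 1:15) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- sample(1:100, n1); y <- sample(setdiff(1:100, x), n2)
    ours <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  # approximate path is close to exact at n = 12 without ties
  for (i in 1:10) {
    x <- sample(1:1000, 6); y <- sample(setdiff(1:1000, x), 6)
    exact_p <- wilcoxon_rank_sum(x, y, exact_threshold = 20)$p.value
    approx_p <- wilcoxon_rank_sum(x, y, exact_threshold = 0)$p.value
    expect_lte(abs(exact_p - approx_p), 0.02)
  }
  # tie-corrected approximation agrees with base R's corrected test
  x <- c(1, 2, 2, 3, 5, 5, 5, 8); y <- c(2, 3, 3, 4, 5, 9, 9, 10)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  ours <- wilcoxon_rank_sum(x, y)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("Pearson correlation matches hand computation", {
  expect_equal(pearson_r(1:4, 2 * (1:4))$statistic, 1)
  expect_equal(pearson_r(1:4, -(1:4))$statistic, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))$statistic, 0.6)
  expect_error(pearson_r(1:4, rep(2, 4)), "zero variance")
  set.seed(33)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pearson_r(x, y)$statistic, cor(x, y), tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(34)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q <= 1) && all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p-order
  }
})

test_that("hypergeometric enrichment matches closed forms and phyper", {
  ann <- data.frame(
    gene_id = c(sprintf("g%d", 1:5), sprintf("g%d", 1:20)),
    term_id = c(rep("T1", 5), rep("T2", 20)), stringsAsFactors = FALSE)
  # selection == the whole term universe: nothing can be enriched
  res_all <- hypergeom_enrichment(sprintf("g%d", 1:20), ann)
  expect_true(all(res_all$p == 1))
  # selecting exactly the 5-gene term out of 20: p = 1 / C(20,5)
  res <- hypergeom_enrichment(sprintf("g%d", 1:5), ann)
  expect_equal(res$p[res$term_id == "T1"], 1 / choose(20, 5))
  expect_equal(res$p[res$term_id == "T1"], 6.4499e-5, tolerance = 1e-4)
  expect_error(hypergeom_enrichment(character(0), ann), "empty selection")
  expect_error(hypergeom_enrichment("gX", ann), "outside the universe")
  # agreement with stats::phyper on random configurations
  set.seed(35)
  genes <- sprintf("g%d", 1:200)
  ann2 <- data.frame(gene_id = sample(genes, 400, replace = TRUE),
                     term_id = sample(sprintf("T%d", 1:8), 400, TRUE))
  ann2 <- unique(ann2)
  sel <- sample(genes, 40)
  res2 <- hypergeom_enrichment(sel, ann2, universe = genes)
  for (i in seq_len(nrow(res2)))
    expect_equal(res2$p[i],
                 phyper(res2$k[i] - 1, res2$K[i], res2$N[i] - res2$K[i],
                        res2$n[i], lower.tail = FALSE),
                 tolerance = 1e-10)
  expect_equal(res2$q, p.adjust(res2$p, "BH"), tolerance = 1e-12)
})

test_that("modification-level comparisons run pooled and per replicate", {
  sim <- simulate_series(sim_config(150, assays = "H3K4me3", seed = 9),
                         c(1, 0, 0, 0), "ploidy")
  sm <- signal_matrix_from_sim(sim)
  pooled <- modification_level_test(sm, sim$triads, "TAA10", "ETW",
                                    "H3K4me3", subgenome = "A")
  expect_s3_class(pooled, "triad_test")
  expect_true(pooled$p.value >= 0 && pooled$p.value <= 1)
  per_rep <- modification_level_test(sm, sim$triads, "TAA10", "ETW",
                                     "H3K4me3", subgenome = "A",
                                     pool_replicates = FALSE)
  expect_length(per_rep, 4L)  # 2 x 2 replicate pairings
})
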