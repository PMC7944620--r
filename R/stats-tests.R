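# The inferential toolkit. Each test is written out in full (the package's
# contract pins down the exact algorithm: minimum-likelihood two-sided
# binomial p, Yates-corrected proportion chi-square, enumeration-exact
# Wilcoxon, upper-tail hypergeometric with BH step-up); base R's
# implementations serve as independent cross-checks in the test suite.

triad_test <- function(method, statistic, p.value, n, alternative =
                         "two.sided", ...) {
  structure(list(method = method, statistic = statistic,
                 p.value = p.value, n = n, alternative = alternative, ...),
            class = "triad_test")
}

#' @export
print.triad_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p.value),
      " n =", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Exact binomial test of subgenome asymmetry
#'
#' Tests whether, among biased triads, A>B and A<B calls are equally
#' frequent: an exact two-sided binomial test of `n_AgtB` successes in
#' `n_AgtB + n_AltB` trials at null probability 0.5.  The two-sided p-value
#' is the minimum-likelihood sum: the total probability of all outcomes no
#' more likely than the observed one.
#'
#' @param n_AgtB,n_AltB counts of A-biased and B-biased triads.
#' @return a `triad_test` with `statistic` = `n_AgtB` and the exact
#'   p-value.
#' @export
binom_asymmetry <- function(n_AgtB, n_AltB) {
  if (n_AgtB < 0 || n_AltB < 0) stop("counts must be non-negative")
  n <- n_AgtB + n_AltB
  if (n < 1) stop("no biased triads: both counts are zero")
  d <- dbinom(0:n, n, 0.5)
  p <- min(1, sum(d[d <= d[n_AgtB + 1L] * (1 + 1e-7)]))
  triad_test("Exact binomial test (p0 = 0.5, two-sided)",
             statistic = n_AgtB, p.value = p, n = n,
             estimate = n_AgtB / n)
}

#' Two-sample proportion test
#'
#' Chi-square test on 1 df for equality of two proportions, with the Yates
#' continuity correction on by default (the correction is capped at the
#' observed difference).  A pooled proportion of 0 or 1 leaves the
#' statistic undefined; p = 1 is returned with a warning.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2 (`x2` may be a
#'   non-integral expected count when testing against a fixed expectation).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return a `triad_test` with the chi-square `statistic`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 < 1 || n2 < 1) stop("each sample needs at least one trial")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("successes must lie in [0, n]")
  p1 <- x1 / n1; p2 <- x2 / n2
  pb <- (x1 + x2) / (n1 + n2)
  if (pb <= 0 || pb >= 1) {
    warning("pooled proportion is 0 or 1; statistic undefined, p = 1")
    return(triad_test("Two-sample proportion test", statistic = NA_real_,
                      p.value = 1, n = c(n1, n2), estimate = c(p1, p2)))
  }
  cc <- if (correct) min(0.5 * (1 / n1 + 1 / n2), abs(p1 - p2)) else 0
  chi <- (abs(p1 - p2) - cc)^2 / (pb * (1 - pb) * (1 / n1 + 1 / n2))
  triad_test(paste0("Two-sample proportion test (chi-square, 1 df",
                    if (correct) ", Yates-corrected", ")"),
             statistic = chi, p.value = pchisq(chi, 1L, lower.tail = FALSE),
             n = c(n1, n2), estimate = c(p1, p2))
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test for a location shift between two samples,
#' as used for comparing modification levels between genotypes.  The exact
#' two-sided p-value (twice the smaller tail of the permutation
#' distribution of U, capped at 1) is computed by full enumeration of rank
#' assignments when the combined sample size is at most `exact_threshold`
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_threshold maximum combined size for the enumeration path
#'   (default 20).
#' @return a `triad_test` with `statistic` = U (pairs where an `x` exceeds
#'   a `y`, ties counting half).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 20L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  if (N <= exact_threshold && !has_ties) {
    Us <- colSums(combn(N, n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    method <- "Wilcoxon rank-sum test (exact, enumeration)"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 == 0) {
      p <- 1
      method <- "Wilcoxon rank-sum test (degenerate: all values tied)"
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- "Wilcoxon rank-sum test (normal approximation)"
    }
  }
  triad_test(method, statistic = U, p.value = p, n = c(n1, n2))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length (at least 3) with nonzero
#'   variance.
#' @return a `triad_test` with `statistic` = r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stop("zero variance; correlation undefined")
  triad_test("Pearson correlation",
             statistic = sum(dx * dy) / (sx * sy),
             p.value = NA_real_, n = length(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q[q > 1] <- 1
  q[order(ord)]
}

#' Hypergeometric (GO) enrichment with BH FDR
#'
#' For each annotation term, tests over-representation of the term among a
#' gene selection relative to a universe: the upper-tail hypergeometric
#' probability `P(X >= k)` for `X ~ Hypergeom(N, K, n)`, where `N` is the
#' universe size, `K` the term size within the universe, `n` the selection
#' size and `k` the overlap.  q-values are Benjamini-Hochberg over all
#' tested terms.
#'
#' @param selection character vector of selected genes (must lie within
#'   the universe).
#' @param annotation data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name` (see [read_go()]).
#' @param universe character vector of background genes; defaults to all
#'   annotated genes.
#' @param q_max significance threshold on the q-value (default 0.05).
#' @return data frame, one row per term: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `significant`, ordered by p.
#' @export
hypergeom_enrichment <- function(selection, annotation, universe = NULL,
                                 q_max = 0.05) {
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  universe <- unique(universe)
  selection <- unique(selection)
  if (!length(selection)) stop("empty selection")
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(selection, universe)
  if (length(outside))
    stop("selection gene outside the universe: ", outside[1L])
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  if (is.null(ann$term_name)) ann$term_name <- ann$term_id
  N <- length(universe); n <- length(selection)
  terms <- split(ann$gene_id, ann$term_id)
  term_names <- tapply(ann$term_name, ann$term_id, `[`, 1L)
  res <- lapply(names(terms), function(t) {
    tg <- unique(terms[[t]])
    K <- length(tg); k <- length(intersect(tg, selection))
    kk <- k:min(K, n)
    p <- sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
    data.frame(term_id = t, term_name = unname(term_names[t]),
               k = k, K = K, n = n, N = N, p = min(1, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_max
  out[order(out$p), , drop = FALSE]
}

#' Wilcoxon comparisons of modification level between genotypes
#'
#' Compares per-gene TPM of one subgenome's homoeologs between two
#' genotypes for a given assay, the per-subgenome level comparison used to
#' contrast overall modification intensity across the ploidy series.
#' Replicates may be pooled into per-gene mean TPM (default) or tested
#' separately per replicate pair.
#'
#' @param sm a `signal_matrix`.
#' @param triads a `triad_table`.
#' @param genotype1,genotype2 genotypes to compare.
#' @param assay assay name.
#' @param subgenome `"A"`, `"B"` or `"D"`.
#' @param triad_ids optional subset of triads (e.g. one tracking label).
#' @param pool_replicates pool replicates by per-gene mean (default) or
#'   test each replicate pairing separately.
#' @return for pooled mode a single `triad_test`; otherwise a list of
#'   `triad_test`, one per replicate pairing.
#' @export
modification_level_test <- function(sm, triads, genotype1, genotype2, assay,
                                    subgenome = "A", triad_ids = NULL,
                                    pool_replicates = TRUE) {
  stopifnot(inherits(sm, "signal_matrix"), inherits(triads, "triad_table"))
  g <- triads$genes
  keep <- g$subgenome == subgenome
  if (!is.null(triad_ids)) keep <- keep & g$triad_id %in% triad_ids
  genes <- g$gene_id[keep]
  cols <- function(geno) which(sm$design$genotype == geno &
                               sm$design$assay == assay)
  i1 <- cols(genotype1); i2 <- cols(genotype2)
  if (!length(i1) || !length(i2))
    stop("genotype/assay combination absent from the signal matrix")
  if (pool_replicates) {
    x <- rowMeans(sm$tpm[genes, i1, drop = FALSE])
    y <- rowMeans(sm$tpm[genes, i2, drop = FALSE])
    wilcoxon_rank_sum(x, y)
  } else {
    pairs <- expand.grid(a = i1, b = i2)
    lapply(seq_len(nrow(pairs)), function(k)
      wilcoxon_rank_sum(sm$tpm[genes, pairs$a[k]],
                        sm$tpm[genes, pairs$b[k]]))
  }
}
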