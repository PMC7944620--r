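#' Normalize a triad's A/B signal to relative fractions
#'
#' Within-triad normalization: each homoeolog's TPM is divided by the A+B
#' total so that a triad is represented by a point `(rel_A, rel_B)` on the
#' unit simplex, comparable across triads regardless of absolute signal.
#'
#' @param tpm_A,tpm_B non-negative TPM values (vectorized).
#' @return a two-column matrix `(rel_A, rel_B)` with rows summing to 1.
#'   A triad with `tpm_A + tpm_B == 0` has undefined relative signal and
#'   returns `NA` (callers treat it as unmodified).
#' @export
normalize_triad <- function(tpm_A, tpm_B) {
  if (any(tpm_A < 0 | tpm_B < 0, na.rm = TRUE)) stop("negative TPM")
  tot <- tpm_A + tpm_B
  rel_A <- ifelse(tot > 0, tpm_A / tot, NA_real_)
  cbind(rel_A = rel_A, rel_B = 1 - rel_A)
}

#' Modified-triad filter
#'
#' A triad counts as modified by a mark (or expressed, for RNA) when the A
#' or the B homoeolog exceeds the TPM threshold, strictly.
#'
#' @param tpm_A,tpm_B non-negative TPM values (vectorized).
#' @param tau TPM threshold (default 0.5).
#' @return logical vector.
#' @export
is_modified <- function(tpm_A, tpm_B, tau = 0.5) {
  if (tau < 0) stop("tau must be >= 0")
  tpm_A > tau | tpm_B > tau
}

# Anchor coordinates in the (rel_A, rel_B) plane.
ANCHORS <- rbind(A_eq_B = c(0.5, 0.5), A_gt_B = c(1, 0), A_lt_B = c(0, 1))

#' Nearest-anchor bias classification
#'
#' Assigns each normalized triad to the category whose anchor --
#' `A_eq_B` = (0.5, 0.5), `A_gt_B` = (1, 0), `A_lt_B` = (0, 1) -- is
#' nearest in Euclidean distance.  On the simplex this places the balanced/
#' biased boundary exactly at `rel_A` = 0.25 and 0.75.  Exact ties are
#' resolved conservatively in favour of the balanced category, then
#' `A_gt_B`.
#'
#' @param rel_A,rel_B relative fractions summing to 1 (vectorized).
#' @return a data frame with columns `category` and the three anchor
#'   distances `d_eq`, `d_gt`, `d_lt`.
#' @export
classify_bias <- function(rel_A, rel_B) {
  ok <- !is.na(rel_A)
  if (any(abs(rel_A[ok] + rel_B[ok] - 1) > 1e-9))
    stop("rel_A + rel_B must equal 1")
  if (any(rel_A[ok] < 0 | rel_A[ok] > 1)) stop("rel_A must lie in [0, 1]")
  d <- vapply(rownames(ANCHORS), function(k)
    sqrt((rel_A - ANCHORS[k, 1L])^2 + (rel_B - ANCHORS[k, 2L])^2),
    numeric(length(rel_A)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L,
                                   dimnames = list(NULL, rownames(ANCHORS)))
  # ties go to the earlier column: A_eq_B, then A_gt_B, then A_lt_B
  idx <- rep(NA_integer_, length(rel_A))
  okr <- which(ok)
  if (length(okr))
    idx[okr] <- apply(round(d[okr, , drop = FALSE], 12L), 1L, which.min)
  data.frame(category = CATEGORIES[idx],
             d_eq = d[, "A_eq_B"], d_gt = d[, "A_gt_B"],
             d_lt = d[, "A_lt_B"], stringsAsFactors = FALSE)
}

#' Classify every triad in a dataset
#'
#' Applies the modification filter and nearest-anchor classification to
#' each triad for every requested (genotype, assay), using replicate-mean
#' TPM.  For hexaploid genotypes the D homoeolog is ignored: `rel_A` is
#' computed over A + B only.
#'
#' @param x an `aggregated_signal` (from [aggregate_replicates()]) or a
#'   `signal_matrix` (aggregated with replicate means first).
#' @param triads a `triad_table`.
#' @param genotypes,assays optional subsets; default all present.
#' @param tau modification filter in TPM (default 0.5, strict).
#' @return an object of class `bias_calls`: a data frame with one row per
#'   triad x genotype x assay and columns `triad_id`, `genotype`, `assay`,
#'   `tpm_A`, `tpm_B`, `rel_A`, `rel_B`, `d_eq`, `d_gt`, `d_lt`,
#'   `category` (one of `A_eq_B`, `A_gt_B`, `A_lt_B`, `unmodified`).
#' @seealso [summary.bias_calls()] for category counts and percentages,
#'   [modified_union()] for multi-genotype modified-triad denominators.
#' @export
classify_dataset <- function(x, triads, genotypes = NULL, assays = NULL,
                             tau = 0.5) {
  if (inherits(x, "signal_matrix")) x <- aggregate_replicates(x, "mean")
  stopifnot(inherits(x, "aggregated_signal"), inherits(triads, "triad_table"))
  gr <- x$groups
  if (is.null(genotypes)) genotypes <- unique(gr$genotype)
  if (is.null(assays)) assays <- unique(gr$assay)
  tt <- triads$triads
  missing <- setdiff(c(tt$gene_A, tt$gene_B), rownames(x$tpm))
  if (length(missing))
    stop("homoeolog missing from TPM matrix: ", missing[1L])
  out <- list()
  for (g in genotypes) for (a in assays) {
    col <- which(gr$genotype == g & gr$assay == a)
    if (!length(col)) stop("no TPM column for ", g, "/", a)
    if (length(col) > 1L)
      stop("multiple TPM columns for ", g, "/", a,
           "; aggregate replicates (method = \"mean\") before classifying")
    tpm_A <- x$tpm[tt$gene_A, col[1L]]
    tpm_B <- x$tpm[tt$gene_B, col[1L]]
    mod <- is_modified(tpm_A, tpm_B, tau)
    rel <- normalize_triad(tpm_A, tpm_B)
    cls <- classify_bias(ifelse(mod, rel[, 1L], NA),
                         ifelse(mod, rel[, 2L], NA))
    cls$category[!mod] <- UNMODIFIED
    out[[paste(g, a)]] <- data.frame(
      triad_id = tt$triad_id, genotype = g, assay = a,
      tpm_A = unname(tpm_A), tpm_B = unname(tpm_B),
      rel_A = ifelse(mod, rel[, 1L], NA), rel_B = ifelse(mod, rel[, 2L], NA),
      d_eq = cls$d_eq, d_gt = cls$d_gt, d_lt = cls$d_lt,
      category = cls$category, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(calls, "tau") <- tau
  class(calls) <- c("bias_calls", "data.frame")
  calls
}

#' Summarise bias calls per genotype and assay
#'
#' @param object a `bias_calls` object.
#' @param ... unused.
#' @return data frame with, per (genotype, assay): `n_triads`,
#'   `n_modified`, `pct_modified`, counts `n_eq`, `n_gt`, `n_lt`,
#'   percentages of modified triads `pct_eq`, `pct_gt`, `pct_lt`, and
#'   `pct_biased` (biased share of modified triads).
#' @export
summary.bias_calls <- function(object, ...) {
  sp <- split(seq_len(nrow(object)),
              list(genotype = object$genotype, assay = object$assay),
              drop = TRUE)
  out <- lapply(sp, function(i) {
    cat_ <- object$category[i]
    n <- length(i); nm <- sum(cat_ != UNMODIFIED)
    cnt <- vapply(CATEGORIES, function(k) sum(cat_ == k), 0L)
    data.frame(genotype = object$genotype[i][1L],
               assay = object$assay[i][1L],
               n_triads = n, n_modified = nm,
               pct_modified = 100 * nm / n,
               n_eq = cnt[1L], n_gt = cnt[2L], n_lt = cnt[3L],
               pct_eq = 100 * cnt[1L] / nm, pct_gt = 100 * cnt[2L] / nm,
               pct_lt = 100 * cnt[3L] / nm,
               pct_biased = 100 * (cnt[2L] + cnt[3L]) / nm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out[order(out$assay, out$genotype), , drop = FALSE]
}

#' @export
print.bias_calls <- function(x, ...) {
  cat("Bias calls:", length(unique(x$triad_id)), "triads x",
      length(unique(x$genotype)), "genotypes x",
      length(unique(x$assay)), "assays (tau =", attr(x, "tau"), "TPM)\n")
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Modified-in-at-least-one-genotype denominators
#'
#' Counts triads modified in at least one genotype of a named set, the
#' union denominator used when reporting what fraction of all triads is
#' covered by a mark across a panel of lines.
#'
#' @param calls a `bias_calls` object.
#' @param genotypes genotypes forming the union (default: all in `calls`).
#' @return data frame per assay: `n_total`, `n_modified_union`,
#'   `pct_modified_union`.
#' @export
modified_union <- function(calls, genotypes = NULL) {
  stopifnot(inherits(calls, "bias_calls"))
  if (is.null(genotypes)) genotypes <- unique(calls$genotype)
  sub <- calls[calls$genotype %in% genotypes, , drop = FALSE]
  out <- lapply(split(sub, sub$assay), function(d) {
    mod <- tapply(d$category != UNMODIFIED, d$triad_id, any)
    data.frame(assay = d$assay[1L], n_total = length(mod),
               n_modified_union = sum(mod),
               pct_modified_union = 100 * mean(mod),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Subgenome-asymmetry test on a set of bias calls
#'
#' Tests, per (genotype, assay), whether biased triads favour the A
#' subgenome more often than the B subgenome, by the exact binomial test on
#' the (A>B, A<B) counts.
#'
#' @param calls a `bias_calls` object.
#' @return data frame with `genotype`, `assay`, `n_gt`, `n_lt`, `p_value`.
#' @export
asymmetry_tests <- function(calls) {
  stopifnot(inherits(calls, "bias_calls"))
  sp <- split(seq_len(nrow(calls)),
              list(genotype = calls$genotype, assay = calls$assay),
              drop = TRUE)
  out <- lapply(sp, function(i) {
    n_gt <- sum(calls$category[i] == "A_gt_B")
    n_lt <- sum(calls$category[i] == "A_lt_B")
    data.frame(genotype = calls$genotype[i][1L],
               assay = calls$assay[i][1L], n_gt = n_gt, n_lt = n_lt,
               p_value = binom_asymmetry(n_gt, n_lt)$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
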