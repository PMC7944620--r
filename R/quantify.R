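#' Convert gene-level counts to TPM
#'
#' Transcripts Per Kilobase Million: each gene's count is divided by its
#' length in kilobases and the resulting per-kilobase rates are scaled to
#' sum to one million over the gene universe of the sample.
#'
#' @param counts named numeric vector of non-negative gene counts.
#' @param lengths named numeric vector of gene lengths in bp; must cover
#'   every gene in `counts`.
#' @return named numeric vector of TPM values, summing to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) == 0L) stop("empty count vector")
  L <- lengths[names(counts)]
  if (anyNA(L))
    stop("gene with count but no length: ",
         names(counts)[is.na(L)][1L])
  if (any(L <= 0)) stop("gene length must be > 0")
  if (any(counts < 0)) stop("negative count")
  total <- sum(counts)
  if (total == 0) stop("all counts are zero; TPM undefined")
  rate <- counts / (L / 1000)
  1e6 * rate / sum(rate)
}

#' Assemble a TPM signal matrix from per-sample counts
#'
#' @param counts a genes x samples matrix of raw counts (as in a
#'   `triad_sim`), or a named list of per-sample count vectors from
#'   [read_counts()].
#' @param lengths named gene lengths in bp.
#' @param design sample sheet with columns `sample_id`, `genotype`,
#'   `assay`, `replicate`; `(genotype, assay, replicate)` must be unique.
#' @return an object of class `signal_matrix`: list with `tpm` and
#'   `counts` (genes x samples matrices) and `design`.
#' @export
signal_matrix <- function(counts, lengths, design) {
  if (is.list(counts) && !is.matrix(counts)) {
    genes <- names(counts[[1L]])
    counts <- vapply(counts, function(x) x[genes], numeric(length(genes)))
    rownames(counts) <- genes
  }
  if (anyNA(counts)) stop("count matrix has missing values")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (anyDuplicated(design[c("genotype", "assay", "replicate")]))
    stop("(genotype, assay, replicate) must be unique in the design")
  if (!setequal(design$sample_id, colnames(counts)))
    stop("design sample_id does not match count matrix columns")
  counts <- counts[, design$sample_id, drop = FALSE]
  tpm <- apply(counts, 2L, compute_tpm, lengths = lengths)
  structure(list(tpm = tpm, counts = counts, design = design),
            class = "signal_matrix")
}

#' Build a signal matrix directly from a simulated dataset
#'
#' @param sim a `triad_sim` object.
#' @return a `signal_matrix` (see [signal_matrix()]).
#' @export
signal_matrix_from_sim <- function(sim) {
  stopifnot(inherits(sim, "triad_sim"))
  signal_matrix(sim$counts, sim$lengths, sim$design)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("Signal matrix:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples\n")
  invisible(x)
}

#' Aggregate replicate TPM columns per (genotype, assay)
#'
#' @param sm a `signal_matrix`.
#' @param method `"mean"` (default: arithmetic mean of replicate TPMs per
#'   gene) or `"separate"` (replicates kept as distinct columns, for
#'   per-replicate analyses).
#' @return a list with `tpm` (genes x groups matrix) and `groups` (data
#'   frame with `genotype`, `assay`, and for `"separate"` also
#'   `replicate`), of class `aggregated_signal`.
#' @export
aggregate_replicates <- function(sm, method = c("mean", "separate")) {
  stopifnot(inherits(sm, "signal_matrix"))
  method <- match.arg(method)
  d <- sm$design
  if (method == "separate") {
    groups <- d[c("genotype", "assay", "replicate")]
    tpm <- sm$tpm
    colnames(tpm) <- d$sample_id
  } else {
    key <- paste(d$genotype, d$assay, sep = ".")
    groups <- unique(d[c("genotype", "assay")])
    ukey <- paste(groups$genotype, groups$assay, sep = ".")
    tpm <- vapply(ukey, function(k)
      rowMeans(sm$tpm[, key == k, drop = FALSE]), numeric(nrow(sm$tpm)))
    colnames(tpm) <- ukey
  }
  rownames(groups) <- NULL
  structure(list(tpm = tpm, groups = groups, method = method),
            class = "aggregated_signal")
}

#' Replicate concordance (Pearson correlation of TPM)
#'
#' Computes the Pearson correlation of per-gene TPM between every pair of
#' replicates within each (genotype, assay), the standard QC for ChIP/RNA
#' replicate agreement.
#'
#' @param sm a `signal_matrix` with at least two replicates per group and
#'   at least three genes.
#' @param log2 if `TRUE`, correlate `log2(TPM + 1)` instead of linear TPM.
#' @return data frame with columns `genotype`, `assay`, `rep1`, `rep2`,
#'   `r`, `n_genes`.  A zero-variance column yields `NA` with a warning.
#' @export
replicate_correlation <- function(sm, log2 = FALSE) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (nrow(sm$tpm) < 3L) stop("need at least 3 genes")
  d <- sm$design
  out <- list()
  for (g in unique(d$genotype)) for (a in unique(d$assay)) {
    sel <- which(d$genotype == g & d$assay == a)
    if (length(sel) < 2L) next
    for (i in seq_along(sel)[-length(sel)]) for (j in seq((i + 1L),
                                                          length(sel))) {
      x <- sm$tpm[, sel[i]]; y <- sm$tpm[, sel[j]]
      if (log2) { x <- log2(x + 1); y <- log2(y + 1) }
      r <- if (var(x) == 0 || var(y) == 0) {
        warning("zero-variance replicate in ", g, "/", a,
                "; correlation undefined")
        NA_real_
      } else pearson_r(x, y)$statistic
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, assay = a,
        rep1 = d$replicate[sel[i]], rep2 = d$replicate[sel[j]],
        r = r, n_genes = nrow(sm$tpm), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no replicate pairs found")
  do.call(rbind, out)
}

#' Subgenome read share per sample
#'
#' Fraction of triad-gene reads attributable to each subgenome, the QC used
#' to verify homoeolog-specific mapping: a DD diploid should place all its
#' triad reads on D-subgenome homoeologs, a tetraploid none.
#'
#' @param sm a `signal_matrix` (raw counts are used) or a genes x samples
#'   count matrix.
#' @param triads a `triad_table`.
#' @return data frame with columns `sample_id`, `A`, `B`, `D` (proportions
#'   summing to 1 per sample).
#' @export
subgenome_share <- function(sm, triads) {
  counts <- if (inherits(sm, "signal_matrix")) sm$counts else sm
  stopifnot(inherits(triads, "triad_table"))
  g <- triads$genes
  missing <- setdiff(g$gene_id, rownames(counts))
  if (length(missing))
    stop("triad gene missing from count matrix: ", missing[1L])
  share <- sapply(c("A", "B", "D"), function(s)
    colSums(counts[g$gene_id[g$subgenome == s], , drop = FALSE]))
  if (is.null(dim(share)))
    share <- matrix(share, nrow = 1L,
                    dimnames = list(colnames(counts), c("A", "B", "D")))
  tot <- rowSums(share)
  if (any(tot == 0)) stop("sample with zero triad-gene reads: ",
                          colnames(counts)[tot == 0][1L])
  data.frame(sample_id = colnames(counts), share / tot,
             row.names = NULL, stringsAsFactors = FALSE)
}
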