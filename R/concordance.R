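#' Classify triad expression bias from RNA data
#'
#' Expression bias uses the identical machinery as modification bias: the
#' same 0.5 TPM filter (triads below it are unexpressed) and the same
#' nearest-anchor classification of within-triad relative expression.
#'
#' @param x an `aggregated_signal` or `signal_matrix` containing an RNA
#'   assay.
#' @param triads a `triad_table`.
#' @param genotypes optional genotype subset.
#' @param tau expression filter in TPM (default 0.5).
#' @param assay assay name holding expression data (default `"RNA"`).
#' @return a `bias_calls` object (see [classify_dataset()]).
#' @export
classify_expression <- function(x, triads, genotypes = NULL, tau = 0.5,
                                assay = "RNA") {
  if (inherits(x, "signal_matrix")) x <- aggregate_replicates(x, "mean")
  if (!assay %in% x$groups$assay)
    stop("no ", assay, " assay present in the signal")
  classify_dataset(x, triads, genotypes = genotypes, assays = assay,
                   tau = tau)
}

#' Modification-expression concordance of series labels
#'
#' Crosses the series labels of a modification assay with those of the
#' expression assay on the triads tracked in both, and tests each cell of
#' the label-by-label contingency table for enrichment: the share of the
#' expression label among triads carrying the modification label is
#' compared with its share among the remaining triads (two-sample
#' proportion test; by default without continuity correction, appropriate
#' for the large tables this is used on).
#'
#' @param mod_tracks a `series_tracks` object for the modification assay.
#' @param expr_tracks a `series_tracks` object for the expression (RNA)
#'   assay over the same series.
#' @param correct continuity correction for the per-cell tests (default
#'   `FALSE`).
#' @param alpha per-cell significance threshold (default 0.05).
#' @return an object of class `concordance_table`: a list with `counts`,
#'   `expected` (product-of-margins expectation), `p_values` and
#'   `significant` (label x label matrices), `cells` (long-format data
#'   frame), `mod_margin`, `expr_margin`, `n` (common tracked triads), and
#'   the assay names.
#' @export
concordance_matrix <- function(mod_tracks, expr_tracks, correct = FALSE,
                               alpha = 0.05) {
  m <- mod_tracks[mod_tracks$label != "not_tracked", ]
  e <- expr_tracks[expr_tracks$label != "not_tracked", ]
  common <- intersect(m$triad_id, e$triad_id)
  if (!length(common)) stop("no triads tracked in both assays")
  labels <- c("I", "II", "III", "IV")
  ml <- factor(m$label[match(common, m$triad_id)], levels = labels)
  el <- factor(e$label[match(common, e$triad_id)], levels = labels)
  counts <- table(modification = ml, expression = el)
  N <- length(common)
  rm_ <- rowSums(counts); cm_ <- colSums(counts)
  expected <- outer(rm_, cm_) / N
  p <- matrix(NA_real_, 4L, 4L, dimnames = dimnames(counts))
  for (i in seq_len(4L)) for (j in seq_len(4L)) {
    if (rm_[i] == 0L || rm_[i] == N) next
    p[i, j] <- two_proportion_test(counts[i, j], rm_[i],
                                   cm_[j] - counts[i, j], N - rm_[i],
                                   correct = correct)$p.value
  }
  cells <- data.frame(
    modification = rep(labels, 4L), expression = rep(labels, each = 4L),
    n = as.vector(counts), expected = as.vector(expected),
    p_value = as.vector(p),
    significant = as.vector(p) < alpha, stringsAsFactors = FALSE)
  structure(list(counts = unclass(counts), expected = expected,
                 p_values = p, significant = p < alpha, cells = cells,
                 mod_margin = rm_, expr_margin = cm_, n = N,
                 mod_assay = mod_tracks$assay[1L],
                 expr_assay = expr_tracks$assay[1L], alpha = alpha),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance of", x$mod_assay, "vs", x$expr_assay, "series labels (",
      x$n, "triads tracked in both)\n")
  cat("Counts (modification rows x expression columns):\n")
  print(x$counts)
  cat("Cells enriched at p <", x$alpha, ":",
      sum(x$significant, na.rm = TRUE), "\n")
  invisible(x)
}
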