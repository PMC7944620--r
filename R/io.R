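#' Read a gene-level count table
#'
#' Reads a two-column tab-separated table (`gene_id`, `count`) as produced by
#' gene-body read counting of uniquely mapped ChIP or RNA reads.
#'
#' @param path path to a TSV file with a header line and columns
#'   `gene_id` and `count`.
#' @return a named numeric vector of counts, one element per gene.
#' @details Counts must be non-negative and integral; a duplicated
#'   `gene_id` is an error.  A header-only file yields an empty vector with
#'   a warning.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("count file must have two columns (gene_id, count): ", path)
  if (nrow(tab) == 0L) {
    warning("count file is empty (header only): ", path)
    return(structure(numeric(0), names = character(0)))
  }
  ids <- as.character(tab[[1L]])
  counts <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(counts)) {
    bad <- ids[is.na(counts)][1L]
    stop("malformed count for gene '", bad, "' in ", path)
  }
  if (any(counts < 0)) {
    bad <- ids[counts < 0][1L]
    stop("negative count for gene '", bad, "' in ", path)
  }
  if (any(counts != round(counts))) {
    bad <- ids[counts != round(counts)][1L]
    stop("non-integer count for gene '", bad, "' in ", path)
  }
  if (anyDuplicated(ids)) {
    bad <- ids[duplicated(ids)][1L]
    stop("duplicate gene_id '", bad, "' in ", path)
  }
  structure(counts, names = ids)
}

#' Read gene coordinates from GFF3 or BED
#'
#' Coordinates are normalized to the 0-based half-open convention used
#' throughout the package (GFF3 is 1-based closed on disk; BED already
#' 0-based half-open).
#'
#' @param path a GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.
#' @param feature_type for GFF3, the feature type to keep (default
#'   `"gene"`).
#' @return a data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `length`.
#' @export
read_gene_coords <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(gr$type) == feature_type]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    if (anyNA(ids) || is.null(ids))
      stop("GFF3 gene features must carry an ID or Name attribute")
    ids <- sub("^gene:", "", ids)
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,  # to 0-based
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("BED file needs chrom,start,end,name: ", path)
    out <- data.frame(gene_id = as.character(tab[[4L]]),
                      chrom = as.character(tab[[1L]]),
                      start = as.integer(tab[[2L]]),
                      end = as.integer(tab[[3L]]),
                      stringsAsFactors = FALSE)
  }
  out$length <- out$end - out$start
  if (any(out$length <= 0))
    stop("gene with non-positive length: ",
         out$gene_id[out$length <= 0][1L])
  if (anyDuplicated(out$gene_id))
    stop("duplicated gene_id in coordinates: ",
         out$gene_id[duplicated(out$gene_id)][1L])
  out
}

#' Read a homoeolog triad table
#'
#' A triad is a 1:1:1 set of homoeologous genes, one per subgenome.  The
#' table must have columns `triad_id`, `gene_A`, `gene_B`, `gene_D`; gene
#' coordinates are joined from a GFF3/BED file (or an already-parsed
#' coordinate data frame).
#'
#' @param path TSV file with header `triad_id`, `gene_A`, `gene_B`,
#'   `gene_D`.
#' @param coords a coordinate source accepted by [read_gene_coords()], or a
#'   data frame in its output format.
#' @return an object of class `triad_table`: a list with elements `triads`
#'   (the mapping) and `genes` (per-gene `gene_id`, `triad_id`,
#'   `subgenome`, `chrom`, `start`, `end`, `length`).
#' @export
read_triads <- function(path, coords) {
  if (!file.exists(path)) stop("triad file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("triad_id", "gene_A", "gene_B", "gene_D")
  if (!all(need %in% names(tab)))
    stop("triad table must have columns: ", paste(need, collapse = ", "))
  if (is.character(coords)) coords <- read_gene_coords(coords)
  triad_table(tab[need], coords)
}

#' Construct and validate a triad table
#'
#' @param triads data frame with `triad_id`, `gene_A`, `gene_B`, `gene_D`.
#' @param coords data frame with `gene_id`, `chrom`, `start`, `end` (and
#'   optionally `length`).
#' @return a validated `triad_table` object.
#' @export
triad_table <- function(triads, coords) {
  triads <- as.data.frame(triads, stringsAsFactors = FALSE)
  if (anyDuplicated(triads$triad_id))
    stop("duplicate triad_id: ",
         triads$triad_id[duplicated(triads$triad_id)][1L])
  all_genes <- c(triads$gene_A, triads$gene_B, triads$gene_D)
  if (anyDuplicated(all_genes))
    stop("gene assigned to more than one triad slot: ",
         all_genes[duplicated(all_genes)][1L])
  genes <- data.frame(
    gene_id = all_genes,
    triad_id = rep(triads$triad_id, 3L),
    subgenome = rep(c("A", "B", "D"), each = nrow(triads)),
    stringsAsFactors = FALSE)
  if (is.null(coords$length)) coords$length <- coords$end - coords$start
  idx <- match(genes$gene_id, coords$gene_id)
  if (anyNA(idx))
    stop("gene missing coordinates: ", genes$gene_id[is.na(idx)][1L])
  genes <- cbind(genes, coords[idx, c("chrom", "start", "end", "length")])
  rownames(genes) <- genes$gene_id
  if (any(genes$length <= 0))
    stop("gene with non-positive length: ",
         genes$gene_id[genes$length <= 0][1L])
  structure(list(triads = triads, genes = genes), class = "triad_table")
}

#' @export
print.triad_table <- function(x, ...) {
  cat("Triad table:", nrow(x$triads), "triads,", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosomes\n")
  print(head(x$triads, 4L))
  invisible(x)
}

#' Read a chromosomal zone partition
#'
#' The wheat chromosome partition into distal (R1, R3), interstitial (R2a,
#' R2b) and proximal/pericentromeric (C) zones, as a BED-like TSV
#' (`chrom`, `start`, `end`, `zone`), 0-based half-open.  A header line is
#' detected automatically.
#'
#' @param path BED-like TSV file.
#' @return a `zone_partition` data frame with columns `chrom`, `start`,
#'   `end`, `zone`.
#' @export
read_zones <- function(path) {
  if (!file.exists(path)) stop("zone file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  has_header <- suppressWarnings(is.na(as.numeric(first[2L])))
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("chrom", "start", "end", "zone")
  zone_partition(tab)
}

#' Construct and validate a zone partition
#'
#' @param zones data frame with columns `chrom`, `start`, `end`, `zone`.
#' @return the validated `zone_partition` data frame, sorted by chromosome
#'   and start.
#' @export
zone_partition <- function(zones) {
  zones <- as.data.frame(zones, stringsAsFactors = FALSE)
  bad <- setdiff(unique(zones$zone), ZONES)
  if (length(bad))
    stop("unknown zone label: ", bad[1L], " (allowed: ",
         paste(ZONES, collapse = ", "), ")")
  zones$start <- as.numeric(zones$start)
  zones$end <- as.numeric(zones$end)
  if (any(zones$end <= zones$start)) stop("zone interval with end <= start")
  zones <- zones[order(zones$chrom, zones$start), , drop = FALSE]
  for (ch in unique(zones$chrom)) {
    z <- zones[zones$chrom == ch, ]
    if (nrow(z) > 1L && any(z$start[-1L] < z$end[-nrow(z)]))
      stop("overlapping zone intervals on ", ch)
  }
  rownames(zones) <- NULL
  class(zones) <- c("zone_partition", "data.frame")
  zones
}

#' Read a GO (or GO-slim) annotation table
#'
#' @param path TSV with header columns `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @return a data frame with one row per (gene, term) link.
#' @export
read_go <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tab)))
    stop("annotation table needs columns gene_id, term_id")
  if (is.null(tab$term_name)) tab$term_name <- tab$term_id
  tab[c("gene_id", "term_id", "term_name")]
}

#' Read a run configuration file
#'
#' A single YAML document keyed by section: `samples` (per-sample genotype,
#' assay, replicate and count-file path), `files` (triads, coordinates,
#' zones, annotation) and `thresholds`.  All thresholds default to the
#' analysis defaults (`tau` = 0.5 TPM modification filter, `alpha` = 0.05,
#' `q_max` = 0.05) and may be overridden.
#'
#' @param path YAML file.
#' @return a named list with elements `samples`, `files`, `thresholds`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(tau = 0.5, alpha = 0.05, q_max = 0.05)
  cfg$thresholds <- utils::modifyList(defaults,
                                      as.list(cfg$thresholds %||% list()))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tab-separated table
#'
#' All tabular outputs of the package are written in this dialect (tab
#' separated, header, no quoting, no row names) so that writing and
#' re-reading reproduces the table field-for-field.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_tsv()]
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk in the package's input formats
#'
#' Emits one count TSV per sample (`counts_<sample_id>.tsv`), the triad
#' mapping (`triads.tsv`), gene coordinates (`genes.bed`), the zone
#' partition (`zones.tsv`), the sample design (`design.tsv`) and the
#' planted truth (`truth_labels.tsv`, plus `truth_series.tsv` for series
#' simulations), so a round trip through the readers reproduces the
#' in-memory dataset.
#'
#' @param sim a `triad_sim` object from [simulate_dataset()] or
#'   [simulate_series()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "triad_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in colnames(sim$counts)) {
    df <- data.frame(gene_id = rownames(sim$counts),
                     count = as.integer(sim$counts[, s]))
    write_tsv(df, file.path(dir, paste0("counts_", s, ".tsv")))
  }
  write_tsv(sim$triads$triads, file.path(dir, "triads.tsv"))
  g <- sim$all_coords
  bed <- data.frame(g$chrom, g$start, g$end, g$gene_id)
  write.table(bed, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(as.data.frame(sim$zones), file.path(dir, "zones.tsv"))
  write_tsv(sim$design, file.path(dir, "design.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth_labels.tsv"))
  if (!is.null(sim$series_truth))
    write_tsv(sim$series_truth, file.path(dir, "truth_series.tsv"))
  invisible(dir)
}
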