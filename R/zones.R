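#' Assign genomic positions to chromosomal zones
#'
#' Looks up, for each (chromosome, position) pair, the unique zone whose
#' half-open interval `[start, end)` contains the position.  Gene positions
#' are taken as the midpoint `floor((start + end) / 2)` by convention (see
#' [gene_midpoints()]).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions.
#' @param zones a `zone_partition` (see [read_zones()]).
#' @param ids optional identifiers used in error messages.
#' @return character vector of zone labels.
#' @export
assign_zone <- function(chrom, pos, zones, ids = NULL) {
  stopifnot(inherits(zones, "zone_partition"))
  if (is.null(ids)) ids <- paste0(chrom, ":", pos)
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    z <- zones[zones$chrom == ch, , drop = FALSE]
    if (nrow(z) == 0L)
      stop("chromosome absent from zone partition: ", ch)
    i <- findInterval(pos[sel], z$start)
    ok <- i >= 1L & pos[sel] < z$end[pmax(i, 1L)]
    if (any(!ok))
      stop("position outside all zone intervals: ", ids[sel][!ok][1L])
    out[sel] <- z$zone[i]
  }
  out
}

#' Gene midpoints of a triad table
#'
#' @param triads a `triad_table`.
#' @param subgenome optional subgenome filter (`"A"`, `"B"`, `"D"`).
#' @return data frame with `gene_id`, `triad_id`, `subgenome`, `chrom`,
#'   `pos` (midpoint, 0-based).
#' @export
gene_midpoints <- function(triads, subgenome = NULL) {
  stopifnot(inherits(triads, "triad_table"))
  g <- triads$genes
  if (!is.null(subgenome)) g <- g[g$subgenome %in% subgenome, , drop = FALSE]
  data.frame(gene_id = g$gene_id, triad_id = g$triad_id,
             subgenome = g$subgenome, chrom = g$chrom,
             pos = floor((g$start + g$end) / 2),
             stringsAsFactors = FALSE)
}

#' Zone distribution of labelled genes
#'
#' Summarises how a set of labelled genes distributes over the chromosome
#' zones: per (label, zone) the gene count, the density per Mb of zone
#' span, and the fraction of the label's genes falling in the zone.
#' Optionally each (label, zone) share is tested against a background set
#' with [two_proportion_test()].
#'
#' @param genes data frame with columns `chrom`, `pos`, `label` (and
#'   optionally `gene_id`).
#' @param zones a `zone_partition`.
#' @param background optional data frame of background genes (`chrom`,
#'   `pos`); when supplied, a Yates-corrected two-proportion test compares
#'   each label's zone share with the background zone share.
#' @return an object of class `zone_summary`: a data frame with `label`,
#'   `zone`, `zone_class` (distal/interstitial/proximal), `n`,
#'   `density_per_mb`, `fraction`, and (with background) `background_n`,
#'   `p_value`.
#' @export
zone_distribution <- function(genes, zones, background = NULL) {
  if (nrow(genes) == 0L) stop("empty gene table")
  stopifnot(inherits(zones, "zone_partition"))
  if (is.null(genes$label)) genes$label <- "all"
  genes$zone <- assign_zone(genes$chrom, genes$pos, zones, genes$gene_id)
  span_mb <- vapply(ZONES, function(z)
    sum(zones$end[zones$zone == z] - zones$start[zones$zone == z]) / 1e6, 0)
  bg_n <- NULL
  if (!is.null(background)) {
    bz <- assign_zone(background$chrom, background$pos, zones)
    bg_n <- vapply(ZONES, function(z) sum(bz == z), 0L)
  }
  out <- lapply(split(genes, genes$label), function(d) {
    n <- vapply(ZONES, function(z) sum(d$zone == z), 0L)
    res <- data.frame(label = d$label[1L], zone = ZONES,
                      zone_class = unname(ZONE_CLASS[ZONES]), n = n,
                      density_per_mb = n / span_mb,
                      fraction = n / nrow(d), stringsAsFactors = FALSE)
    if (!is.null(bg_n)) {
      res$background_n <- bg_n
      res$p_value <- vapply(seq_along(ZONES), function(i)
        two_proportion_test(n[i], nrow(d), bg_n[i], sum(bg_n))$p.value, 0)
    }
    res
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  class(out) <- c("zone_summary", "data.frame")
  out
}

#' Zone distribution of tracked triads
#'
#' Convenience wrapper locating each tracked triad by one homoeolog's gene
#' midpoint and summarising the zone distribution of its series label,
#' against all tracked triads as background.
#'
#' @param tracks a `series_tracks` object.
#' @param triads a `triad_table`.
#' @param zones a `zone_partition`.
#' @param assay assay to summarise (default: first in `tracks`).
#' @param subgenome homoeolog whose position represents the triad
#'   (default `"A"`).
#' @return a `zone_summary` (see [zone_distribution()]).
#' @export
track_zone_distribution <- function(tracks, triads, zones,
                                    assay = NULL, subgenome = "A") {
  stopifnot(inherits(tracks, "series_tracks"))
  if (is.null(assay)) assay <- tracks$assay[1L]
  tr <- tracks[tracks$assay == assay & tracks$label != "not_tracked", ]
  mid <- gene_midpoints(triads, subgenome)
  idx <- match(tr$triad_id, mid$triad_id)
  genes <- data.frame(gene_id = mid$gene_id[idx], chrom = mid$chrom[idx],
                      pos = mid$pos[idx], label = tr$label,
                      stringsAsFactors = FALSE)
  zone_distribution(genes, zones,
                    background = genes[c("chrom", "pos")])
}
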