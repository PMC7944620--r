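#' Group label for the domestication series (WTW -> DTW -> ETW)
#'
#' Classifies a triad's category sequence across the three genotypes:
#' \describe{
#'   \item{I}{no change: `c1 = c2 = c3`.}
#'   \item{II}{change arising in DTW and maintained in ETW:
#'     `c1 != c2`, `c2 = c3`.}
#'   \item{III}{change arising in DTW and changing again in ETW:
#'     `c1 != c2`, `c2 != c3` (covers both reversion to the original state
#'     and a new third state).}
#'   \item{IV}{change specific to ETW: `c1 = c2`, `c2 != c3`.}
#' }
#' A triad unmodified at any genotype carries no category there and is
#' `not_tracked`.
#'
#' @param c1,c2,c3 category vectors (`A_eq_B`, `A_gt_B`, `A_lt_B`, or
#'   `unmodified`) at the three genotypes, in series order.
#' @return character vector of labels `I`/`II`/`III`/`IV`/`not_tracked`.
#' @export
track_domestication <- function(c1, c2, c3) {
  check_categories(c1, c2, c3)
  lab <- ifelse(c1 == c2,
                ifelse(c2 == c3, "I", "IV"),
                ifelse(c2 == c3, "II", "III"))
  lab[c1 == UNMODIFIED | c2 == UNMODIFIED | c3 == UNMODIFIED] <- "not_tracked"
  lab
}

#' Pattern label for the ploidy-transition series (TAA10 -> ETW -> XX329)
#'
#' \describe{
#'   \item{I}{conserved throughout: `c1 = c2 = c3`.}
#'   \item{II}{reversible change tied to tetraploid extraction:
#'     `c1 != c2`, `c1 = c3`.}
#'   \item{III}{change arising only in the resynthesized hexaploid:
#'     `c1 = c2`, `c2 != c3`.}
#'   \item{IV}{change upon extraction maintained after resynthesis:
#'     `c1 != c2`, `c2 = c3`.}
#' }
#' Sequences with all three categories distinct satisfy none of the four
#' verbal definitions; they are labelled `III` (change present in the
#' resynthesized hexaploid) and flagged by `all_distinct` in
#' [track_series()] output so they can be counted separately.
#'
#' @inheritParams track_domestication
#' @return character vector of labels.
#' @export
track_ploidy <- function(c1, c2, c3) {
  check_categories(c1, c2, c3)
  lab <- ifelse(c1 == c2,
                ifelse(c2 == c3, "I", "III"),
                ifelse(c1 == c3, "II",
                       ifelse(c2 == c3, "IV", "III")))
  lab[c1 == UNMODIFIED | c2 == UNMODIFIED | c3 == UNMODIFIED] <- "not_tracked"
  lab
}

check_categories <- function(...) {
  vals <- unlist(list(...))
  bad <- setdiff(unique(vals), c(CATEGORIES, UNMODIFIED, NA))
  if (length(bad)) stop("unknown category: ", bad[1L])
  invisible(NULL)
}

#' Track per-triad categories across a three-genotype series
#'
#' @param calls a `bias_calls` object covering the three genotypes of the
#'   series.
#' @param series `"domestication"` (WTW -> DTW -> ETW, Group I-IV) or
#'   `"ploidy"` (TAA10 -> ETW -> XX329, Pattern I-IV).
#' @param genotypes optional custom genotype order (length 3) overriding
#'   the series default.
#' @return an object of class `series_tracks`: a data frame with
#'   `triad_id`, `assay`, the three per-genotype categories (`c1`, `c2`,
#'   `c3`), `label`, and `all_distinct` (`TRUE` when the three categories
#'   are pairwise distinct).
#' @export
track_series <- function(calls, series = c("domestication", "ploidy"),
                         genotypes = NULL) {
  stopifnot(inherits(calls, "bias_calls"))
  series <- match.arg(series)
  if (is.null(genotypes)) genotypes <- series_genotypes(series)
  if (length(genotypes) != 3L) stop("a series has exactly 3 genotypes")
  missing <- setdiff(genotypes, unique(calls$genotype))
  if (length(missing)) stop("genotype absent from calls: ", missing[1L])
  rule <- if (series == "domestication") track_domestication else track_ploidy
  out <- lapply(split(calls, calls$assay), function(d) {
    wide <- lapply(genotypes, function(g) {
      di <- d[d$genotype == g, ]
      structure(di$category, names = di$triad_id)
    })
    ids <- names(wide[[1L]])
    c1 <- wide[[1L]][ids]; c2 <- wide[[2L]][ids]; c3 <- wide[[3L]][ids]
    data.frame(triad_id = ids, assay = d$assay[1L],
               c1 = unname(c1), c2 = unname(c2), c3 = unname(c3),
               label = rule(c1, c2, c3),
               all_distinct = c1 != c2 & c2 != c3 & c1 != c3,
               stringsAsFactors = FALSE)
  })
  tracks <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(tracks, "series") <- series
  attr(tracks, "genotypes") <- genotypes
  class(tracks) <- c("series_tracks", "data.frame")
  tracks
}

#' Tabulate series labels per assay
#'
#' @param tracks a `series_tracks` object (or a data frame with `assay` and
#'   `label` columns).
#' @return data frame per (assay, label in I-IV): `n`, `proportion` (over
#'   tracked triads of that assay; proportions sum to 1), and
#'   `n_tracked`/`n_not_tracked` totals.
#' @export
tabulate_tracks <- function(tracks) {
  if (nrow(tracks) == 0L) stop("empty track table")
  labels <- c("I", "II", "III", "IV")
  out <- lapply(split(tracks, tracks$assay), function(d) {
    tr <- d$label[d$label != "not_tracked"]
    n <- vapply(labels, function(l) sum(tr == l), 0L)
    data.frame(assay = d$assay[1L], label = labels, n = n,
               proportion = if (length(tr)) n / length(tr) else NA_real_,
               n_tracked = length(tr),
               n_not_tracked = sum(d$label == "not_tracked"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
print.series_tracks <- function(x, ...) {
  cat("Series tracks (", attr(x, "series"), ": ",
      paste(attr(x, "genotypes"), collapse = " -> "), ")\n", sep = "")
  print(tabulate_tracks(x), row.names = FALSE)
  invisible(x)
}
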