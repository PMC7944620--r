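#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' triad-structured gene-level counts for histone-mark ChIP and RNA assays
#' across wheat genotypes, with planted bias categories and
#' negative-binomial replicate noise.
#'
#' @param n_triads number of homoeolog triads to simulate.
#' @param genotypes character vector of genotypes to emit.  Defaults to the
#'   three tetraploid lines (WTW, DTW, ETW: wild, domesticated and
#'   extracted tetraploid wheat).  Ploidy per genotype is looked up in
#'   `ploidy`.
#' @param assays assays to emit; any of `"H3K4me3"`, `"H3K27me3"`, `"RNA"`.
#' @param replicates biological replicates per (genotype, assay); default 2.
#' @param category_props named list (by assay) of category proportions
#'   `c(A_eq_B, A_gt_B, A_lt_B, unmodified)`, each summing to 1.  May be
#'   nested one level deeper by genotype.  Defaults emulate the relative
#'   magnitudes observed in tetraploid wheat: mostly balanced triads, a
#'   slight A-ward excess among biased ones, and a mark-dependent
#'   unmodified fraction (larger for H3K27me3 than H3K4me3).
#' @param mu mean per-homoeolog signal level of modified triads, in TPM.
#'   The triad total is drawn log-normally with expectation `2 * mu`.
#' @param sdlog log-scale spread of the triad signal level (log-normal
#'   shape; 1 gives the heavy-tailed TPM distribution typical of
#'   expression-like data).
#' @param s_min floor on the triad signal total (TPM).  Keeps planted
#'   modified triads unambiguously above the 0.5 TPM modification filter.
#' @param dispersion named numeric (by assay): negative-binomial size
#'   parameter `phi` (count variance `mu + mu^2/phi`).  `Inf` switches the
#'   generator to its noiseless mode (counts equal to rounded
#'   expectations).  Defaults reproduce replicate TPM correlations close to
#'   those reported for real data (about 0.99 for H3K4me3, 0.9 for
#'   H3K27me3).
#' @param epsilon baseline TPM of unmodified homoeologs; each is drawn
#'   uniformly on `[0, epsilon]`.  Must be below the 0.5 TPM filter.
#' @param rel_biased interval from which `rel_A` of an A>B triad is drawn
#'   (mirrored for A<B).
#' @param rel_balanced interval from which `rel_A` of a balanced triad is
#'   drawn.
#' @param lib_per_1k sequencing depth: library size per 1000 triads
#'   (default 1e6 reads).
#' @param n_background number of non-triad background genes absorbing the
#'   remaining TPM mass; defaults to `2 * n_triads`.
#' @param ploidy named character vector mapping genotype to subgenome
#'   content (`"AB"`, `"ABD"` or `"D"`).  Unlisted genotypes default to
#'   `"AB"`.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_triads,
                       genotypes = c("WTW", "DTW", "ETW"),
                       assays = c("H3K4me3", "H3K27me3"),
                       replicates = 2L,
                       category_props = NULL,
                       mu = 30,
                       sdlog = 1,
                       s_min = 5,
                       dispersion = c(H3K4me3 = 150, H3K27me3 = 10,
                                      RNA = 20),
                       epsilon = 0.1,
                       rel_biased = c(0.80, 0.95),
                       rel_balanced = c(0.45, 0.55),
                       lib_per_1k = 1e6,
                       n_background = NULL,
                       ploidy = c(WTW = "AB", DTW = "AB", ETW = "AB",
                                  TAA10 = "ABD", XX329 = "ABD",
                                  AeTauschii = "D"),
                       seed = 1L) {
  if (n_triads < 1L) stop("n_triads must be >= 1")
  if (epsilon >= 0.5) stop("epsilon must be < 0.5 (the modification filter)")
  if (any(is.finite(unlist(dispersion)) & unlist(dispersion) <= 0))
    stop("dispersion must be > 0")
  if (is.null(category_props))
    category_props <- list(
      H3K4me3  = c(A_eq_B = 0.730, A_gt_B = 0.048, A_lt_B = 0.032,
                   unmodified = 0.190),
      H3K27me3 = c(A_eq_B = 0.410, A_gt_B = 0.045, A_lt_B = 0.037,
                   unmodified = 0.508),
      RNA      = c(A_eq_B = 0.550, A_gt_B = 0.120, A_lt_B = 0.100,
                   unmodified = 0.230))
  for (a in assays) {
    pr <- category_props[[a]]
    if (is.null(pr)) stop("no category proportions for assay ", a)
    if (!is.list(pr)) pr <- list(pr)
    for (p in pr)
      if (abs(sum(p) - 1) > 1e-9)
        stop("category proportions for assay ", a, " must sum to 1")
  }
  structure(list(
    n_triads = as.integer(n_triads), genotypes = genotypes, assays = assays,
    replicates = as.integer(replicates), category_props = category_props,
    mu = mu, sdlog = sdlog, s_min = s_min, dispersion = dispersion,
    epsilon = epsilon, rel_biased = rel_biased, rel_balanced = rel_balanced,
    lib_per_1k = lib_per_1k,
    n_background = as.integer(n_background %||% (2L * n_triads)),
    ploidy = ploidy, seed = as.integer(seed)), class = "sim_config")
}

# Deterministic multinomial apportionment: floor(n*p) plus largest-remainder
# top-up, so planted frequencies are exact rather than sampled.
round_multinomial <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, seq_along(p), decreasing = c(TRUE, FALSE),
                 method = "radix")
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

sim_props <- function(cfg, genotype, assay) {
  pr <- cfg$category_props[[assay]]
  if (is.list(pr)) pr <- pr[[genotype]] %||% pr[[1L]]
  pr
}

sim_ploidy <- function(cfg, genotype) {
  p <- cfg$ploidy[genotype]
  if (is.na(p)) "AB" else unname(p)
}

# Genome scaffold: triad genes on chr1A/1B/1D, background genes on
# chr2A/2B/2D, 4 kb spacing, lengths uniform on [600, 3000] bp, and a
# 5-zone partition per chromosome (R1 15%, R2a 25%, C 20%, R2b 25%, R3 15%).
sim_scaffold <- function(cfg) {
  n <- cfg$n_triads
  ids <- sprintf("TRD%05d", seq_len(n))
  gene <- function(sub) sprintf("G%05d%s", seq_len(n), sub)
  triads <- data.frame(triad_id = ids, gene_A = gene("A"),
                       gene_B = gene("B"), gene_D = gene("D"),
                       stringsAsFactors = FALSE)
  lens <- function(m) round(runif(m, 600, 3000))
  starts <- (seq_len(n) - 1L) * 4000
  coords <- do.call(rbind, lapply(c(A = "A", B = "B", D = "D"), function(s) {
    L <- lens(n)
    data.frame(gene_id = gene(s), chrom = paste0("chr1", s),
               start = starts, end = starts + L, length = L,
               stringsAsFactors = FALSE)
  }))
  nb <- cfg$n_background
  bgsub <- rep(c("A", "B", "D"), length.out = nb)
  bgpos <- (seq_len(nb) - 1L) %/% 3L * 4000
  Lb <- lens(nb)
  bg <- data.frame(gene_id = sprintf("BG%05d", seq_len(nb)),
                   chrom = paste0("chr2", bgsub),
                   start = bgpos, end = bgpos + Lb, length = Lb,
                   stringsAsFactors = FALSE)
  all_coords <- rbind(coords, bg)
  rownames(all_coords) <- all_coords$gene_id
  zones <- do.call(rbind, lapply(split(all_coords, all_coords$chrom),
    function(g) {
      len <- max(g$end)
      cut <- round(len * cumsum(c(0, 0.15, 0.25, 0.20, 0.25, 0.15)))
      cut[6L] <- len
      data.frame(chrom = g$chrom[1L], start = cut[1:5], end = cut[2:6],
                 zone = ZONES, stringsAsFactors = FALSE)
    }))
  list(triads = triad_table(triads, coords), all_coords = all_coords,
       zones = zone_partition(zones))
}

# Draw per-triad planted TPMs for one (genotype, assay): categories by
# exact apportionment, triad signal total S log-normal (E[S] = 2*mu,
# floored at s_min), rel_A by category.  Returns the truth rows and the
# planted TPM for the A/B/D homoeologs.
sim_signal <- function(cfg, genotype, assay) {
  n <- cfg$n_triads
  pr <- sim_props(cfg, genotype, assay)
  counts <- round_multinomial(n, pr)
  cats <- sample(rep(c(CATEGORIES, UNMODIFIED), counts))
  plant_signal(cfg, cats, genotype)
}

# Shared emitter: given planted categories, draw rel_A, S and per-homoeolog
# TPM consistent with the genotype's ploidy.
plant_signal <- function(cfg, cats, genotype) {
  n <- length(cats)
  S <- pmax(cfg$s_min,
            2 * cfg$mu * rlnorm(n, -cfg$sdlog^2 / 2, cfg$sdlog))
  rel <- numeric(n)
  rel[cats == "A_eq_B"] <- runif(sum(cats == "A_eq_B"),
                                 cfg$rel_balanced[1L], cfg$rel_balanced[2L])
  rel[cats == "A_gt_B"] <- runif(sum(cats == "A_gt_B"),
                                 cfg$rel_biased[1L], cfg$rel_biased[2L])
  rel[cats == "A_lt_B"] <- 1 - runif(sum(cats == "A_lt_B"),
                                     cfg$rel_biased[1L], cfg$rel_biased[2L])
  unmod <- cats == UNMODIFIED
  tpm_A <- ifelse(unmod, runif(n, 0, cfg$epsilon), S * rel)
  tpm_B <- ifelse(unmod, runif(n, 0, cfg$epsilon), S * (1 - rel))
  tpm_D <- ifelse(unmod, runif(n, 0, cfg$epsilon), S / 2)
  pl <- sim_ploidy(cfg, genotype)
  if (pl == "AB") tpm_D[] <- 0
  if (pl == "D") { tpm_A[] <- 0; tpm_B[] <- 0 }
  rel[unmod] <- NA_real_
  list(category = cats, rel_A = rel, S = S,
       tpm = cbind(A = tpm_A, B = tpm_B, D = tpm_D))
}

# Convert one sample's planted TPM vector (over the full gene universe,
# background genes absorbing the remaining mass so the planted values are
# exact expected TPMs) into replicate count vectors.
sim_counts <- function(cfg, tpm_triad, lengths, phi) {
  n <- cfg$n_triads; nb <- cfg$n_background
  tot <- sum(tpm_triad)
  if (tot >= 0.9e6)
    stop("planted signal mass ", round(tot), " TPM leaves no room for ",
         "background; lower mu or n_triads")
  w <- rlnorm(nb, -cfg$sdlog^2 / 2, cfg$sdlog)
  tpm <- c(tpm_triad, (1e6 - tot) * w / sum(w))
  lib <- cfg$lib_per_1k * n / 1000
  # Noiseless mode emulates the infinite-depth limit: the library is
  # scaled up 1000-fold and counts are the rounded expectations, so count
  # quantization cannot blur the planted categories or the 0.5 TPM filter.
  if (is.infinite(phi)) lib <- lib * 1000
  mu_counts <- lib * (tpm * lengths) / sum(tpm * lengths)
  reps <- lapply(seq_len(cfg$replicates), function(r) {
    if (is.infinite(phi)) round(mu_counts)
    else rnbinom(length(mu_counts), mu = mu_counts, size = phi)
  })
  do.call(cbind, reps)
}

#' Simulate a triad-structured dataset with planted truth
#'
#' Generates gene-level count tables for every (genotype, assay, replicate)
#' in the configuration, together with the triad mapping, gene coordinates,
#' a chromosomal zone partition and the planted category labels.  With the
#' same seed the output is reproduced exactly.
#'
#' @param cfg a [sim_config()] object.
#' @return an object of class `triad_sim`: a list with elements `config`,
#'   `triads` (a `triad_table`), `all_coords` (triad plus background gene
#'   coordinates), `zones`, `design` (sample sheet), `counts` (genes x
#'   samples integer matrix), `lengths`, and `truth` (per triad x genotype
#'   x assay planted category and `rel_A`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sc <- sim_scaffold(cfg)
  emit_sim(cfg, sc, planted = NULL)
}

#' Simulate a three-genotype series with planted transition labels
#'
#' Plants per-triad category sequences across a three-genotype series so
#' that the transition labels (Group I-IV for the domestication series
#' WTW -> DTW -> ETW; Pattern I-IV for the ploidy-transition series
#' TAA10 -> ETW -> XX329) realize the requested frequencies exactly (by
#' largest-remainder apportionment).  A triad planted as unmodified is
#' unmodified at all three genotypes and is excluded from the label
#' apportionment (it is untracked downstream).
#'
#' @param cfg a [sim_config()] object; its `genotypes` are overridden by
#'   the series.
#' @param label_freqs numeric vector of length 4 over labels I-IV, summing
#'   to 1.
#' @param series `"domestication"` (labels by Group rules) or `"ploidy"`
#'   (labels by Pattern rules).
#' @return a `triad_sim` object (see [simulate_dataset()]) whose `truth`
#'   holds the planted per-genotype categories and whose `series_truth`
#'   holds the planted per-triad label per assay.
#' @export
simulate_series <- function(cfg, label_freqs, series = c("domestication",
                                                         "ploidy")) {
  stopifnot(inherits(cfg, "sim_config"))
  series <- match.arg(series)
  if (length(label_freqs) != 4L)
    stop("label_freqs must have length 4 (labels I-IV)")
  if (abs(sum(label_freqs) - 1) > 1e-9)
    stop("label_freqs must sum to 1")
  genotypes <- series_genotypes(series)
  cfg$genotypes <- genotypes
  set.seed(cfg$seed)
  sc <- sim_scaffold(cfg)
  n <- cfg$n_triads
  labels <- c("I", "II", "III", "IV")
  planted <- list()
  for (a in cfg$assays) {
    pr <- sim_props(cfg, genotypes[1L], a)
    n_un <- round_multinomial(n, c(1 - pr[[UNMODIFIED]], pr[[UNMODIFIED]]))[2L]
    is_un <- seq_len(n) %in% sample(n, n_un)
    n_tr <- n - n_un
    lab <- rep(NA_character_, n)
    lab[!is_un] <- sample(rep(labels, round_multinomial(n_tr, label_freqs)))
    base_pr <- pr[CATEGORIES] / sum(pr[CATEGORIES])
    c1 <- sample(CATEGORIES, n, TRUE, base_pr)
    other <- function(cat) vapply(cat, function(cc)
      sample(setdiff(CATEGORIES, cc), 1L), "")
    c2 <- c1; c3 <- c1
    if (series == "domestication") {
      # I: c1=c2=c3; II: c1!=c2=c3; III: c1!=c2, c2!=c3; IV: c1=c2!=c3
      ii <- !is_un & lab == "II";  c2[ii] <- other(c1[ii]); c3[ii] <- c2[ii]
      ii <- !is_un & lab == "III"; c2[ii] <- other(c1[ii]); c3[ii] <- other(c2[ii])
      ii <- !is_un & lab == "IV";  c3[ii] <- other(c2[ii])
    } else {
      # I: c1=c2=c3; II: c1!=c2, c1=c3; III: c1=c2!=c3; IV: c1!=c2=c3
      ii <- !is_un & lab == "II";  c2[ii] <- other(c1[ii])
      ii <- !is_un & lab == "III"; c3[ii] <- other(c2[ii])
      ii <- !is_un & lab == "IV";  c2[ii] <- other(c1[ii]); c3[ii] <- c2[ii]
    }
    cats <- cbind(c1, c2, c3)
    cats[is_un, ] <- UNMODIFIED
    colnames(cats) <- genotypes
    planted[[a]] <- list(cats = cats, label = lab)
  }
  sim <- emit_sim(cfg, sc, planted = planted)
  sim$series <- series
  sim$series_genotypes <- genotypes
  sim$series_truth <- do.call(rbind, lapply(cfg$assays, function(a)
    data.frame(triad_id = sc$triads$triads$triad_id, assay = a,
               label = ifelse(is.na(planted[[a]]$label), "not_tracked",
                              planted[[a]]$label),
               stringsAsFactors = FALSE)))
  sim
}

#' Genotype order of a tracking series
#'
#' @param series `"domestication"` or `"ploidy"`.
#' @return character vector of the three genotypes in series order.
#' @export
series_genotypes <- function(series = c("domestication", "ploidy")) {
  switch(match.arg(series),
         domestication = c("WTW", "DTW", "ETW"),
         ploidy = c("TAA10", "ETW", "XX329"))
}

# Core emitter shared by simulate_dataset and simulate_series.
emit_sim <- function(cfg, sc, planted = NULL) {
  genes <- sc$triads$genes
  lengths <- structure(sc$all_coords$length, names = sc$all_coords$gene_id)
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        assay = cfg$assays, genotype = cfg$genotypes,
                        stringsAsFactors = FALSE)[, 3:1]
  design$sample_id <- sprintf("%s_%s_r%d", design$genotype, design$assay,
                              design$replicate)
  counts <- matrix(0L, nrow = length(lengths), ncol = nrow(design),
                   dimnames = list(names(lengths), design$sample_id))
  truth <- list()
  ord_A <- match(sc$triads$triads$gene_A, names(lengths))
  ord_B <- match(sc$triads$triads$gene_B, names(lengths))
  ord_D <- match(sc$triads$triads$gene_D, names(lengths))
  for (g in cfg$genotypes) for (a in cfg$assays) {
    if (is.null(planted)) {
      sig <- sim_signal(cfg, g, a)
    } else {
      sig <- plant_signal(cfg, planted[[a]]$cats[, g], g)
    }
    tpm_vec <- numeric(length(lengths))
    tpm_vec[ord_A] <- sig$tpm[, "A"]
    tpm_vec[ord_B] <- sig$tpm[, "B"]
    tpm_vec[ord_D] <- sig$tpm[, "D"]
    phi <- cfg$dispersion[[a]] %||% Inf
    cnt <- sim_counts(cfg, tpm_vec[seq_len(3 * cfg$n_triads)],
                      lengths, phi)
    sel <- design$genotype == g & design$assay == a
    counts[, sel] <- cnt
    truth[[paste(g, a)]] <- data.frame(
      triad_id = sc$triads$triads$triad_id, genotype = g, assay = a,
      category = sig$category, rel_A = sig$rel_A,
      stringsAsFactors = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(list(config = cfg, triads = sc$triads,
                 all_coords = sc$all_coords, zones = sc$zones,
                 design = design[c("sample_id", "genotype", "assay",
                                   "replicate")],
                 counts = counts, lengths = lengths,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE))),
            class = "triad_sim")
}

#' @export
print.triad_sim <- function(x, ...) {
  cat("Simulated triad dataset:", x$config$n_triads, "triads,",
      ncol(x$counts), "samples (",
      paste(unique(x$design$genotype), collapse = ", "), ") x (",
      paste(unique(x$design$assay), collapse = ", "), ")\n")
  if (!is.null(x$series))
    cat("Series:", x$series, "(",
        paste(x$series_genotypes, collapse = " -> "), ")\n")
  invisible(x)
}
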