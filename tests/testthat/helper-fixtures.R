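# Small fixtures built in code.

toy_coords <- function(n = 3L) {
  gene <- function(sub) sprintf("g%d%s", seq_len(n), sub)
  starts <- (seq_len(n) - 1L) * 1000L
  do.call(rbind, lapply(c("A", "B", "D"), function(s)
    data.frame(gene_id = gene(s), chrom = paste0("chr1", s),
               start = starts, end = starts + 500L,
               stringsAsFactors = FALSE)))
}

toy_triads <- function(n = 3L) {
  triad_table(
    data.frame(triad_id = sprintf("t%d", seq_len(n)),
               gene_A = sprintf("g%dA", seq_len(n)),
               gene_B = sprintf("g%dB", seq_len(n)),
               gene_D = sprintf("g%dD", seq_len(n)),
               stringsAsFactors = FALSE),
    toy_coords(n))
}

toy_zones <- function(chroms = c("chr1A", "chr1B", "chr1D"), len = 1000L) {
  zone_partition(do.call(rbind, lapply(chroms, function(ch) {
    cut <- round(len * cumsum(c(0, .2, .2, .2, .2, .2)))
    data.frame(chrom = ch, start = cut[1:5], end = cut[2:6],
               zone = c("R1", "R2a", "C", "R2b", "R3"),
               stringsAsFactors = FALSE)
  })))
}

write_counts_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A minimal aggregated_signal from a named tpm matrix whose columns are
# "<genotype>.<assay>".
toy_aggregated <- function(tpm, genotypes, assays) {
  structure(list(tpm = tpm,
                 groups = data.frame(genotype = genotypes, assay = assays,
                                     stringsAsFactors = FALSE),
                 method = "mean"),
            class = "aggregated_signal")
}
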