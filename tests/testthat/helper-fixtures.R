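# Small hand-built gene models used across test files.
#
# two_transcript_models():
#   one gene on [0, 300) with transcripts
#     T1: exons [0,50) [100,150) [200,300); UTR5 [0,20), CDS to [200,260),
#         UTR3 [260,300)
#     T2: exons [0,50) [200,300)
# neighbour_models(): genes A [0,100) and B [50,150) overlapping, single
#   exon each, no CDS/UTR annotation.

two_transcript_models <- function() {
  genes <- data.frame(gene_id = "gA", chrom = "chr1", start = 0L, end = 300L,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = c("gA.T1", "gA.T2"), gene_id = "gA",
                   stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = "gA",
    transcript_id = c("gA.T1", "gA.T1", "gA.T1", "gA.T2", "gA.T2"),
    start = c(0L, 100L, 200L, 0L, 200L),
    end = c(50L, 150L, 300L, 50L, 300L), stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = "gA",
                    transcript_id = c("gA.T1", "gA.T1", "gA.T1"),
                    start = c(20L, 100L, 200L), end = c(50L, 150L, 260L),
                    stringsAsFactors = FALSE)
  utr5 <- data.frame(gene_id = "gA", transcript_id = "gA.T1",
                     start = 0L, end = 20L, stringsAsFactors = FALSE)
  utr3 <- data.frame(gene_id = "gA", transcript_id = "gA.T1",
                     start = 260L, end = 300L, stringsAsFactors = FALSE)
  gene_models(genes, tx, exons, cds = cds, utr5 = utr5, utr3 = utr3)
}

neighbour_models <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(0L, 50L), end = c(100L, 150L), strand = "+",
                      stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = c("gA.T1", "gB.T1"),
                   gene_id = c("gA", "gB"), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gB"),
                      transcript_id = c("gA.T1", "gB.T1"),
                      start = c(0L, 50L), end = c(100L, 150L),
                      stringsAsFactors = FALSE)
  gene_models(genes, tx, exons)
}

# brute-force per-base overlap counting oracle used by interval tests
brute_force_counts <- function(intervals, models) {
  g <- models$genes
  counts <- stats::setNames(integer(nrow(g)), g$gene_id)
  if (!nrow(intervals)) return(counts)
  for (k in seq_len(nrow(intervals))) {
    bases <- seq.int(intervals$start[k], intervals$end[k] - 1L)
    for (i in seq_len(nrow(g))) {
      if (intervals$chrom[k] == g$chrom[i] &&
          any(bases >= g$start[i] & bases < g$end[i]))
        counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# brute-force per-base covered-fraction oracle
brute_force_density <- function(segments, models) {
  g <- models$genes
  dens <- stats::setNames(numeric(nrow(g)), g$gene_id)
  for (i in seq_len(nrow(g))) {
    bases <- seq.int(g$start[i], g$end[i] - 1L)
    covered <- rep(FALSE, length(bases))
    for (k in seq_len(nrow(segments))) {
      if (segments$chrom[k] != g$chrom[i]) next
      covered <- covered | (bases >= segments$start[k] &
                              bases < segments$end[k])
    }
    dens[i] <- mean(covered)
  }
  dens
}

# random small gene set + intervals on one chromosome for oracle comparisons
random_interval_instance <- function(seed, max_genes = 10, max_intervals = 50,
                                     range = 500L) {
  set.seed(seed)
  n_g <- sample.int(max_genes, 1)
  starts <- sort(sample.int(range - 20L, n_g))
  ends <- pmin(range, starts + sample(5:60, n_g, replace = TRUE))
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_g)),
                      chrom = "chr1", start = starts, end = ends,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = paste0(genes$gene_id, ".T1"),
                   gene_id = genes$gene_id, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id,
                      transcript_id = tx$transcript_id,
                      start = genes$start, end = genes$end,
                      stringsAsFactors = FALSE)
  n_i <- sample.int(max_intervals, 1)
  is <- sample.int(range - 10L, n_i, replace = TRUE)
  intervals <- data.frame(chrom = "chr1", start = is,
                          end = is + sample(1:30, n_i, replace = TRUE),
                          stringsAsFactors = FALSE)
  list(models = gene_models(genes, tx, exons), intervals = intervals)
}
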