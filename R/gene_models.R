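#' Gene models with exon/CDS/UTR structure
#'
#' A `gene_models` object holds gene, transcript and sub-transcript intervals
#' in 0-based half-open coordinates (the internal convention throughout the
#' package; GTF input/output is converted at the boundary). It is a list of
#' data frames:
#' \describe{
#'   \item{genes}{`gene_id`, `chrom`, `start`, `end`, `strand`}
#'   \item{transcripts}{`transcript_id`, `gene_id`}
#'   \item{exons, cds, utr5, utr3}{`gene_id`, `transcript_id`, `start`, `end`}
#' }
#' Exons of one transcript must be non-overlapping and sorted, and every exon
#' must lie within its gene's span.
#'
#' @param genes,transcripts,exons data frames as described above.
#' @param cds,utr5,utr3 optional data frames (default: empty).
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons,
                        cds = NULL, utr5 = NULL, utr3 = NULL) {
  empty <- data.frame(gene_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  check_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  check_columns(transcripts, c("transcript_id", "gene_id"), "transcripts")
  check_columns(exons, c("gene_id", "transcript_id", "start", "end"), "exons")
  if (is.null(cds)) cds <- empty
  if (is.null(utr5)) utr5 <- empty
  if (is.null(utr3)) utr3 <- empty

  if (any(genes$end <= genes$start))
    stopf("gene spans must have positive length")
  if (nrow(exons)) {
    if (!all(exons$gene_id %in% genes$gene_id))
      stopf("exon rows reference unknown gene ids")
    sp <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(exons$start < sp$start | exons$end > sp$end))
      stopf("exons must lie within their gene span")
    ok <- vapply(split(exons, exons$transcript_id), function(e) {
      e <- e[order(e$start), ]
      all(e$end > e$start) && (nrow(e) < 2 ||
        all(e$start[-1] >= e$end[-nrow(e)]))
    }, logical(1))
    if (!all(ok))
      stopf("exons of transcript(s) %s overlap or are degenerate",
            paste(names(ok)[!ok], collapse = ", "))
  }
  tx_n <- table(factor(exons$transcript_id, levels = transcripts$transcript_id))
  if (nrow(transcripts) && any(tx_n == 0))
    stopf("transcript(s) with 0 exons: %s",
          paste(names(tx_n)[tx_n == 0], collapse = ", "))
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, utr5 = utr5, utr3 = utr3),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

# GRanges view of an interval data frame (0-based half-open -> 1-based closed)
intervals_as_granges <- function(df, chrom = df$chrom) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

genes_as_granges <- function(models) {
  gr <- intervals_as_granges(models$genes)
  names(gr) <- models$genes$gene_id
  gr
}

#' Read gene models from a GTF file
#'
#' GTF coordinates are 1-based inclusive and converted to the internal 0-based
#' half-open convention on read. Recognized feature types are `gene`,
#' `transcript`, `exon`, `CDS`, `five_prime_utr` and `three_prime_utr`;
#' gene and transcript identity come from the `gene_id`/`transcript_id`
#' attributes.
#'
#' @param path path to a GTF file.
#' @return a [gene_models] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = as.character(gr$gene_id),
                   transcript_id = if (is.null(gr$transcript_id))
                     NA_character_ else as.character(gr$transcript_id),
                   stringsAsFactors = FALSE)
  part <- function(tp) {
    p <- df[df$type == tp, c("gene_id", "transcript_id", "start", "end")]
    rownames(p) <- NULL
    p[order(p$transcript_id, p$start), ]
  }
  g <- df[df$type == "gene", c("gene_id", "chrom", "start", "end", "strand")]
  tx <- unique(df[df$type %in% c("transcript", "exon"),
                  c("transcript_id", "gene_id")])
  tx <- tx[!is.na(tx$transcript_id), ]
  rownames(g) <- rownames(tx) <- NULL
  gene_models(g, tx[order(tx$transcript_id), ], part("exon"),
              cds = part("CDS"), utr5 = part("five_prime_utr"),
              utr3 = part("three_prime_utr"))
}

#' Write gene models to a GTF file
#'
#' Internal 0-based half-open intervals are emitted as 1-based inclusive GTF
#' records with `gene_id`/`transcript_id` attributes, so that
#' `read_gtf(write_gtf(x))` round-trips exactly.
#'
#' @param models a [gene_models] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tpanelomics\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  }
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, fmt(g$chrom[i], "gene", g$start[i], g$end[i],
                          g$strand[i], sprintf('gene_id "%s";', gid)))
    txs <- models$transcripts[models$transcripts$gene_id == gid, ]
    type_of <- c(exons = "exon", cds = "CDS", utr5 = "five_prime_utr",
                 utr3 = "three_prime_utr")
    for (tid in txs$transcript_id) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      ex <- models$exons[models$exons$transcript_id == tid, ]
      lines <- c(lines, fmt(g$chrom[i], "transcript", min(ex$start),
                            max(ex$end), g$strand[i], attrs))
      for (slot in names(type_of)) {
        part <- models[[slot]][models[[slot]]$transcript_id == tid, ,
                               drop = FALSE]
        if (nrow(part))
          lines <- c(lines, fmt(g$chrom[i], type_of[[slot]], part$start,
                                part$end, g$strand[i], attrs))
      }
    }
  }
  writeLines(lines, con)
  invisible(path)
}
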