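#' Count interval overlaps per gene
#'
#' An interval overlapping k gene spans contributes one count to each of the k
#' genes (density is treated as a per-gene property; loci shared between
#' overlapping genes are not deduplicated). Strand is ignored.
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param models a [gene_models] object.
#' @return named integer vector, one count per gene.
#' @export
count_gene_overlaps <- function(intervals, models) {
  check_columns(intervals, c("chrom", "start", "end"), "intervals")
  if (any(intervals$start >= intervals$end))
    stopf("malformed interval: start must be < end")
  counts <- stats::setNames(integer(nrow(models$genes)),
                            models$genes$gene_id)
  if (!nrow(intervals)) return(counts)
  hits <- GenomicRanges::countOverlaps(genes_as_granges(models),
                                       intervals_as_granges(intervals))
  counts[names(hits)] <- hits
  counts
}

#' Classify the genic context of an STR locus within one gene
#'
#' Context is assigned over the union of all the gene's transcripts with the
#' precedence `coding_exon > five_prime_utr > three_prime_utr > intron`: a
#' locus touching coding sequence in any transcript is `coding_exon` even if
#' it is intronic in others; a locus overlapping no exonic part of any
#' transcript is `intron`. If a gene carries no CDS/UTR annotation, any exon
#' overlap counts as `coding_exon`.
#'
#' @param locus one-row data frame (or list) with `chrom`, `start`, `end`.
#' @param models a [gene_models] object.
#' @param gene_id the gene to classify against; the locus must overlap its
#'   span.
#' @return one of `"coding_exon"`, `"five_prime_utr"`, `"three_prime_utr"`,
#'   `"intron"`.
#' @export
classify_str_context <- function(locus, models, gene_id) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  if (!nrow(g)) stopf("unknown gene '%s'", gene_id)
  if (g$chrom != locus$chrom || locus$end <= g$start || locus$start >= g$end)
    stopf("locus does not overlap the span of gene '%s'", gene_id)
  touches <- function(part) {
    p <- part[part$gene_id == gene_id, ]
    any(p$start < locus$end & p$end > locus$start)
  }
  has_cds <- any(models$cds$gene_id == gene_id)
  if (!has_cds) {
    if (touches(models$exons)) return("coding_exon")
  } else {
    if (touches(models$cds)) return("coding_exon")
    if (touches(models$utr5)) return("five_prime_utr")
    if (touches(models$utr3)) return("three_prime_utr")
  }
  "intron"
}

# vectorized (locus, gene) context assignment over span overlaps
str_gene_contexts <- function(catalog, models) {
  if (!nrow(catalog))
    return(data.frame(locus_id = character(), gene_id = character(),
                      context = character(), stringsAsFactors = FALSE))
  hits <- GenomicRanges::findOverlaps(intervals_as_granges(catalog),
                                      genes_as_granges(models))
  qi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(locus_id = catalog$locus_id[qi],
                    gene_id = models$genes$gene_id[gi],
                    context = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out)))
    out$context[k] <- classify_str_context(catalog[qi[k], ], models,
                                           out$gene_id[k])
  out
}

#' Per-gene STR counts and length statistics
#'
#' Loci are assigned to every gene whose span they overlap. For each gene the
#' total count equals the sum of per-period counts and the sum of per-context
#' counts (contexts partition the assigned loci).
#'
#' @param models a [gene_models] object.
#' @param catalog STR catalog data frame (`locus_id`, `chrom`, `start`, `end`,
#'   `period`, `ref_repeats`).
#' @return data frame keyed by `gene_id` with columns `n_strs`,
#'   `n_strs_period2` .. `n_strs_period6`, one column per context,
#'   `str_total_bases` and `str_mean_repeats`.
#' @export
str_features <- function(models, catalog) {
  gene_ids <- models$genes$gene_id
  contexts <- c("coding_exon", "five_prime_utr", "three_prime_utr", "intron")
  out <- data.frame(gene_id = gene_ids, n_strs = 0L, stringsAsFactors = FALSE)
  for (p in 2:6) out[[sprintf("n_strs_period%d", p)]] <- 0L
  for (cx in contexts) out[[sprintf("n_strs_%s", cx)]] <- 0L
  out$str_total_bases <- 0L
  out$str_mean_repeats <- 0
  asg <- str_gene_contexts(catalog, models)
  if (!nrow(asg)) return(out)
  asg$period <- catalog$period[match(asg$locus_id, catalog$locus_id)]
  asg$bases <- with(catalog[match(asg$locus_id, catalog$locus_id), ],
                    end - start)
  asg$repeats <- catalog$ref_repeats[match(asg$locus_id, catalog$locus_id)]
  for (g in split(asg, asg$gene_id)) {
    i <- match(g$gene_id[1], out$gene_id)
    out$n_strs[i] <- nrow(g)
    for (p in 2:6)
      out[[sprintf("n_strs_period%d", p)]][i] <- sum(g$period == p)
    for (cx in contexts)
      out[[sprintf("n_strs_%s", cx)]][i] <- sum(g$context == cx)
    out$str_total_bases[i] <- sum(g$bases)
    out$str_mean_repeats[i] <- mean(g$repeats)
  }
  out
}

#' Per-gene eSTR counts
#'
#' Duplicate (gene, locus) rows are collapsed before counting.
#' `n_estr_tissues` is the size of the union of tissue labels over the gene's
#' eSTRs. Genes absent from the table get zero counts.
#'
#' @param gene_ids character vector of genes to report.
#' @param estr data frame with columns `locus_id`, `gene_id`, `tissues`
#'   (comma-separated tissue labels).
#' @return data frame `gene_id`, `n_estrs`, `n_estr_tissues`.
#' @export
estr_features <- function(gene_ids, estr) {
  check_columns(estr, c("locus_id", "gene_id", "tissues"), "estr")
  out <- data.frame(gene_id = gene_ids, n_estrs = 0L, n_estr_tissues = 0L,
                    stringsAsFactors = FALSE)
  estr <- estr[!duplicated(estr[c("gene_id", "locus_id")]), ]
  estr <- estr[estr$gene_id %in% gene_ids, ]
  for (g in split(estr, estr$gene_id)) {
    i <- match(g$gene_id[1], out$gene_id)
    out$n_estrs[i] <- nrow(g)
    tis <- unique(trimws(unlist(strsplit(g$tissues, ","))))
    out$n_estr_tissues[i] <- length(setdiff(tis, ""))
  }
  out
}

#' Fraction of a gene covered by constrained non-conserved regions
#'
#' Input segments may overlap; density is computed on their base-level union
#' intersected with the gene span, divided by gene length, hence always in
#' `[0, 1]` and invariant under segment order or splitting.
#'
#' @param models a [gene_models] object.
#' @param segments data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return named numeric vector of densities, one per gene.
#' @export
cncr_density <- function(models, segments) {
  check_columns(segments, c("chrom", "start", "end"), "segments")
  g <- models$genes
  if (any(g$end <= g$start)) stopf("zero-length gene span")
  dens <- stats::setNames(numeric(nrow(g)), g$gene_id)
  if (!nrow(segments)) return(dens)
  seg <- GenomicRanges::reduce(intervals_as_granges(segments))
  gr <- genes_as_granges(models)
  # per-gene covered bases: overlap widths of reduced segments with each span
  hits <- GenomicRanges::findOverlaps(gr, seg)
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr)[S4Vectors::queryHits(hits)],
      GenomicRanges::ranges(seg)[S4Vectors::subjectHits(hits)]))
    cov <- tapply(w, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(cov))
    dens[idx] <- as.numeric(cov) / (g$end[idx] - g$start[idx])
  }
  dens
}

#' Gene structure features
#'
#' Junctions are unique (donor, acceptor) genomic coordinate pairs over all
#' transcripts of the gene; GC content is (G+C)/(A+C+G+T) over the gene span,
#' case-insensitive, with ambiguous bases excluded from the denominator.
#'
#' @param models a [gene_models] object.
#' @param genome optional named [Biostrings::DNAStringSet]; when absent the
#'   `gc_content` column is omitted.
#' @return data frame `gene_id`, `gene_length`, `n_transcripts`,
#'   `n_junctions` and (with a genome) `gc_content`.
#' @export
structure_features <- function(models, genome = NULL) {
  g <- models$genes
  n_tx <- table(factor(models$transcripts$gene_id, levels = g$gene_id))
  junc <- vapply(g$gene_id, function(gid) {
    jn <- character(0)
    ex <- models$exons[models$exons$gene_id == gid, ]
    for (e in split(ex, ex$transcript_id)) {
      e <- e[order(e$start), ]
      if (nrow(e) > 1)
        jn <- c(jn, paste(e$end[-nrow(e)], e$start[-1], sep = "-"))
    }
    length(unique(jn))
  }, integer(1))
  out <- data.frame(gene_id = g$gene_id,
                    gene_length = g$end - g$start,
                    n_transcripts = as.integer(n_tx),
                    n_junctions = junc,
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    out$gc_content <- vapply(seq_len(nrow(g)), function(i) {
      seq <- Biostrings::subseq(genome[[g$chrom[i]]], g$start[i] + 1L,
                                g$end[i])
      freq <- Biostrings::alphabetFrequency(seq)
      acgt <- sum(freq[c("A", "C", "G", "T")])
      if (acgt == 0) return(NA_real_)
      sum(freq[c("G", "C")]) / acgt
    }, numeric(1))
  }
  out
}

#' Per-gene repetitive-element counts
#'
#' Counts overlaps of RepeatMasker-style elements with gene spans, one column
#' per requested family.
#'
#' @param models a [gene_models] object.
#' @param rmsk data frame with `family`, `chrom`, `start`, `end`.
#' @param families character vector of families to count.
#' @return data frame keyed by `gene_id` with one count column per family
#'   (`n_line_l1`, `n_sine_alu`, `n_sva` for the defaults).
#' @export
repeat_features <- function(models, rmsk,
                            families = c("LINE/L1", "SINE/Alu",
                                         "Retroposon/SVA")) {
  check_columns(rmsk, c("family", "chrom", "start", "end"), "rmsk")
  col_name <- c("LINE/L1" = "n_line_l1", "SINE/Alu" = "n_sine_alu",
                "Retroposon/SVA" = "n_sva")
  out <- data.frame(gene_id = models$genes$gene_id, stringsAsFactors = FALSE)
  for (fam in families) {
    nm <- if (fam %in% names(col_name)) col_name[[fam]] else
      paste0("n_", gsub("[^a-z0-9]+", "_", tolower(fam)))
    out[[nm]] <- as.integer(
      count_gene_overlaps(rmsk[rmsk$family == fam, , drop = FALSE], models))
  }
  out
}

#' Assemble the per-gene feature table
#'
#' Joins structure, STR, eSTR, repetitive-element and CNCR features with panel
#' labels into one row per gene. A feature-metadata data frame (name,
#' category, dtype) is attached as the `"metadata"` attribute and written as a
#' sidecar by [write_features()].
#'
#' @param annotation result of [gen_annotation()], or a list with `models`,
#'   `genome` (optional) and `panels`.
#' @param catalog STR catalog data frame (optional).
#' @param estr eSTR table (optional).
#' @param rmsk repetitive-element table (optional).
#' @param cncr CNCR segment data frame (optional).
#' @return a feature table data frame with `gene_id`, `panel` and numeric
#'   feature columns.
#' @export
gene_features <- function(annotation, catalog = NULL, estr = NULL,
                          rmsk = NULL, cncr = NULL) {
  models <- annotation$models
  out <- structure_features(models, annotation$genome)
  category <- stats::setNames(rep("structure", ncol(out) - 1L),
                              setdiff(names(out), "gene_id"))
  add <- function(df, cat) {
    category[setdiff(names(df), "gene_id")] <<- cat
    merge(out, df, by = "gene_id", sort = FALSE)
  }
  if (!is.null(catalog)) out <- add(str_features(models, catalog), "str")
  if (!is.null(estr)) out <- add(estr_features(models$genes$gene_id, estr),
                                 "estr")
  if (!is.null(rmsk)) out <- add(repeat_features(models, rmsk), "repeats")
  if (!is.null(cncr)) {
    d <- cncr_density(models, cncr)
    out <- add(data.frame(gene_id = names(d), cncr_density = as.numeric(d),
                          stringsAsFactors = FALSE), "conservation")
  }
  out <- merge(out, annotation$panels, by = "gene_id", sort = FALSE)
  meta <- data.frame(name = names(category),
                     category = as.character(category),
                     dtype = vapply(out[names(category)], function(x)
                       if (is.numeric(x)) "numeric" else "categorical",
                       character(1)),
                     stringsAsFactors = FALSE)
  attr(out, "metadata") <- meta
  out
}

#' Write a feature table and its metadata sidecar
#' @param features result of [gene_features()].
#' @param path output TSV path; the sidecar goes to `<path>.meta.tsv`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write_tsv(features, path)
  meta <- attr(features, "metadata")
  if (!is.null(meta)) write_tsv(meta, paste0(path, ".meta.tsv"))
  invisible(path)
}
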