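#' Read an STR catalog in HipSTR-dialect BED
#'
#' The dialect is tab-separated `chrom, start, end, period, n_repeats, name`
#' with a 0-based start and an inclusive end; the end is converted to the
#' internal half-open convention on read. Some catalog builds use fully
#' 1-based coordinates instead; set `one_based = TRUE` for those.
#'
#' @param path input file path (no header).
#' @param one_based read coordinates as 1-based inclusive instead.
#' @return data frame `locus_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `period`, `ref_repeats`.
#' @export
read_str_bed <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "period",
                                        "ref_repeats", "locus_id"))
  if (one_based) df$start <- df$start - 1L else df$end <- df$end + 1L
  df[c("locus_id", "chrom", "start", "end", "period", "ref_repeats")]
}

#' Write an STR catalog in HipSTR-dialect BED
#'
#' Inverse of [read_str_bed()] with `one_based = FALSE`: emits a 0-based start
#' and an inclusive end. Any extra columns (e.g. the simulator's `gene_id`
#' truth column) are dropped.
#'
#' @param catalog STR catalog data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_str_bed <- function(catalog, path) {
  out <- data.frame(chrom = catalog$chrom, start = catalog$start,
                    end = catalog$end - 1L, period = catalog$period,
                    ref_repeats = catalog$ref_repeats,
                    locus_id = catalog$locus_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3+ column BED file as 0-based half-open intervals
#' @param path input file path (no header).
#' @return data frame `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df
}

#' Read / write a numeric gene-by-column matrix as TSV
#'
#' The first column holds gene identifiers; the header row holds
#' tissue/cell-type labels.
#'
#' @param path file path.
#' @return `read_matrix_tsv`: a numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param mat numeric matrix with gene rownames.
#' @return `write_matrix_tsv`: `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, path)
}
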