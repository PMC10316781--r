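#' Derive a reproducible per-stage seed from a root seed
#'
#' All random draws in the simulator flow from one root seed. Each stage
#' (annotation, STR catalog, expression, variants, genotypes, ...) derives its
#' own substream seed by hashing the stage name together with the root seed,
#' so a stage can be re-run in isolation and still reproduce the exact output
#' of a full pipeline run.
#'
#' @param seed integer root seed.
#' @param stage character scalar naming the stage.
#' @return an integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' stage_seed(1L, "annotation")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1000003
  # keep all arithmetic well inside double precision, result < 2^31 - 1
  as.integer((((abs(seed) %% 2097152) * 1013) + h * 977) %% 2147483629) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  invisible(x)
}

check_columns <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("'%s' is missing required column(s): %s", name,
          paste(miss, collapse = ", "))
  invisible(df)
}

#' Write a tab-separated table without quoting or row names
#' @param df data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table with a header row
#' @param path input file path.
#' @return a data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
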