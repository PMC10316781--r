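#' Flag tissue-specific expression by a fold rule
#'
#' A gene is flagged in a tissue when its expression there is at least `fold`
#' times its mean across all tissues, the focal tissue included. Because the
#' focal tissue enters the mean, the rule is unsatisfiable when the number of
#' tissues does not exceed the fold, so fewer than `fold + 1` tissues is a
#' configuration error rather than a silent all-FALSE result. At most
#' `floor(T / fold)` tissues can be flagged per gene.
#'
#' @param expr numeric genes-by-tissues matrix (residualized expression).
#' @param fold fold-change threshold (default 5).
#' @return logical matrix of the same shape.
#' @export
tissue_specific_flags <- function(expr, fold = 5) {
  expr <- as.matrix(expr)
  if (ncol(expr) < fold + 1)
    stopf(paste("the %s-fold rule needs at least %d tissues: with T <= fold,",
                "no tissue can reach fold x the all-tissue mean"),
          format(fold), as.integer(floor(fold) + 1))
  if (anyNA(expr)) stopf("expression matrix contains missing values")
  expr >= fold * rowMeans(expr)
}

#' Flag tissue-specific module membership by a fold rule
#'
#' A gene is flagged in a tissue when its module membership there is positive
#' and at least `fold` times the mean over the *other* tissues, with negative
#' values floored at 0 before averaging (fold change over a negative baseline
#' is undefined). With `baseline = "max"` the maximum over other tissues is
#' used instead of the mean.
#'
#' @param mm numeric genes-by-tissues matrix of module-membership values in
#'   `[-1, 1]`.
#' @param fold fold-change threshold (default 3.5).
#' @param baseline `"mean"` (default) or `"max"` over the other tissues.
#' @return logical matrix of the same shape.
#' @export
mm_specific_flags <- function(mm, fold = 3.5, baseline = c("mean", "max")) {
  baseline <- match.arg(baseline)
  mm <- as.matrix(mm)
  if (ncol(mm) < 2) stopf("at least 2 tissues required")
  if (any(mm < -1 | mm > 1, na.rm = TRUE))
    stopf("module-membership values must lie in [-1, 1]")
  floored <- pmax(mm, 0)
  tot <- rowSums(floored)
  flags <- mm
  for (j in seq_len(ncol(mm))) {
    base <- if (baseline == "mean") (tot - floored[, j]) / (ncol(mm) - 1)
            else apply(floored[, -j, drop = FALSE], 1, max)
    flags[, j] <- mm[, j] > 0 & mm[, j] >= fold * base
  }
  flags <- flags == 1
  dimnames(flags) <- dimnames(mm)
  flags
}

#' Row-normalize cell-type mean expression into a specificity matrix
#'
#' Each retained gene's row gives the fraction of its expression attributable
#' to each cell type and sums to 1; all-zero rows are dropped with a message.
#' The result is invariant under uniform rescaling of a gene's expression row.
#'
#' @param celltype_means non-negative numeric genes-by-cell-types matrix.
#' @param level optional label for the cell-type hierarchy level, stored as
#'   the `"level"` attribute.
#' @return numeric matrix of specificities with unit row sums.
#' @export
specificity_matrix <- function(celltype_means, level = NULL) {
  m <- as.matrix(celltype_means)
  if (any(m < 0)) stopf("cell-type mean expression must be non-negative")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    message(sprintf("dropping %d gene(s) with all-zero expression: %s",
                    sum(tot == 0),
                    paste(utils::head(rownames(m)[tot == 0], 5),
                          collapse = ", ")))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  s <- m / tot
  attr(s, "level") <- level
  s
}

#' Contribution of one gene to a cell type's expression signal
#'
#' The gene's mean expression in the cell type divided by its summed
#' expression over all cell types (identical to the gene's specificity entry,
#' exposed as a named report). A zero total is undefined and reported as
#' `NA` with a message.
#'
#' @param celltype_means non-negative numeric genes-by-cell-types matrix.
#' @param gene,cell_type row and column to report.
#' @return a single number in `[0, 1]`, or `NA`.
#' @export
gene_contribution <- function(celltype_means, gene, cell_type) {
  m <- as.matrix(celltype_means)
  if (!gene %in% rownames(m)) stopf("unknown gene '%s'", gene)
  if (!cell_type %in% colnames(m)) stopf("unknown cell type '%s'", cell_type)
  tot <- sum(m[gene, ])
  if (tot == 0) {
    message(sprintf("gene '%s' has zero total expression; contribution undefined",
                    gene))
    return(NA_real_)
  }
  m[gene, cell_type] / tot
}

#' Emit specificity flags in long format
#' @param flags logical genes-by-tissues matrix.
#' @return data frame `gene_id`, `tissue`, `flag`.
#' @export
flags_to_long <- function(flags) {
  data.frame(gene_id = rep(rownames(flags), ncol(flags)),
             tissue = rep(colnames(flags), each = nrow(flags)),
             flag = as.vector(flags), stringsAsFactors = FALSE)
}
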