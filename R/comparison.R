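#' Two-sample Wilcoxon rank-sum test
#'
#' Uses exact enumeration of the rank-sum distribution when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. Degenerate
#' inputs whose approximation is undefined (all values identical) return
#' p = 1.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `statistic` (W, the Mann-Whitney count for `x`), `p`
#'   (two-sided) and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p) || is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p = min(p, 1), exact = exact)
}

#' Chi-squared test for a 2x2 table with Yates continuity correction
#'
#' The statistic is `sum(max(|O - E| - 0.5, 0)^2 / E)` (continuity correction
#' on by default), compared against a chi-squared distribution with 1 degree
#' of freedom. A table with a zero margin is degenerate: it returns p = 1
#' with a warning rather than an error.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param continuity apply the Yates correction (default `TRUE`).
#' @return list with `statistic` and `p`.
#' @export
chisq_2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stopf("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stopf("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate table (zero margin); returning p = 1")
    return(list(statistic = 0, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH with enforced monotonicity, order-preserving with the input.
#' Adjusted values are always at least the raw values.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pairwise comparison of one feature across panel groups
#'
#' Compares the feature between every pair of panel labels: numeric features
#' by Wilcoxon rank-sum with group medians attached, categorical features by
#' chi-squared on the pair's contingency table with the proportion of the
#' first feature level attached. With the four standard labels this yields
#' six pairs. P-values are BH-adjusted over the pairs actually tested; a
#' group with fewer than two observations causes its pairs to be skipped with
#' a recorded reason.
#'
#' @param table feature table with columns `gene_id`, `panel` and the
#'   feature.
#' @param feature name of the feature column.
#' @return data frame with one row per pair: `feature`, `group_x`, `group_y`,
#'   `test`, `statistic`, `p`, `p_adj`, `n_x`, `n_y`, `summary_x`,
#'   `summary_y`, `skipped`.
#' @export
compare_feature <- function(table, feature) {
  check_columns(table, c("panel", feature), "table")
  vals <- table[[feature]]
  groups <- sort(unique(table$panel))
  pairs <- utils::combn(groups, 2)
  numeric_feature <- is.numeric(vals)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    gx <- pairs[1, k]; gy <- pairs[2, k]
    x <- vals[table$panel == gx & !is.na(vals)]
    y <- vals[table$panel == gy & !is.na(vals)]
    row <- data.frame(feature = feature, group_x = gx, group_y = gy,
                      test = if (numeric_feature) "wilcoxon" else "chisq",
                      statistic = NA_real_, p = NA_real_,
                      n_x = length(x), n_y = length(y),
                      summary_x = NA_real_, summary_y = NA_real_,
                      skipped = NA_character_, stringsAsFactors = FALSE)
    if (length(x) < 2 || length(y) < 2) {
      row$skipped <- "fewer than 2 observations in a group"
      return(row)
    }
    if (numeric_feature) {
      wt <- wilcoxon_rank_sum(x, y)
      row$statistic <- wt$statistic; row$p <- wt$p
      row$summary_x <- stats::median(x); row$summary_y <- stats::median(y)
    } else {
      lev <- sort(unique(c(x, y)))
      tab <- rbind(table(factor(x, levels = lev)),
                   table(factor(y, levels = lev)))
      ct <- if (all(dim(tab) == 2)) chisq_2x2(tab) else
        suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      row$statistic <- unname(ct$statistic)
      row$p <- if (is.na(ct$p.value %||% ct$p)) 1 else (ct$p.value %||% ct$p)
      row$summary_x <- mean(x == lev[1]); row$summary_y <- mean(y == lev[1])
    }
    row
  })
  out <- do.call(rbind, rows)
  tested <- is.na(out$skipped)
  out$p_adj <- NA_real_
  if (any(tested)) out$p_adj[tested] <- fdr_bh(out$p[tested])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise comparison of every feature in a feature table
#'
#' Runs [compare_feature()] for each feature column (everything except
#' `gene_id` and `panel`, or the names given) and stacks the results in long
#' format; adjustment stays within each feature's family of pairs.
#'
#' @param table feature table.
#' @param features feature column names (default: all).
#' @return long-format data frame of comparison rows.
#' @export
compare_all_features <- function(table,
                                 features = setdiff(names(table),
                                                    c("gene_id", "panel"))) {
  do.call(rbind, lapply(features, function(f) compare_feature(table, f)))
}
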