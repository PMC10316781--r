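#' Configuration for expression-weighted cell-type enrichment
#'
#' @param n_boot number of bootstrap replicates (default 10000, minimum 100).
#' @param n_bins quantile bins per covariate for matched sampling (default 5,
#'   minimum 2).
#' @param seed integer seed for the bootstrap stream.
#' @return an object of class `ewce_config`.
#' @export
ewce_config <- function(n_boot = 10000L, n_bins = 5L, seed = 1L) {
  check_scalar_number(n_boot, "n_boot", min = 100)
  check_scalar_number(n_bins, "n_bins", min = 2)
  check_scalar_number(seed, "seed")
  structure(list(n_boot = as.integer(n_boot), n_bins = as.integer(n_bins),
                 seed = as.integer(seed)), class = "ewce_config")
}

#' Covariate-matched bootstrap gene sets
#'
#' Builds joint quantile bins (default 5 per covariate, e.g. transcript
#' length x GC content) over the universe, then for every replicate replaces
#' each target gene by a gene drawn uniformly, with replacement, from the
#' target gene's own joint bin. A target gene always occupies a non-empty bin
#' (it is in the universe itself); should a bin come out empty through
#' degenerate covariates, it is widened to the nearest non-empty bin by
#' covariate distance, with a message. With zero covariate columns the
#' sampler degenerates to plain uniform sampling from the universe.
#'
#' @param target character vector of target genes, a subset of `universe`.
#' @param universe character vector of all candidate genes.
#' @param covariates numeric matrix/data frame with one row per universe gene
#'   (rownames = gene ids) and one column per covariate, or `NULL`.
#' @param config an [ewce_config].
#' @return an `n_boot` x `length(target)` integer matrix of indices into
#'   `universe`.
#' @export
matched_bootstrap <- function(target, universe, covariates, config) {
  if (!all(target %in% universe))
    stopf("target genes must be a subset of the universe")
  set.seed(config$seed)
  n_t <- length(target)
  B <- config$n_boot
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(matrix(sample.int(length(universe), B * n_t, replace = TRUE),
                  nrow = B))
  }
  cov <- as.matrix(covariates)
  if (!all(universe %in% rownames(cov)))
    stopf("covariate values missing for some universe genes")
  cov <- cov[universe, , drop = FALSE]
  bins <- apply(cov, 2, function(x) {
    brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                   config$n_bins + 1)))
    if (length(brk) < 2) rep(1L, length(x))
    else as.integer(cut(x, breaks = brk, include.lowest = TRUE))
  })
  bins <- matrix(bins, nrow = length(universe))
  bin_id <- apply(bins, 1, paste, collapse = ":")
  pools <- split(seq_along(universe), bin_id)
  centers <- do.call(rbind, lapply(pools, function(ix)
    colMeans(cov[ix, , drop = FALSE])))
  out <- matrix(0L, nrow = B, ncol = n_t)
  for (j in seq_len(n_t)) {
    gi <- match(target[j], universe)
    pool <- pools[[bin_id[gi]]]
    if (is.null(pool) || !length(pool)) {
      d <- rowSums((sweep(centers, 2, cov[gi, ]))^2)
      nearest <- names(sort(d))[1]
      message(sprintf("empty covariate bin for '%s'; widened to bin %s",
                      target[j], nearest))
      pool <- pools[[nearest]]
    }
    out[, j] <- pool[sample.int(length(pool), B, replace = TRUE)]
  }
  out
}

#' Bootstrap test of cell-type expression specificity for a gene set
#'
#' Asks whether a gene set's mean expression specificity in a cell type
#' exceeds that of covariate-matched random gene sets. The p-value uses the
#' add-one estimator `(1 + #{replicate mean >= target mean}) / (n_boot + 1)`,
#' so it is always in `(0, 1]`; `sd_from_mean` is the distance of the target
#' mean from the bootstrap mean in bootstrap standard deviations (reported
#' missing when the bootstrap SD is zero).
#'
#' @param target character vector of target genes (rows of `spec`).
#' @param spec specificity matrix from [specificity_matrix()].
#' @param cell_type column of `spec` to test.
#' @param config an [ewce_config].
#' @param covariates covariate matrix for matched sampling (see
#'   [matched_bootstrap()]), or `NULL` for plain uniform sampling.
#' @param gene_set optional label recorded in the result.
#' @return one-row data frame: `gene_set`, `cell_type`, `n_genes`,
#'   `target_mean`, `boot_mean`, `boot_sd`, `sd_from_mean`, `p`.
#' @export
ewce_test <- function(target, spec, cell_type, config, covariates = NULL,
                      gene_set = "target") {
  target <- intersect(target, rownames(spec))
  if (!length(target)) stopf("no target genes present in the specificity matrix")
  if (!cell_type %in% colnames(spec)) stopf("unknown cell type '%s'", cell_type)
  universe <- rownames(spec)
  idx <- matched_bootstrap(target, universe, covariates, config)
  vals <- spec[, cell_type]
  target_mean <- mean(vals[target])
  boot_means <- rowMeans(matrix(vals[idx], nrow = nrow(idx)))
  boot_sd <- stats::sd(boot_means)
  p <- (1 + sum(boot_means >= target_mean)) / (config$n_boot + 1)
  data.frame(gene_set = gene_set, cell_type = cell_type,
             n_genes = length(target), target_mean = target_mean,
             boot_mean = mean(boot_means), boot_sd = boot_sd,
             sd_from_mean = if (boot_sd > 0)
               (target_mean - mean(boot_means)) / boot_sd else NA_real_,
             p = p, stringsAsFactors = FALSE)
}

#' Run EWCE over gene sets and cell types and adjust over the grid
#'
#' @param targets named list of gene-set character vectors.
#' @param spec specificity matrix.
#' @param config an [ewce_config]; each (set, cell type) test derives its own
#'   seed from `config$seed` so results do not depend on evaluation order.
#' @param covariates covariate matrix or `NULL`.
#' @param cell_types columns of `spec` to test (default: all).
#' @return data frame of [ewce_test()] rows, one per set x cell type.
#' @export
ewce_grid <- function(targets, spec, config, covariates = NULL,
                      cell_types = colnames(spec)) {
  rows <- list()
  for (nm in names(targets)) {
    for (ct in cell_types) {
      cfg <- config
      cfg$seed <- stage_seed(config$seed, paste0("ewce_", nm, "_", ct))
      rows[[length(rows) + 1L]] <-
        ewce_test(targets[[nm]], spec, ct, cfg, covariates, gene_set = nm)
    }
  }
  do.call(rbind, rows)
}

#' Benjamini-Hochberg adjustment over a declared grid scope
#'
#' With `scope = "all"` the correction runs over every row (all cell types x
#' gene sets jointly); with `scope = "per_gene_set"` it runs within each gene
#' set (i.e. over cell types only, as appropriate when the cell-type level is
#' too granular to correct across sets). The scope is recorded in the output.
#'
#' @param results data frame with columns `gene_set` and `p`.
#' @param scope `"all"` or `"per_gene_set"`.
#' @return `results` with `p_adj` and `adjust_scope` columns.
#' @export
adjust_over_grid <- function(results, scope = c("all", "per_gene_set")) {
  scope <- match.arg(scope)
  if (scope == "all") {
    results$p_adj <- fdr_bh(results$p)
  } else {
    results$p_adj <- NA_real_
    for (nm in unique(results$gene_set)) {
      i <- results$gene_set == nm
      results$p_adj[i] <- fdr_bh(results$p[i])
    }
  }
  results$adjust_scope <- scope
  results
}
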