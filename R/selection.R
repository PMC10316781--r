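#' Greedily prune highly correlated features
#'
#' Constant columns (undefined correlation) are removed first. Then, while
#' any pair of remaining features has absolute Pearson correlation above the
#' threshold, the member of the worst pair with the larger mean absolute
#' correlation to all other features is dropped; ties break deterministically
#' by feature name. The output is guaranteed to contain no pair above the
#' threshold.
#'
#' @param features numeric matrix or data frame (genes x features).
#' @param threshold correlation threshold (default 0.9).
#' @return character vector of retained feature names, with attributes
#'   `pruned` (dropped by correlation) and `constant` (dropped as constant).
#' @export
prune_correlated <- function(features, threshold = 0.9) {
  X <- as.matrix(features)
  sds <- apply(X, 2, stats::sd)
  constant <- colnames(X)[is.na(sds) | sds == 0]
  keep <- setdiff(colnames(X), constant)
  pruned <- character(0)
  if (length(keep) > 1) {
    cm <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(cm) <- 0
    while (max(cm) > threshold) {
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      cand <- colnames(cm)[worst]
      mean_abs <- colMeans(cm[, cand, drop = FALSE])
      drop <- if (mean_abs[1] > mean_abs[2]) cand[1]
              else if (mean_abs[2] > mean_abs[1]) cand[2]
              else sort(cand)[2]
      pruned <- c(pruned, drop)
      ix <- match(drop, colnames(cm))
      cm <- cm[-ix, -ix, drop = FALSE]
      if (nrow(cm) < 2) break
    }
    keep <- colnames(cm)
  }
  structure(keep, pruned = pruned, constant = constant)
}

#' Cohen's kappa agreement statistic
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` from
#' marginal products. When both label vectors are constant and equal
#' (`p_e = 1`), agreement is perfect by construction and kappa is defined
#' as 1.
#'
#' @param predicted,truth equal-length label vectors.
#' @return kappa, a single number.
#' @export
cohen_kappa <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopf("label vectors must have equal length")
  lev <- sort(unique(c(as.character(predicted), as.character(truth))))
  tab <- table(factor(predicted, lev), factor(truth, lev)) / length(truth)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_e >= 1) return(if (p_o >= 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Configuration for balanced recursive feature elimination
#'
#' @param corr_threshold correlation-pruning threshold (default 0.9).
#' @param repeats number of balanced resampling repeats (default 50).
#' @param disease_fraction fraction of disease genes sampled per repeat
#'   (default 0.5).
#' @param keep_frequency minimum selection frequency for a feature to be
#'   retained (default 0.8, i.e. selected in more than 40 of 50 repeats).
#' @param cv_folds folds for the inner cross-validation (default 5).
#' @param skill_kappa minimum cross-validated kappa of the full (all-feature)
#'   model for a repeat to contribute selections (default 0.2, the
#'   conventional floor of "fair" agreement). A repeat in which even the full
#'   model predicts no better than chance carries no information about
#'   feature relevance, so its "best subset" is noise and is not counted.
#' @param seed integer seed.
#' @return an object of class `rfe_config`.
#' @export
rfe_config <- function(corr_threshold = 0.9, repeats = 50L,
                       disease_fraction = 0.5, keep_frequency = 0.8,
                       cv_folds = 5L, skill_kappa = 0.2, seed = 1L) {
  check_scalar_number(corr_threshold, "corr_threshold", min = 1e-9, max = 1)
  check_scalar_number(repeats, "repeats", min = 2)
  check_scalar_number(disease_fraction, "disease_fraction", min = 1e-9, max = 1)
  check_scalar_number(keep_frequency, "keep_frequency", min = 1e-9, max = 1)
  check_scalar_number(cv_folds, "cv_folds", min = 2)
  check_scalar_number(skill_kappa, "skill_kappa", min = -1, max = 1)
  structure(list(corr_threshold = corr_threshold,
                 repeats = as.integer(repeats),
                 disease_fraction = disease_fraction,
                 keep_frequency = keep_frequency,
                 cv_folds = as.integer(cv_folds), skill_kappa = skill_kappa,
                 seed = as.integer(seed)),
            class = "rfe_config")
}

# logistic fit returning |standardized coefficient| feature ranking; columns
# are z-scored by the caller, so raw |coefficients| are comparable
rank_features <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                    family = stats::binomial())),
    error = function(e) NULL)
  score <- if (is.null(fit)) abs(apply(X, 2, function(v)
    suppressWarnings(stats::cor(v, y)))) else abs(fit$coefficients[-1])
  score[is.na(score)] <- 0
  score
}

predict_logit <- function(X_train, y_train, X_test) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, X_train), y_train,
                                    family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients))
    return(rep(mean(y_train) > 0.5, nrow(X_test)) * 1)
  eta <- cbind(1, X_test) %*% fit$coefficients
  as.numeric(stats::plogis(eta) > 0.5)
}

# candidate subset sizes: powers of two descending from p, plus p itself
size_grid <- function(p) {
  sizes <- 2^(floor(log2(p)):1)
  sort(unique(c(p, sizes[sizes <= p])), decreasing = TRUE)
}

# recursive elimination on (X, y): refit at each grid size, dropping the
# lowest-|coefficient| features to reach the next size; returns the feature
# sets at every size
elimination_path <- function(X, y, sizes) {
  current <- colnames(X)
  path <- list()
  for (s in sizes) {
    if (length(current) > s) {
      score <- rank_features(X[, current, drop = FALSE], y)
      current <- current[order(score, decreasing = TRUE)][seq_len(s)]
    }
    path[[as.character(s)]] <- current
  }
  path
}

#' Class-balanced recursive feature elimination with selection frequencies
#'
#' Each repeat draws half (`disease_fraction`) of the disease genes without
#' replacement and an equal-sized bootstrap sample of control genes, z-scores
#' the features on that sample, and runs recursive feature elimination with a
#' logistic-link linear model: features are ranked by absolute standardized
#' coefficient, candidate subset sizes (powers of two down from the full set)
#' are scored by cross-validated Cohen's kappa, and the best size's feature
#' set on the full repeat sample is recorded. Selection frequencies are
#' aggregated over repeats; features at or above `keep_frequency` are
#' retained.
#'
#' @param features numeric matrix/data frame (genes x features), already
#'   pruned of redundant columns (see [prune_correlated()]).
#' @param labels per-gene labels; anything other than `"control"` counts as
#'   disease.
#' @param config an [rfe_config].
#' @return an object of class `selection_report`: list with `frequency`
#'   (named, in `[0, 1]`), `retained`, `per_repeat` (list of selected sets)
#'   and `config`.
#' @export
balanced_rfe <- function(features, labels, config = rfe_config()) {
  X <- as.matrix(features)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  disease <- which(labels != "control")
  control <- which(labels == "control")
  if (!length(disease) || !length(control))
    stopf("both disease and control genes are required")
  if (all(apply(X, 2, stats::sd) == 0))
    warning("degenerate feature matrix: all columns constant")
  sizes <- size_grid(ncol(X))
  per_repeat <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    set.seed(stage_seed(config$seed, paste0("rfe_repeat_", r)))
    n_d <- max(2L, round(config$disease_fraction * length(disease)))
    d_idx <- sample(disease, n_d)
    c_idx <- sample(control, n_d, replace = TRUE)
    idx <- c(d_idx, c_idx)
    y <- rep(c(1, 0), c(n_d, n_d))
    Xr <- X[idx, , drop = FALSE]
    mu <- colMeans(Xr); sg <- apply(Xr, 2, stats::sd)
    sg[sg == 0] <- 1
    Xr <- sweep(sweep(Xr, 2, mu), 2, sg, "/")
    # one elimination path per repeat; cross-validation then scores the
    # candidate sizes on shared folds, so size comparisons are paired and the
    # size choice is not dominated by fold-to-fold path variability
    path <- elimination_path(Xr, y, sizes)
    folds <- sample(rep(seq_len(config$cv_folds), length.out = nrow(Xr)))
    kappa_by_size <- matrix(NA_real_, config$cv_folds, length(sizes),
                            dimnames = list(NULL, as.character(sizes)))
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      for (s in names(path)) {
        pred <- predict_logit(Xr[tr, path[[s]], drop = FALSE], y[tr],
                              Xr[!tr, path[[s]], drop = FALSE])
        kappa_by_size[f, s] <- cohen_kappa(pred, y[!tr])
      }
    }
    mean_kappa <- colMeans(kappa_by_size)
    # the full-size model involves no feature selection, so its CV kappa is
    # an unbiased skill estimate; a no-skill repeat contributes no selection
    if (mean_kappa[[as.character(ncol(X))]] < config$skill_kappa) {
      per_repeat[[r]] <- character(0)
      next
    }
    # best size: maximum kappa, ties to the smaller (more parsimonious) size
    best <- names(mean_kappa)[order(-mean_kappa, as.integer(names(mean_kappa)))][1]
    per_repeat[[r]] <- path[[best]]
  }
  freq <- table(factor(unlist(per_repeat), levels = colnames(X))) /
    config$repeats
  freq <- stats::setNames(as.numeric(freq), colnames(X))
  structure(list(frequency = freq,
                 retained = names(freq)[freq >= config$keep_frequency],
                 per_repeat = per_repeat, config = config),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report: %d/%d features retained at frequency >= %.2f over %d repeats\n",
              length(x$retained), length(x$frequency),
              x$config$keep_frequency, x$config$repeats))
  invisible(x)
}

#' Two-dimensional embedding of genes on selected features
#'
#' Z-scores the selected feature columns (constant columns dropped) and runs
#' UMAP as an external routine. The neighbourhood size is shrunk with a
#' warning when there are fewer genes than neighbours. Deterministic given
#' the seed.
#'
#' @param features numeric matrix (genes x features); at least 3 genes.
#' @param seed integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @return a genes x 2 coordinate matrix with the input rownames.
#' @export
embed_2d <- function(features, seed = 1L, n_neighbors = 15L) {
  X <- as.matrix(features)
  if (nrow(X) < 3) stopf("at least 3 genes are required")
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  if (n_neighbors >= nrow(X)) {
    warning(sprintf("n_neighbors reduced from %d to %d (too few genes)",
                    n_neighbors, nrow(X) - 1L))
    n_neighbors <- nrow(X) - 1L
  }
  set.seed(seed)
  coords <- uwot::umap(X, n_neighbors = n_neighbors, n_threads = 1,
                       n_sgd_threads = 1)
  rownames(coords) <- rownames(features)
  colnames(coords) <- c("umap1", "umap2")
  coords
}
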