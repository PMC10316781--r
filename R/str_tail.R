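#' Configuration for the repeat-size tail comparison
#'
#' @param q upper-tail quantile (default 0.01, i.e. the top 1% of
#'   per-individual maximum repeat sizes); must lie in (0, 0.5).
#' @param min_individuals_per_group minimum genotyped individuals per group at
#'   a locus (default 100).
#' @param known_pathogenic_loci locus ids of known repeat-expansion loci.
#' @return an object of class `tail_config`.
#' @export
tail_config <- function(q = 0.01, min_individuals_per_group = 100L,
                        known_pathogenic_loci = character()) {
  check_scalar_number(q, "q", min = 1e-9, max = 0.5 - 1e-12)
  check_scalar_number(min_individuals_per_group, "min_individuals_per_group",
                      min = 1)
  structure(list(q = q,
                 min_individuals_per_group =
                   as.integer(min_individuals_per_group),
                 known_pathogenic_loci = known_pathogenic_loci),
            class = "tail_config")
}

#' Select screenable STR loci for a gene panel
#'
#' Restricts a context-annotated catalog to loci of the allowed repeat-unit
#' periods (tri- to hexanucleotides by default) in the allowed genic contexts
#' (coding exons and 5'UTRs by default) of the panel's genes. Known
#' pathogenic loci are tagged (`known_pathogenic` column) but retained.
#'
#' @param catalog STR catalog data frame with `locus_id`, `period`.
#' @param contexts_table locus-gene context assignments from
#'   [str_gene_contexts()] semantics: columns `locus_id`, `gene_id`,
#'   `context`. Alternatively pass a [gene_models] object via `models` to
#'   compute it here.
#' @param panel_genes character vector of gene ids in the screening panel.
#' @param periods allowed repeat-unit lengths (default 3:6).
#' @param contexts allowed contexts (default coding exon and 5'UTR).
#' @param known_pathogenic_loci locus ids to tag as known expansions.
#' @param models optional [gene_models] used to compute context assignments
#'   when `contexts_table` is `NULL`.
#' @return the filtered catalog with `gene_id`, `context` and
#'   `known_pathogenic` columns.
#' @export
select_screen_loci <- function(catalog, contexts_table = NULL,
                               panel_genes, periods = 3:6,
                               contexts = c("coding_exon", "five_prime_utr"),
                               known_pathogenic_loci = character(),
                               models = NULL) {
  if (is.null(contexts_table)) {
    if (is.null(models))
      stopf("either 'contexts_table' or 'models' must be supplied")
    contexts_table <- str_gene_contexts(catalog, models)
  }
  ok <- contexts_table$gene_id %in% panel_genes &
    contexts_table$context %in% contexts
  hit <- contexts_table[ok, c("locus_id", "gene_id", "context")]
  hit <- hit[!duplicated(hit$locus_id), ]
  out <- merge(catalog[c("locus_id", "chrom", "start", "end", "period",
                         "ref_repeats")],
               hit, by = "locus_id")
  out <- out[out$period %in% periods, ]
  out$known_pathogenic <- out$locus_id %in% known_pathogenic_loci
  rownames(out) <- NULL
  out[order(out$locus_id), ]
}

#' Per-individual maximum allele size
#'
#' The larger of the available allele repeat counts; a single present allele
#' is its own maximum, and an individual with no called allele yields `NA`
#' (excluded at that locus by the callers, with a log message).
#'
#' @param allele1,allele2 numeric repeat counts; `NA` for missing.
#' @return numeric vector of maxima (`NA` where both alleles are missing).
#' @export
max_allele <- function(allele1, allele2) {
  pmax(allele1, allele2, na.rm = TRUE)
}

#' Compare upper-tail repeat sizes between two groups at one locus
#'
#' Per group, individuals are ranked by their maximum allele; the
#' `ceiling(q * n)` largest values form the tail. Ties at the boundary are
#' resolved deterministically: ordering is by repeat size (descending) then
#' individual id (ascending), and the tail is trimmed to size, so membership
#' does not depend on input row order.
#'
#' @param genotypes data frame `individual_id`, `cohort`, `locus_id`,
#'   `allele1`, `allele2` restricted (or restrictable) to one locus.
#' @param locus locus id to compare.
#' @param case_group,control_group cohort labels to contrast.
#' @param config a [tail_config].
#' @return one-row data frame with per-group n, tail size, tail means, the
#'   difference (case minus control) and quartiles of the per-individual
#'   maxima; `NULL` (with a message) when a group is below the minimum size.
#' @export
top_tail_compare <- function(genotypes, locus, case_group = "case_adult",
                             control_group = "control",
                             config = tail_config()) {
  g <- genotypes[genotypes$locus_id == locus, ]
  g$max_allele <- max_allele(g$allele1, g$allele2)
  if (anyNA(g$max_allele)) {
    message(sprintf("excluding %d individual(s) with no called allele at %s",
                    sum(is.na(g$max_allele)), locus))
    g <- g[!is.na(g$max_allele), ]
  }
  tail_stats <- function(grp) {
    gi <- g[g$cohort == grp, ]
    if (nrow(gi) < config$min_individuals_per_group) return(NULL)
    k <- ceiling(config$q * nrow(gi))
    ord <- order(-gi$max_allele, gi$individual_id)
    list(n = nrow(gi), k = k, tail_mean = mean(gi$max_allele[ord][seq_len(k)]),
         quartiles = unname(stats::quantile(gi$max_allele,
                                            c(0.25, 0.5, 0.75))))
  }
  ca <- tail_stats(case_group)
  co <- tail_stats(control_group)
  if (is.null(ca) || is.null(co)) {
    message(sprintf("locus %s skipped: a group is below %d individuals",
                    locus, config$min_individuals_per_group))
    return(NULL)
  }
  data.frame(locus_id = locus, case_group = case_group,
             control_group = control_group,
             n_case = ca$n, n_control = co$n,
             tail_size_case = ca$k, tail_size_control = co$k,
             tail_mean_case = ca$tail_mean, tail_mean_control = co$tail_mean,
             difference = ca$tail_mean - co$tail_mean,
             case_q25 = ca$quartiles[1], case_median = ca$quartiles[2],
             case_q75 = ca$quartiles[3],
             control_q25 = co$quartiles[1], control_median = co$quartiles[2],
             control_q75 = co$quartiles[3],
             stringsAsFactors = FALSE)
}

#' Tail comparison over a locus panel with pooled class summaries
#'
#' Runs [top_tail_compare()] for every locus in the panel against each
#' requested case group and pools the results by locus class (known
#' pathogenic vs naturally occurring): the pooled difference is the mean of
#' per-locus differences (sign convention: case minus control). With
#' `mode = "pooled"` the per-individual maxima of all loci in a class are
#' instead pooled into a single tail comparison per class.
#'
#' @param loci locus panel from [select_screen_loci()] (needs `locus_id` and
#'   `known_pathogenic`).
#' @param genotypes genotype table (see [top_tail_compare()]).
#' @param case_groups case cohort labels to contrast against controls.
#' @param config a [tail_config].
#' @param mode `"per_locus"` (default) or `"pooled"`.
#' @return list with `per_locus` (data frame of per-locus rows) and `pooled`
#'   (data frame per locus class x case group). Empty inputs give empty
#'   tables with a warning.
#' @export
aggregate_tails <- function(loci, genotypes, case_groups = "case_adult",
                            config = tail_config(),
                            mode = c("per_locus", "pooled")) {
  mode <- match.arg(mode)
  if (!nrow(loci)) stopf("locus panel is empty")
  known <- loci$locus_id[loci$known_pathogenic]
  per_locus <- list()
  pooled <- list()
  for (grp in case_groups) {
    if (mode == "per_locus") {
      rows <- lapply(loci$locus_id, function(l)
        top_tail_compare(genotypes, l, grp, "control", config))
      rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
      per_locus[[grp]] <- rows
      for (cls in c("known_pathogenic", "naturally_occurring")) {
        ids <- if (cls == "known_pathogenic") known
               else setdiff(loci$locus_id, known)
        sub <- rows[rows$locus_id %in% ids, , drop = FALSE]
        if (is.null(sub) || !nrow(sub)) next
        pooled[[length(pooled) + 1L]] <- data.frame(
          locus_class = cls, case_group = grp, n_loci = nrow(sub),
          mean_difference = mean(sub$difference),
          median_case = stats::median(sub$case_median),
          median_control = stats::median(sub$control_median),
          stringsAsFactors = FALSE)
      }
    } else {
      for (cls in c("known_pathogenic", "naturally_occurring")) {
        ids <- if (cls == "known_pathogenic") known
               else setdiff(loci$locus_id, known)
        sub <- genotypes[genotypes$locus_id %in% ids, ]
        if (!nrow(sub)) next
        sub$locus_id <- "pooled"
        row <- top_tail_compare(sub, "pooled", grp, "control", config)
        if (is.null(row)) next
        pooled[[length(pooled) + 1L]] <- data.frame(
          locus_class = cls, case_group = grp, n_loci = length(ids),
          mean_difference = row$difference,
          median_case = row$case_median,
          median_control = row$control_median, stringsAsFactors = FALSE)
      }
    }
  }
  per_locus <- if (length(per_locus)) do.call(rbind, per_locus) else NULL
  if (is.null(per_locus) && mode == "per_locus")
    warning("no loci passed the minimum group sizes")
  list(per_locus = per_locus,
       pooled = if (length(pooled)) do.call(rbind, pooled) else
         data.frame())
}

#' Permutation test for a tail difference at one locus
#'
#' No hypothesis test is attached to tail comparisons by default (the
#' comparison reports a trend); this optional test shuffles cohort labels
#' among the genotyped individuals at the locus and recomputes the tail
#' difference, with an add-one upper-tail p-value. Intended for validating
#' the comparison on synthetic data.
#'
#' @inheritParams top_tail_compare
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @return list with `observed` difference and `p`.
#' @export
tail_permutation_test <- function(genotypes, locus, case_group = "case_adult",
                                  control_group = "control",
                                  config = tail_config(), n_perm = 10000L,
                                  seed = 1L) {
  g <- genotypes[genotypes$locus_id == locus &
                   genotypes$cohort %in% c(case_group, control_group), ]
  obs <- top_tail_compare(g, locus, case_group, control_group, config)
  if (is.null(obs)) stopf("locus %s does not meet the minimum group sizes",
                          locus)
  set.seed(seed)
  m <- g$max_allele <- max_allele(g$allele1, g$allele2)
  n_case <- sum(g$cohort == case_group)
  diff_of <- function(labels) {
    k_ca <- ceiling(config$q * n_case)
    k_co <- ceiling(config$q * (length(m) - n_case))
    ca <- sort(m[labels], decreasing = TRUE)[seq_len(k_ca)]
    co <- sort(m[!labels], decreasing = TRUE)[seq_len(k_co)]
    mean(ca) - mean(co)
  }
  perm <- replicate(n_perm, {
    lab <- rep(FALSE, length(m))
    lab[sample.int(length(m), n_case)] <- TRUE
    diff_of(lab)
  })
  list(observed = obs$difference,
       p = (1 + sum(perm >= obs$difference)) / (n_perm + 1))
}
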