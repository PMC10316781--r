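#' Built-in burden scenarios
#'
#' Four qualifying-variant scenarios: predicted loss-of-function variants
#' (`lof`), predicted pathogenic variants (`pathogenic`, score > 0.8),
#' predicted pathogenic variants in constrained coding regions
#' (`pathogenic_ccr`), and de novo variants (`de_novo`, restricted to
#' probands where de novo calling was possible).
#'
#' @return character vector of scenario names.
#' @export
burden_scenarios <- function() c("lof", "pathogenic", "pathogenic_ccr",
                                 "de_novo")

scenario_predicate <- function(variants, scenario) {
  switch(scenario,
         lof = variants$lof,
         pathogenic = variants$score > 0.8,
         pathogenic_ccr = variants$score > 0.8 & variants$ccr,
         de_novo = variants$de_novo,
         stopf("unknown scenario '%s'", scenario))
}

#' Identify per-gene qualifying-variant carriers under one scenario
#'
#' A variant qualifies when its minor allele frequency is below the threshold
#' for its mode of inheritance (defaults: 0.1% dominant, 1% recessive) and
#' the scenario predicate holds. A proband carries a gene when it has at
#' least one qualifying dominant variant, or at least two qualifying
#' recessive alleles in that gene (a homozygous variant counts as two).
#' Variants with missing frequency are excluded with a message.
#'
#' @param variants data frame with columns `proband_id`, `gene_id`, `score`,
#'   `lof`, `ccr`, `de_novo`, `genotype` (`"het"`/`"hom"`), `maf`, `moi`
#'   (`"dominant"`/`"recessive"`).
#' @param scenario one of [burden_scenarios()].
#' @param maf_thresholds named thresholds for `dominant` and `recessive`.
#' @return data frame of carriers: `gene_id`, `proband_id`.
#' @export
qualify_carriers <- function(variants, scenario,
                             maf_thresholds = c(dominant = 0.001,
                                                recessive = 0.01)) {
  check_columns(variants, c("proband_id", "gene_id", "score", "lof", "ccr",
                            "de_novo", "genotype", "maf", "moi"), "variants")
  if (anyNA(variants$maf)) {
    message(sprintf("excluding %d variant(s) with missing MAF",
                    sum(is.na(variants$maf))))
    variants <- variants[!is.na(variants$maf), ]
  }
  pass <- variants$maf < maf_thresholds[variants$moi] &
    scenario_predicate(variants, scenario)
  v <- variants[pass, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(gene_id = character(), proband_id = character(),
                      stringsAsFactors = FALSE))
  v$alleles <- ifelse(v$genotype == "hom", 2L, 1L)
  dom <- unique(v[v$moi == "dominant", c("gene_id", "proband_id")])
  rec <- v[v$moi == "recessive", ]
  if (nrow(rec)) {
    cnt <- stats::aggregate(alleles ~ gene_id + proband_id, rec, sum)
    rec <- cnt[cnt$alleles >= 2, c("gene_id", "proband_id")]
  } else {
    rec <- dom[0, ]
  }
  out <- unique(rbind(dom, rec))
  rownames(out) <- NULL
  out
}

#' One-sided Fisher's exact test for carrier enrichment in cases
#'
#' For the 2x2 table `(a, b; c, d)` of case carriers/non-carriers vs control
#' carriers/non-carriers, the p-value is the hypergeometric upper-tail
#' probability of observing at least `a` case carriers given the margins.
#' The odds ratio is the sample cross-product ratio `(a d)/(b c)` with the
#' Haldane-Anscombe 0.5 correction applied to all cells when any cell is
#' zero; `or_method = "conditional"` reports the conditional maximum
#' likelihood estimate instead.
#'
#' @param a,b,c,d non-negative integer cell counts (vectorized).
#' @param or_method `"sample"` (default) or `"conditional"`.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_one_sided <- function(a, b, c, d, or_method = c("sample",
                                                       "conditional")) {
  or_method <- match.arg(or_method)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stopf("cell counts must be non-negative integers")
  p <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  odds <- if (or_method == "sample") {
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    ifelse(zero,
           ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
           (a * d) / (b * c))
  } else {
    mapply(function(a, b, c, d)
      unname(stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                alternative = "greater")$estimate),
      a, b, c, d)
  }
  list(odds_ratio = odds, p = p)
}

#' Gene-based case/control rare-variant burden testing
#'
#' Runs the four-way design: childhood-onset genes in adult-onset cases,
#' adult-onset genes in childhood-onset cases, and overlap-onset genes in
#' each case group, every combination against the shared controls, under each
#' requested scenario. Gene tests with fewer than `min_probands` total
#' carriers are dropped before correction; Benjamini-Hochberg runs jointly
#' over all retained tests across scenarios, and the realized family size is
#' recorded on every row.
#'
#' @param variants qualifying-variant table (see [qualify_carriers()]), with
#'   a `de_novo_evaluable` column used by the de novo scenario.
#' @param panels data frame `gene_id`, `panel` with labels in
#'   `adult`, `childhood`, `overlap`, `control`.
#' @param cohorts data frame `proband_id`, `cohort`
#'   (`case_adult`/`case_childhood`/`control`), `de_novo_evaluable`.
#' @param scenarios subset of [burden_scenarios()].
#' @param min_probands minimum total carriers for a test to be retained
#'   (default 4).
#' @param maf_thresholds passed to [qualify_carriers()].
#' @param or_method passed to [fisher_one_sided()].
#' @return data frame with one row per retained gene x scenario test:
#'   counts `a`, `b`, `c_`, `d`, `odds_ratio`, `p`, `p_adj`,
#'   `n_tests_in_family`, and volcano-ready `log2_or`, `neg_log10_p_adj`.
#' @export
run_burden <- function(variants, panels, cohorts,
                       scenarios = burden_scenarios(), min_probands = 4L,
                       maf_thresholds = c(dominant = 0.001, recessive = 0.01),
                       or_method = "sample") {
  check_columns(cohorts, c("proband_id", "cohort", "de_novo_evaluable"),
                "cohorts")
  check_columns(panels, c("gene_id", "panel"), "panels")
  design <- data.frame(panel = c("childhood", "adult", "overlap", "overlap"),
                       case_group = c("case_adult", "case_childhood",
                                      "case_adult", "case_childhood"),
                       stringsAsFactors = FALSE)
  design <- design[design$case_group %in% cohorts$cohort, , drop = FALSE]
  if (!nrow(design)) stopf("no case probands found in 'cohorts'")
  rows <- list()
  for (sc in scenarios) {
    carriers <- qualify_carriers(variants, sc, maf_thresholds)
    for (k in seq_len(nrow(design))) {
      grp <- design$case_group[k]
      genes <- panels$gene_id[panels$panel == design$panel[k]]
      case_ids <- cohorts$proband_id[cohorts$cohort == grp]
      ctrl_ids <- cohorts$proband_id[cohorts$cohort == "control"]
      if (sc == "de_novo") {
        case_ids <- intersect(case_ids,
                              cohorts$proband_id[cohorts$de_novo_evaluable])
        ctrl_ids <- intersect(ctrl_ids,
                              cohorts$proband_id[cohorts$de_novo_evaluable])
      }
      if (!length(case_ids)) stopf("empty case group '%s'", grp)
      for (g in genes) {
        gc <- carriers$proband_id[carriers$gene_id == g]
        a <- length(intersect(gc, case_ids))
        cc <- length(intersect(gc, ctrl_ids))
        if (a + cc < min_probands) next
        ft <- fisher_one_sided(a, length(case_ids) - a, cc,
                               length(ctrl_ids) - cc, or_method = or_method)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, panel = design$panel[k], case_group = grp,
          scenario = sc, a = a, b = length(case_ids) - a, c_ = cc,
          d = length(ctrl_ids) - cc, odds_ratio = ft$odds_ratio, p = ft$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), panel = character(),
                      case_group = character(), scenario = character(),
                      a = integer(), b = integer(), c_ = integer(),
                      d = integer(), odds_ratio = numeric(), p = numeric(),
                      p_adj = numeric(), n_tests_in_family = integer(),
                      log2_or = numeric(), neg_log10_p_adj = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_bh(out$p)
  out$n_tests_in_family <- nrow(out)
  out$log2_or <- log2(out$odds_ratio)
  out$neg_log10_p_adj <- -log10(out$p_adj)
  rownames(out) <- NULL
  out
}
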