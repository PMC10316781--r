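#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes the stages in dependency order — simulate, annotate, expression
#' features, panel comparison, cell-type enrichment, feature selection and
#' embedding, variant burden, STR tail comparison — writing each stage's
#' outputs as TSV/GTF/FASTA/BED under `out_dir` together with a JSON manifest
#' recording the configuration, seed, per-file MD5 checksums and package
#' version. Re-running with an identical configuration reproduces identical
#' checksums for all stages.
#'
#' Every threshold of the analysis is surfaced as an argument with its
#' standard default: the 5-fold tissue and 3.5-fold module-membership rules,
#' 0.9 correlation pruning, 50 selection repeats at 0.8 keep frequency,
#' 0.001/0.01 MAF thresholds with the 4-proband rule, the top-1% tail, and
#' 10000 enrichment bootstraps.
#'
#' @param config a [sim_config].
#' @param out_dir output directory (created if needed).
#' @param tissue_fold,mm_fold expression specificity fold thresholds.
#' @param ewce an [ewce_config].
#' @param rfe an [rfe_config].
#' @param tail a [tail_config].
#' @param min_probands minimum carriers for a burden test.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         tissue_fold = 5, mm_fold = 3.5,
                         ewce = ewce_config(seed = config$seed),
                         rfe = rfe_config(seed = config$seed),
                         tail = tail_config(),
                         min_probands = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(obj, name, writer = write_tsv) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  ## simulate
  ann <- gen_annotation(config)
  catalog <- gen_str_catalog(ann, config)
  disease <- ann$panels$gene_id[ann$panels$panel != "control"]
  childhood <- ann$panels$gene_id[ann$panels$panel == "childhood"]
  fold <- config$planted_effects[["specificity_fold"]]
  plan <- list(
    tissue = data.frame(gene_id = utils::head(disease, 10),
                        column = "tissue_01", fold = fold),
    celltype = data.frame(gene_id = utils::head(childhood, 20),
                          column = "celltype_01", fold = fold))
  expr <- gen_expression(config, ann$panels$gene_id, plan)
  rates <- data.frame(
    gene_id = ann$panels$gene_id,
    rate_case = ifelse(ann$panels$gene_id %in% childhood,
                       config$planted_effects[["carrier_rate_case"]],
                       config$planted_effects[["carrier_rate_control"]]),
    rate_control = config$planted_effects[["carrier_rate_control"]])
  va <- gen_variants(config, rates, case_group = "case_adult")
  vc <- gen_variants(config, rates, case_group = "case_childhood")
  variants <- rbind(va$variants, vc$variants[vc$variants$cohort != "control", ])
  cohorts <- rbind(va$cohorts,
                   vc$cohorts[vc$cohorts$cohort != "control", ])
  emit(ann$models, "gene_models.gtf", write_gtf)
  emit(ann$genome, "genome.fa",
       function(x, p) Biostrings::writeXStringSet(x, p))
  emit(ann$panels, "panels.tsv")
  emit(catalog, "str_catalog.bed", write_str_bed)
  emit(expr$tissue, "expression_tissue.tsv", write_matrix_tsv)
  emit(expr$mm, "module_membership.tsv", write_matrix_tsv)
  emit(expr$celltype, "celltype_means.tsv", write_matrix_tsv)
  emit(variants, "variants.tsv")
  emit(cohorts, "cohorts.tsv")

  ## ancillary annotation tracks derived from the simulated genome
  set.seed(stage_seed(config$seed, "tracks"))
  est_idx <- which(stats::runif(nrow(catalog)) < 0.1)
  tissues <- colnames(expr$tissue)
  estr <- data.frame(
    locus_id = catalog$locus_id[est_idx],
    gene_id = catalog$gene_id[est_idx],
    tissues = vapply(est_idx, function(i)
      paste(sample(tissues, sample(1:3, 1)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  span <- max(ann$models$genes$end)
  rnd_iv <- function(n, w) {
    s <- sort(sample.int(span - w, n))
    data.frame(chrom = "chrS1", start = s,
               end = s + sample.int(w, n, replace = TRUE))
  }
  rmsk <- cbind(family = sample(c("LINE/L1", "SINE/Alu", "Retroposon/SVA"),
                                400, replace = TRUE), rnd_iv(400, 300))
  cncr <- rnd_iv(150, 500)
  emit(estr, "estr.tsv")
  emit(rmsk, "rmsk.tsv")
  emit(cncr, "cncr.bed", function(x, p)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE))

  ## annotate
  features <- gene_features(ann, catalog = catalog, estr = estr,
                            rmsk = rmsk, cncr = cncr)
  emit(features, "features.tsv", write_features)

  ## expression features
  flags_t <- tissue_specific_flags(expr$tissue, fold = tissue_fold)
  flags_m <- mm_specific_flags(expr$mm, fold = mm_fold)
  spec <- specificity_matrix(expr$celltype)
  emit(flags_to_long(flags_t), "tissue_flags.tsv")
  emit(flags_to_long(flags_m), "mm_flags.tsv")
  emit(spec, "specificity.tsv", write_matrix_tsv)

  ## panel comparison
  cmp_features <- intersect(c("gene_length", "n_transcripts", "n_junctions",
                              "gc_content", "n_strs", "n_strs_period3",
                              "n_estrs", "n_estr_tissues", "n_line_l1",
                              "cncr_density"), names(features))
  comparisons <- compare_all_features(features, cmp_features)
  emit(comparisons, "comparisons.tsv")

  ## cell-type enrichment, matched on transcript length and GC content
  covars <- as.matrix(features[match(rownames(spec), features$gene_id),
                               c("gene_length", "gc_content")])
  rownames(covars) <- rownames(spec)
  targets <- split(ann$panels$gene_id, ann$panels$panel)
  targets <- targets[setdiff(names(targets), "control")]
  enr <- adjust_over_grid(ewce_grid(targets, spec, ewce, covars), "all")
  emit(enr, "ewce.tsv")

  ## feature selection and embedding
  num <- features[vapply(features, is.numeric, logical(1))]
  rownames(num) <- features$gene_id
  kept <- prune_correlated(num, rfe$corr_threshold)
  report <- balanced_rfe(num[, kept, drop = FALSE], features$panel, rfe)
  sel <- if (length(report$retained) >= 2) report$retained else kept
  coords <- embed_2d(num[, sel, drop = FALSE], seed = config$seed)
  emit(data.frame(feature = names(report$frequency),
                  frequency = report$frequency,
                  retained = names(report$frequency) %in% report$retained),
       "selection.tsv")
  emit(data.frame(gene_id = rownames(coords), coords,
                  panel = features$panel[match(rownames(coords),
                                               features$gene_id)]),
       "embedding.tsv")

  ## burden
  burden <- run_burden(variants, ann$panels, cohorts,
                       min_probands = min_probands)
  emit(burden, "burden.tsv")

  ## STR tails
  loci <- select_screen_loci(catalog, panel_genes = disease,
                             models = ann$models)
  tails <- NULL
  if (nrow(loci)) {
    genos <- gen_str_genotypes(catalog, config, loci = loci$locus_id)
    tails <- aggregate_tails(loci, genos,
                             case_groups = c("case_adult", "case_childhood"),
                             config = tail)
    emit(loci, "screen_loci.tsv")
    if (!is.null(tails$per_locus)) emit(tails$per_locus, "str_tails.tsv")
    if (nrow(tails$pooled)) emit(tails$pooled, "str_tails_pooled.tsv")
  }

  manifest <- list(tool = "panelomics",
                   version = as.character(utils::packageVersion("panelomics")),
                   seed = config$seed,
                   config = unclass(config),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
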