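test_that("config validation rejects bad fractions, counts and rates", {
  expect_error(sim_config(panel_fractions = c(adult = 0.5, childhood = 0.5,
                                              overlap = 0.2, control = 0.2)),
               "sum to 1")
  expect_error(sim_config(n_tissues = 5), "n_tissues")
  expect_error(sim_config(planted_effects = c(bogus_effect = 1)), "bogus")
  cfg <- sim_config()
  expect_error(gen_variants(cfg, data.frame(gene_id = "g", rate_case = 1.2,
                                            rate_control = 0)),
               "rates")
})

test_that("annotation generation is deterministic and conserves counts", {
  cfg <- sim_config(seed = 3, n_genes = 40)
  a1 <- gen_annotation(cfg)
  a2 <- gen_annotation(cfg)
  expect_identical(a1$models, a2$models)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$panels, a2$panels)
  expect_equal(nrow(a1$panels), 40)
  expect_equal(anyDuplicated(a1$panels$gene_id), 0)
  # every gene: >=1 transcript with >=1 exon, exons inside span
  n_tx <- table(a1$models$transcripts$gene_id)
  expect_true(all(a1$models$genes$gene_id %in% names(n_tx)))
  expect_true(all(a1$models$exons$transcript_id %in%
                    a1$models$transcripts$transcript_id))
})

test_that("rounding-free panel fractions give exact class counts", {
  cfg <- sim_config(seed = 1, n_genes = 100,
                    panel_fractions = c(adult = 0.05, childhood = 0.5,
                                        overlap = 0.2, control = 0.25))
  ann <- gen_annotation(cfg)
  expect_equal(as.vector(table(ann$panels$panel)[c("adult", "childhood",
                                                   "overlap", "control")]),
               c(5, 50, 20, 25))
})

test_that("emitted GC content matches the per-gene target within 2%", {
  cfg <- sim_config(seed = 5, n_genes = 30)
  ann <- gen_annotation(cfg)
  sf <- structure_features(ann$models, ann$genome)
  expect_true(all(abs(sf$gc_content - ann$gc_target[sf$gene_id]) < 0.02))
})

test_that("requested mean transcripts per gene is met over 500 genes", {
  cfg <- sim_config(seed = 2, n_genes = 500, str_per_gene = 1)
  ann <- gen_annotation(cfg)
  mean_tx <- nrow(ann$models$transcripts) / 500
  expect_lt(abs(mean_tx - cfg$mean_transcripts) / cfg$mean_transcripts, 0.1)
})

test_that("STR catalog density scales with the planted class ratio", {
  per_gene_medians <- function(ratio, seed) {
    cfg <- sim_config(seed = seed, n_genes = 100,
                      panel_fractions = c(adult = 0, childhood = 0.5,
                                          overlap = 0, control = 0.5),
                      planted_effects = c(str_density_ratio = ratio))
    ann <- gen_annotation(cfg)
    cat <- gen_str_catalog(ann, cfg)
    counts <- table(factor(cat$gene_id, levels = ann$panels$gene_id))
    split(as.integer(counts), ann$panels$panel[match(names(counts),
                                                     ann$panels$gene_id)])
  }
  # planted 2x density: disease median exceeds control median across seeds
  wins <- vapply(1:6, function(s) {
    m <- per_gene_medians(2, s)
    median(m$childhood) > median(m$control)
  }, logical(1))
  expect_true(all(wins))
  # null ratio: medians statistically indistinguishable in most seeds
  null_ok <- vapply(1:6, function(s) {
    m <- per_gene_medians(1, s)
    wilcoxon_rank_sum(m$childhood, m$control)$p > 0.05
  }, logical(1))
  expect_gte(sum(null_ok), 5)
})

test_that("empty gene set yields an empty catalog", {
  cfg <- sim_config(seed = 1, n_genes = 5)
  ann <- gen_annotation(cfg)
  ann$models$genes <- ann$models$genes[0, ]
  expect_equal(nrow(gen_str_catalog(ann, cfg)), 0)
})

test_that("expression planting hits the fold rule and unknown genes error", {
  cfg <- sim_config(seed = 4, n_genes = 50, n_tissues = 10)
  ids <- sprintf("G%04d", 1:50)
  plan <- list(tissue = data.frame(gene_id = ids[1:5], column = "tissue_01",
                                   fold = 10))
  flagged <- vapply(1:10, function(s) {
    cfg$seed <- as.integer(s)
    ex <- gen_expression(cfg, ids, plan)
    all(tissue_specific_flags(ex$tissue, fold = 5)[ids[1:5], "tissue_01"])
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
  expect_error(gen_expression(cfg, ids,
                              list(tissue = data.frame(gene_id = "nope",
                                                       column = "tissue_01",
                                                       fold = 2))),
               "unknown gene")
  # same seed, identical matrices; mm values bounded
  e1 <- gen_expression(cfg, ids)
  e2 <- gen_expression(cfg, ids)
  expect_identical(e1, e2)
  expect_true(all(e1$mm >= -1 & e1$mm <= 1))
})

test_that("variant generation plants binomial carrier counts", {
  cfg <- sim_config(seed = 8, n_cases_adult = 400, n_controls = 2000)
  rates <- data.frame(gene_id = c("g1", "g2"), rate_case = c(0.05, 0),
                      rate_control = c(0.01, 0))
  v <- gen_variants(cfg, rates)
  expect_identical(v$variants, gen_variants(cfg, rates)$variants)
  carriers <- v$variants[v$variants$gene_id == "g1", ]
  expect_equal(anyDuplicated(carriers$proband_id), 0)
  expect_true(all(carriers$score > 0.8 & carriers$score <= 1))
  expect_true(all(carriers$maf < 0.001))
  expect_equal(sum(v$variants$gene_id == "g2"), 0)
  # rate 0 everywhere -> empty table
  v0 <- gen_variants(cfg, data.frame(gene_id = "g1", rate_case = 0,
                                     rate_control = 0))
  expect_equal(nrow(v0$variants), 0)
})

test_that("STR genotypes are reproducible and respect the null", {
  cfg <- sim_config(seed = 6, n_genes = 10,
                    planted_effects = c(tail_inflation_repeats = 0))
  ann <- gen_annotation(cfg)
  cat <- gen_str_catalog(ann, cfg)
  g1 <- gen_str_genotypes(cat, cfg, groups = c(case_adult = 50, control = 50))
  expect_identical(g1, gen_str_genotypes(cat, cfg,
                                         groups = c(case_adult = 50,
                                                    control = 50)))
  expect_true(all(g1$allele1 >= 1))
  expect_equal(nrow(g1), 100 * nrow(cat))
  # no inflation: case and control allele means agree closely
  expect_lt(abs(mean(g1$allele1[g1$cohort != "control"]) -
                  mean(g1$allele1[g1$cohort == "control"])), 0.5)
  expect_error(gen_str_genotypes(cat[0, ], cfg), "non-empty")
})
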