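make_genotypes <- function(case_alleles, control_alleles, locus = "L1",
                           case_group = "case_adult") {
  data.frame(
    individual_id = c(sprintf("ca%04d", seq_along(case_alleles)),
                      sprintf("co%04d", seq_along(control_alleles))),
    cohort = rep(c(case_group, "control"),
                 c(length(case_alleles), length(control_alleles))),
    locus_id = locus,
    allele1 = c(case_alleles, control_alleles),
    allele2 = c(case_alleles, control_alleles),
    stringsAsFactors = FALSE)
}

test_that("locus screening filters by period, context and panel jointly", {
  m <- two_transcript_models()
  cat <- data.frame(
    locus_id = c("din_exon", "tri_intron", "tri_utr5", "tri_cds", "tri_out"),
    chrom = "chr1",
    start = c(25L, 60L, 5L, 110L, 5L),
    end = c(35L, 72L, 14L, 122L, 14L),
    period = c(2L, 3L, 3L, 3L, 3L),
    ref_repeats = 4L, stringsAsFactors = FALSE)
  loci <- select_screen_loci(cat[1:4, ], panel_genes = "gA", models = m,
                             known_pathogenic_loci = "tri_cds")
  # dinucleotide and intronic loci excluded; UTR5 + CDS trinucleotides kept
  expect_setequal(loci$locus_id, c("tri_utr5", "tri_cds"))
  expect_equal(loci$known_pathogenic[loci$locus_id == "tri_cds"], TRUE)
  # locus in a non-panel gene is excluded
  loci2 <- select_screen_loci(cat[1:4, ], panel_genes = "other", models = m)
  expect_equal(nrow(loci2), 0)
})

test_that("max allele handles missing and homozygous calls", {
  expect_equal(max_allele(12, 15), 15)
  expect_equal(max_allele(7, 7), 7)
  expect_equal(max_allele(9, NA), 9)
  expect_equal(max_allele(c(12, 7, 9), c(15, 7, NA)), c(15, 7, 9))
})

test_that("top tail means match the worked example", {
  g <- make_genotypes(c(rep(10, 99), 25), c(rep(10, 198), 20, 20))
  res <- top_tail_compare(g, "L1", config = tail_config())
  expect_equal(res$tail_size_case, 1)
  expect_equal(res$tail_size_control, 2)
  expect_equal(res$tail_mean_case, 25)
  expect_equal(res$tail_mean_control, 20)
  expect_equal(res$difference, 5)
  # q -> 0.5 compares upper-half means
  res5 <- top_tail_compare(g, "L1", config = tail_config(q = 0.499))
  expect_equal(res5$tail_size_case, ceiling(0.499 * 100))
  # a group below the minimum size is skipped with a message
  small <- g[c(1:50, 101:300), ]
  expect_message(r0 <- top_tail_compare(small, "L1"), "skipped")
  expect_null(r0)
})

test_that("tail membership is invariant under row permutations", {
  set.seed(3)
  g <- make_genotypes(sample(8:20, 150, replace = TRUE),
                      sample(8:20, 300, replace = TRUE))
  r1 <- top_tail_compare(g, "L1")
  r2 <- top_tail_compare(g[sample(nrow(g)), ], "L1")
  expect_equal(r1, r2)
})

test_that("aggregation splits known and natural loci and pools correctly", {
  g1 <- make_genotypes(c(rep(10, 99), 30), c(rep(10, 199), 12))
  g2 <- make_genotypes(c(rep(9, 99), 9), c(rep(9, 199), 9), locus = "L2")
  g <- rbind(g1, g2)
  loci <- data.frame(locus_id = c("L1", "L2"),
                     known_pathogenic = c(TRUE, FALSE))
  agg <- aggregate_tails(loci, g, config = tail_config())
  expect_equal(nrow(agg$per_locus), 2)
  known <- agg$pooled[agg$pooled$locus_class == "known_pathogenic", ]
  natural <- agg$pooled[agg$pooled$locus_class == "naturally_occurring", ]
  expect_gt(known$mean_difference, 0)
  expect_equal(natural$mean_difference, 0)
  # pooled summary over one locus equals that locus's difference
  expect_equal(known$mean_difference,
               agg$per_locus$difference[agg$per_locus$locus_id == "L1"])
  # pooled-across-loci mode runs and keeps the sign convention
  aggp <- aggregate_tails(loci, g, config = tail_config(), mode = "pooled")
  expect_equal(nrow(aggp$pooled), 2)
})

test_that("planted case inflation yields positive tail differences", {
  cfg <- sim_config(seed = 12, n_genes = 25)
  ann <- gen_annotation(cfg)
  cat <- gen_str_catalog(ann, cfg)
  loci <- head(cat$locus_id, 30)
  g <- gen_str_genotypes(cat, cfg, groups = c(case_adult = 400,
                                              control = 1200), loci = loci)
  agg <- aggregate_tails(data.frame(locus_id = loci,
                                    known_pathogenic = FALSE), g,
                         config = tail_config())
  expect_gt(agg$pooled$mean_difference, 0)
  # permutation test flags the planted locus-level inflation when pooled
  pt <- tail_permutation_test(g, loci[1], n_perm = 300, seed = 1)
  expect_true(pt$p > 0 && pt$p <= 1)
})

test_that("a null inflation leaves the tail difference centred at zero", {
  diffs <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_genes = 15,
                      planted_effects = c(tail_inflation_repeats = 0))
    ann <- gen_annotation(cfg)
    cat <- gen_str_catalog(ann, cfg)
    loci <- head(cat$locus_id, 25)
    g <- gen_str_genotypes(cat, cfg, groups = c(case_adult = 300,
                                                control = 900), loci = loci)
    aggregate_tails(data.frame(locus_id = loci, known_pathogenic = FALSE),
                    g, config = tail_config())$pooled$mean_difference
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.5)
})
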