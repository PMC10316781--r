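test_that("GTF round-trips through the internal representation", {
  cfg <- sim_config(seed = 7, n_genes = 15)
  ann <- gen_annotation(cfg)
  f <- tempfile(fileext = ".gtf")
  write_gtf(ann$models, f)
  m2 <- suppressWarnings(read_gtf(f))
  norm <- function(df) {
    df <- df[do.call(order, df), ]
    rownames(df) <- NULL
    df
  }
  for (slot in c("genes", "exons", "cds", "utr5", "utr3"))
    expect_equal(norm(as.data.frame(lapply(ann$models[[slot]], as.vector))),
                 norm(m2[[slot]]), ignore_attr = TRUE, tolerance = 0)
  # writing the re-read models reproduces the file byte for byte
  f2 <- tempfile(fileext = ".gtf")
  write_gtf(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("count_gene_overlaps matches hand-computed cases", {
  m <- neighbour_models()
  # interval inside only gA's private part plus one fully outside
  iv <- data.frame(chrom = "chr1", start = c(150L, 300L), end = c(160L, 310L))
  g1 <- gene_models(data.frame(gene_id = "g", chrom = "chr1", start = 100L,
                               end = 200L, strand = "+"),
                    data.frame(transcript_id = "g.T1", gene_id = "g"),
                    data.frame(gene_id = "g", transcript_id = "g.T1",
                               start = 100L, end = 200L))
  expect_equal(unname(count_gene_overlaps(iv, g1)), 1L)
  # shared interval counts toward both overlapping genes
  expect_equal(count_gene_overlaps(data.frame(chrom = "chr1", start = 60L,
                                              end = 70L), m),
               c(gA = 1L, gB = 1L))
  expect_equal(unname(count_gene_overlaps(iv[0, ], m)), c(0L, 0L))
  expect_error(count_gene_overlaps(data.frame(chrom = "chr1", start = 10L,
                                              end = 10L), m),
               "malformed")
})

test_that("interval counts and densities match the per-base oracle", {
  for (seed in 1:25) {
    inst <- random_interval_instance(seed)
    expect_equal(count_gene_overlaps(inst$intervals, inst$models),
                 brute_force_counts(inst$intervals, inst$models))
    expect_equal(cncr_density(inst$models, inst$intervals),
                 brute_force_density(inst$intervals, inst$models))
  }
})

test_that("STR context classification follows the precedence rule", {
  m <- two_transcript_models()
  # inside the intron of both transcripts
  expect_equal(classify_str_context(list(chrom = "chr1", start = 60L,
                                         end = 80L), m, "gA"), "intron")
  # spans CDS and flanking intron -> coding wins
  expect_equal(classify_str_context(list(chrom = "chr1", start = 40L,
                                         end = 120L), m, "gA"), "coding_exon")
  # 5'UTR in T1, would be exonic nowhere else; precedence over intron in T2
  expect_equal(classify_str_context(list(chrom = "chr1", start = 5L,
                                         end = 15L), m, "gA"),
               "five_prime_utr")
  expect_equal(classify_str_context(list(chrom = "chr1", start = 270L,
                                         end = 280L), m, "gA"),
               "three_prime_utr")
  expect_error(classify_str_context(list(chrom = "chr1", start = 400L,
                                         end = 410L), m, "gA"),
               "does not overlap")
  # without CDS/UTR annotation any exon overlap is coding
  expect_equal(classify_str_context(list(chrom = "chr1", start = 10L,
                                         end = 20L), neighbour_models(),
                                    "gA"), "coding_exon")
})

test_that("str_features counts partition by period and context", {
  m <- two_transcript_models()
  cat <- data.frame(locus_id = c("s1", "s2", "s3"), chrom = "chr1",
                    start = c(30L, 110L, 65L), end = c(42L, 122L, 77L),
                    period = c(3L, 3L, 4L), ref_repeats = c(4L, 4L, 3L),
                    stringsAsFactors = FALSE)
  sf <- str_features(m, cat)
  expect_equal(sf$n_strs, 3L)
  expect_equal(sf$n_strs_period3, 2L)
  expect_equal(sf$n_strs, sum(sf[, sprintf("n_strs_period%d", 2:6)]))
  ctx_cols <- sprintf("n_strs_%s", c("coding_exon", "five_prime_utr",
                                     "three_prime_utr", "intron"))
  expect_equal(sf$n_strs, sum(sf[, ctx_cols]))
  expect_equal(sf$n_strs_coding_exon, 2L)
  expect_equal(sf$n_strs_intron, 1L)
  # no loci -> all zero
  sf0 <- str_features(m, cat[0, ])
  expect_equal(sf0$n_strs, 0L)
  expect_equal(sum(unlist(sf0[, -1])), 0)
})

test_that("eSTR features deduplicate and union tissues", {
  estr <- data.frame(locus_id = c("e1", "e2", "e2"), gene_id = "gA",
                     tissues = c("brain", "brain,blood", "brain,blood"),
                     stringsAsFactors = FALSE)
  ef <- estr_features(c("gA", "gB"), estr)
  expect_equal(ef$n_estrs, c(2L, 0L))
  expect_equal(ef$n_estr_tissues, c(2L, 0L))
})

test_that("cncr_density handles unions, edge cases and splitting", {
  g1 <- gene_models(data.frame(gene_id = "g", chrom = "chr1", start = 0L,
                               end = 100L, strand = "+"),
                    data.frame(transcript_id = "g.T1", gene_id = "g"),
                    data.frame(gene_id = "g", transcript_id = "g.T1",
                               start = 0L, end = 100L))
  seg <- data.frame(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L))
  expect_equal(unname(cncr_density(g1, seg)), 0.2)
  expect_equal(unname(cncr_density(g1, seg[0, ])), 0)
  expect_equal(unname(cncr_density(g1, data.frame(chrom = "chr1", start = 0L,
                                                  end = 100L))), 1)
  # invariant under segment order and adjacent splitting
  split_seg <- data.frame(chrom = "chr1", start = c(15L, 25L, 10L),
                          end = c(25L, 30L, 20L))
  expect_equal(cncr_density(g1, split_seg), cncr_density(g1, seg))
})

test_that("structure features count unique junctions and GC", {
  m <- two_transcript_models()
  sf <- structure_features(m)
  # T1 junctions (50,100) (150,200); T2 junction (50,200) -> 3 unique
  expect_equal(sf$n_junctions, 3L)
  expect_equal(sf$n_transcripts, 2L)
  expect_equal(sf$gene_length, 300L)
  # single-exon genes have no junctions
  expect_equal(structure_features(neighbour_models())$n_junctions, c(0L, 0L))
  genome <- Biostrings::DNAStringSet(paste(rep("GGCC", 75), collapse = ""))
  names(genome) <- "chr1"
  expect_equal(structure_features(m, genome)$gc_content, 1)
})

test_that("spec'd junction example: shared junctions deduplicate", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 0L, end = 50L,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = c("g.T1", "g.T2"), gene_id = "g")
  exons <- data.frame(
    gene_id = "g", transcript_id = rep(c("g.T1", "g.T2"), c(3, 2)),
    start = c(0L, 20L, 40L, 0L, 20L), end = c(10L, 30L, 50L, 10L, 30L))
  m <- gene_models(genes, tx, exons)
  expect_equal(structure_features(m)$n_junctions, 2L)
})

test_that("HipSTR-dialect BED coordinates round-trip with both dialects", {
  cat <- data.frame(locus_id = c("s1", "s2"), chrom = "chr1",
                    start = c(100L, 220L), end = c(112L, 240L),
                    period = c(3L, 4L), ref_repeats = c(4L, 5L),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_str_bed(cat, f)
  back <- read_str_bed(f)
  expect_equal(back, cat, ignore_attr = TRUE)
  # on-disk end is inclusive
  raw <- read.table(f, sep = "\t")
  expect_equal(raw$V3, cat$end - 1L)
  # one-based dialect shifts starts down on read
  back1 <- read_str_bed(f, one_based = TRUE)
  expect_equal(back1$start, raw$V2 - 1L)
})

test_that("feature table assembles with metadata sidecar", {
  cfg <- sim_config(seed = 9, n_genes = 20)
  ann <- gen_annotation(cfg)
  cat <- gen_str_catalog(ann, cfg)
  feats <- gene_features(ann, catalog = cat)
  expect_equal(nrow(feats), 20)
  expect_true(all(c("gene_id", "panel", "gene_length", "n_strs") %in%
                    names(feats)))
  meta <- attr(feats, "metadata")
  expect_setequal(meta$name, setdiff(names(feats), c("gene_id", "panel")))
  f <- tempfile(fileext = ".tsv")
  write_features(feats, f)
  expect_true(file.exists(paste0(f, ".meta.tsv")))
  expect_equal(nrow(read_tsv(f)), 20)
})
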