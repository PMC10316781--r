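# exhaustive oracle: p(X >= a) over all tables with the observed margins,
# table probabilities from binomial coefficients directly
fisher_enumeration_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  sum(exp(logp)[xs >= a])
}

test_that("one-sided Fisher equals the enumeration oracle on all small tables", {
  for (a in 0:6) for (b in 0:5) for (c in 0:5) for (d in 0:4) {
    if (a + b == 0 || c + d == 0) next
    expect_equal(fisher_one_sided(a, b, c, d)$p,
                 fisher_enumeration_oracle(a, b, c, d), tolerance = 1e-12)
  }
})

test_that("Fisher odds ratio uses the Haldane correction on zero cells", {
  ft <- fisher_one_sided(3, 1, 1, 3)
  expect_equal(ft$p, 17 / 70)
  expect_equal(ft$odds_ratio, 9)
  expect_equal(fisher_one_sided(0, 5, 2, 3)$p, 1)
  z <- fisher_one_sided(4, 0, 1, 5)
  expect_equal(z$odds_ratio, (4.5 * 5.5) / (0.5 * 1.5))
  # conditional MLE route agrees with fisher.test
  est <- fisher_one_sided(6, 2, 1, 7, or_method = "conditional")$odds_ratio
  expect_equal(est,
               unname(fisher.test(matrix(c(6, 2, 1, 7), 2, byrow = TRUE),
                                  alternative = "greater")$estimate))
  expect_error(fisher_one_sided(-1, 1, 1, 1), "non-negative")
})

test_that("carrier qualification follows MAF, scenario and MOI rules", {
  v <- data.frame(
    proband_id = c("p1", "p2", "p3", "p3", "p4", "p5"),
    gene_id = "g1",
    score = c(0.9, 0.9, 0.85, 0.95, 0.99, 0.5),
    lof = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    ccr = FALSE, de_novo = FALSE,
    genotype = c("het", "het", "het", "het", "hom", "het"),
    maf = c(0.0005, 0.005, 0.004, 0.006, 0.002, 0.0001),
    moi = c("dominant", "dominant", "recessive", "recessive", "recessive",
            "dominant"),
    stringsAsFactors = FALSE)
  # lof scenario: p1 passes (rare dominant LoF); p2 fails MAF; p6 fails flag?
  lof <- qualify_carriers(v, "lof")
  expect_equal(lof$proband_id, c("p1", "p5"))
  # pathogenic: p1 (dominant), p3 (two passing recessive hets),
  # p4 (hom counts as two alleles); p2 fails dominant MAF
  path <- qualify_carriers(v, "pathogenic")
  expect_setequal(path$proband_id, c("p1", "p3", "p4"))
  # a single passing recessive het is not a carrier
  single <- v[3, ]
  expect_equal(nrow(qualify_carriers(single, "pathogenic")), 0)
  # missing MAF rows are excluded with a message
  v2 <- v
  v2$maf[1] <- NA
  expect_message(q2 <- qualify_carriers(v2, "pathogenic"), "missing MAF")
  expect_false("p1" %in% q2$proband_id)
})

test_that("run_burden applies the design grid, min-proband rule and joint BH", {
  cohorts <- data.frame(
    proband_id = c(sprintf("a%02d", 1:20), sprintf("c%02d", 1:40)),
    cohort = rep(c("case_adult", "control"), c(20, 40)),
    de_novo_evaluable = TRUE, stringsAsFactors = FALSE)
  mkvar <- function(gene, probands) data.frame(
    proband_id = probands, gene_id = gene, score = 0.9, lof = TRUE,
    ccr = TRUE, de_novo = FALSE, de_novo_evaluable = TRUE, genotype = "het",
    maf = 1e-4, moi = "dominant", stringsAsFactors = FALSE)
  variants <- rbind(mkvar("g1", c(sprintf("a%02d", 1:5), "c01")),
                    mkvar("g2", c("a01", "c02", "c03")))
  panels <- data.frame(gene_id = c("g1", "g2"),
                       panel = "childhood", stringsAsFactors = FALSE)
  res <- run_burden(variants, panels, cohorts,
                    scenarios = c("lof", "pathogenic"))
  # g1 retained in both scenarios (6 carriers); g2 dropped (3 < 4)
  expect_setequal(unique(res$gene_id), "g1")
  expect_equal(nrow(res), 2)
  expect_equal(res$a + res$b, rep(20L, 2))
  expect_equal(res$c_ + res$d, rep(40L, 2))
  expect_equal(res$n_tests_in_family, rep(2L, 2))
  expect_equal(res$p_adj, fdr_bh(res$p))
  # adding a scenario changes the family and p_adj but not raw p
  res3 <- run_burden(variants, panels, cohorts,
                     scenarios = c("lof", "pathogenic", "pathogenic_ccr"))
  expect_equal(res3$p[res3$scenario == "lof"],
               res$p[res$scenario == "lof"])
  expect_equal(unique(res3$n_tests_in_family), 3L)
  # empty case group errors
  expect_error(run_burden(variants, panels,
                          cohorts[cohorts$cohort == "control", ]),
               "no case probands")
})

test_that("de novo testing restricts to evaluable probands", {
  cohorts <- data.frame(
    proband_id = c(sprintf("a%02d", 1:10), sprintf("c%02d", 1:10)),
    cohort = rep(c("case_adult", "control"), each = 10),
    de_novo_evaluable = rep(c(TRUE, FALSE), 10), stringsAsFactors = FALSE)
  variants <- data.frame(
    proband_id = c("a01", "a03", "a05", "a07", "c01"), gene_id = "g1",
    score = 0.9, lof = FALSE, ccr = FALSE, de_novo = TRUE,
    de_novo_evaluable = TRUE, genotype = "het", maf = 1e-4,
    moi = "dominant", stringsAsFactors = FALSE)
  panels <- data.frame(gene_id = "g1", panel = "childhood")
  res <- run_burden(variants, panels, cohorts, scenarios = "de_novo")
  # only evaluable probands count in numerators and denominators
  expect_equal(res$a + res$b, sum(cohorts$de_novo_evaluable &
                                    cohorts$cohort == "case_adult"))
  expect_equal(res$c_ + res$d, sum(cohorts$de_novo_evaluable &
                                     cohorts$cohort == "control"))
})

test_that("planted carrier rates recover the expected odds ratio", {
  ors <- vapply(1:60, function(s) {
    cfg <- sim_config(seed = s, n_genes = 1)
    v <- gen_variants(cfg, data.frame(gene_id = "G0001",
                                      rate_case = 6 / 816,
                                      rate_control = 7 / 6658))
    b <- run_burden(v$variants, data.frame(gene_id = "G0001",
                                           panel = "childhood"),
                    v$cohorts, scenarios = "pathogenic", min_probands = 0L)
    b$odds_ratio
  }, numeric(1))
  expect_lt(abs(exp(mean(log(ors))) / 7.038 - 1), 0.25)
  expect_gt(mean(ors > 1), 0.9)
})
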