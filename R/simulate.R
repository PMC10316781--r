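#' Generate synthetic gene models, genome sequence and panel labels
#'
#' Lays out `n_genes` non-overlapping genes on one synthetic chromosome
#' (`chrS1`). Each gene has a master exon set; its first transcript uses all
#' master exons and additional transcripts drop exons at random, giving a mean
#' transcript count of `mean_transcripts`. Each transcript's exonic sequence is
#' partitioned into 5'UTR (~20%), CDS and 3'UTR (~20%) in transcript
#' orientation. The emitted sequence carries an exact per-gene GC count drawn
#' from a Beta-shaped target in [0.3, 0.6], so observed GC matches the target
#' to within half a base.
#'
#' @param config a [sim_config].
#' @return a list with elements `models` ([gene_models]), `genome`
#'   (a named [Biostrings::DNAStringSet]), `panels` (data frame `gene_id`,
#'   `panel`), `gc_target` (named numeric) and `config`.
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "annotation"))
  n <- config$n_genes
  classes <- c("adult", "childhood", "overlap", "control")
  counts <- panel_counts(n, config$panel_fractions)
  labels <- sample(rep(classes, counts))
  gene_ids <- sprintf("G%04d", seq_len(n))

  genes <- tx <- ex <- cds <- u5 <- u3 <- list()
  cursor <- 0L
  for (i in seq_len(n)) {
    cursor <- cursor + 200L + stats::rnbinom(1, size = 1, mu = 300)
    k <- 1L + stats::rpois(1, config$mean_exons - 1)
    exon_len <- 30L + stats::rnbinom(k, size = 2, mu = 120)
    intron_len <- if (k > 1) 50L + stats::rnbinom(k - 1, size = 1, mu = 750)
                  else integer(0)
    starts <- cursor + cumsum(c(0L, exon_len[-k] + intron_len))
    ends <- starts + exon_len
    strand <- sample(c("+", "-"), 1)
    genes[[i]] <- data.frame(gene_id = gene_ids[i], chrom = "chrS1",
                             start = cursor, end = ends[k], strand = strand,
                             stringsAsFactors = FALSE)
    n_t <- 1L + stats::rpois(1, config$mean_transcripts - 1)
    for (t in seq_len(n_t)) {
      keep <- if (t == 1L) rep(TRUE, k) else stats::runif(k) < 0.75
      if (!any(keep)) keep[sample.int(k, 1)] <- TRUE
      tid <- sprintf("%s.T%02d", gene_ids[i], t)
      e <- data.frame(gene_id = gene_ids[i], transcript_id = tid,
                      start = starts[keep], end = ends[keep],
                      stringsAsFactors = FALSE)
      tx[[length(tx) + 1L]] <- data.frame(transcript_id = tid,
                                          gene_id = gene_ids[i],
                                          stringsAsFactors = FALSE)
      ex[[length(ex) + 1L]] <- e
      parts <- partition_transcript(e, strand)
      cds[[length(cds) + 1L]] <- parts$cds
      u5[[length(u5) + 1L]] <- parts$utr5
      u3[[length(u3) + 1L]] <- parts$utr3
    }
    cursor <- ends[k]
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  models <- gene_models(bind(genes), bind(tx), bind(ex),
                        cds = bind(cds), utr5 = bind(u5), utr3 = bind(u3))

  total_len <- models$genes$end[n] + 500L
  seq_chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  gc_target <- stats::setNames(0.3 + 0.3 * stats::rbeta(n, 2, 2), gene_ids)
  for (i in seq_len(n)) {
    span <- (models$genes$start[i] + 1L):models$genes$end[i]
    len <- length(span)
    n_gc <- round(gc_target[i] * len)
    gc_pos <- span[sample.int(len, n_gc)]
    seq_chars[span] <- sample(c("A", "T"), len, replace = TRUE)
    seq_chars[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "chrS1"

  list(models = models,
       genome = genome,
       panels = data.frame(gene_id = gene_ids, panel = labels,
                           stringsAsFactors = FALSE),
       gc_target = gc_target,
       config = config)
}

# split a transcript's exonic bases into 5'UTR / CDS / 3'UTR in transcript
# orientation; tiny transcripts (<9 exonic bases) are all-CDS
partition_transcript <- function(exons, strand, frac5 = 0.2, frac3 = 0.2) {
  pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L), exons$start,
                       exons$end, SIMPLIFY = FALSE))
  pos <- sort(pos)
  L <- length(pos)
  tmpl <- function(p) {
    if (!length(p)) return(data.frame(gene_id = character(),
                                      transcript_id = character(),
                                      start = integer(), end = integer(),
                                      stringsAsFactors = FALSE))
    iv <- runs_to_intervals(sort(p))
    data.frame(gene_id = exons$gene_id[1], transcript_id = exons$transcript_id[1],
               start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  }
  if (L < 9L)
    return(list(utr5 = tmpl(integer(0)), cds = tmpl(pos),
                utr3 = tmpl(integer(0))))
  n5 <- max(1L, round(frac5 * L))
  n3 <- max(1L, round(frac3 * L))
  ordered <- if (strand == "+") pos else rev(pos)
  list(utr5 = tmpl(ordered[seq_len(n5)]),
       cds = tmpl(ordered[(n5 + 1L):(L - n3)]),
       utr3 = tmpl(ordered[(L - n3 + 1L):L]))
}

# consecutive sorted integer positions -> 0-based half-open intervals
runs_to_intervals <- function(pos) {
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1L],
             end = pos[brk[-1]] + 1L)
}

#' Generate a synthetic STR catalog (HipSTR-dialect)
#'
#' Per-gene STR counts are Poisson with expectation `str_per_gene` for
#' control-class genes and `str_density_ratio` times that for disease-class
#' genes (adult, childhood, overlap). A fraction `str_exonic_prob` of loci is
#' targeted at exons of the gene's canonical transcript; the rest are placed
#' uniformly in the gene span (hence mostly intronic, as in real catalogs).
#' Periods are drawn from 2-6 repeat units.
#'
#' @param annotation result of [gen_annotation()].
#' @param config a [sim_config]; defaults to the one stored in `annotation`.
#' @return a data frame with columns `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `period`, `ref_repeats` and `gene_id` (simulation
#'   truth; dropped by [write_str_bed()]).
#' @export
gen_str_catalog <- function(annotation, config = annotation$config) {
  set.seed(stage_seed(config$seed, "str_catalog"))
  empty <- data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(), period = integer(),
                      ref_repeats = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  g <- annotation$models$genes
  if (!nrow(g)) return(empty)
  ratio <- config$planted_effects[["str_density_ratio"]]
  class_of <- annotation$panels$panel[match(g$gene_id, annotation$panels$gene_id)]
  lambda <- config$str_per_gene * ifelse(class_of == "control", 1, ratio)
  n_str <- stats::rpois(nrow(g), lambda)
  out <- list()
  for (i in seq_len(nrow(g))) {
    if (n_str[i] == 0) next
    canon <- annotation$models$exons[
      annotation$models$exons$transcript_id == sprintf("%s.T01", g$gene_id[i]), ]
    for (j in seq_len(n_str[i])) {
      period <- sample(2:6, 1)
      reps <- 3L + stats::rnbinom(1, size = 2, mu = 4)
      win <- if (stats::runif(1) < config$str_exonic_prob && nrow(canon)) {
        e <- canon[sample.int(nrow(canon), 1), ]
        c(e$start, e$end)
      } else c(g$start[i], g$end[i])
      len <- period * reps
      if (len > win[2] - win[1]) {
        reps <- max(2L, (win[2] - win[1]) %/% period)
        len <- period * reps
      }
      s <- win[1] + sample.int(max(1L, win[2] - win[1] - len + 1L), 1) - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = g$chrom[i], start = s, end = s + len,
        period = period, ref_repeats = reps, gene_id = g$gene_id[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  cat <- do.call(rbind, out)
  cat <- cat[order(cat$start), ]
  cat <- cbind(locus_id = sprintf("STR_%05d", seq_len(nrow(cat))), cat,
               stringsAsFactors = FALSE)
  rownames(cat) <- NULL
  cat
}

#' Generate synthetic expression, module-membership and cell-type matrices
#'
#' Background tissue expression is log-normal; module-membership values are
#' uniform in `[-0.2, 0.5]`; cell-type mean expression is log-normal. Planting
#' sets the target entry of a planted gene to `fold` times the mean of that
#' gene's values in the remaining columns, so downstream fold-change rules see
#' exactly the planted fold against the gene's own background.
#'
#' @param config a [sim_config].
#' @param gene_ids character vector of gene identifiers (from
#'   [gen_annotation()]), keying all output rows.
#' @param plan optional list with any of `tissue`, `mm`, `celltype`, each a
#'   data frame with columns `gene_id`, `column` (tissue/cell-type name) and
#'   `fold`. Unknown gene ids are an error.
#' @return list with matrices `tissue`, `mm`, `celltype` (genes in rows).
#' @export
gen_expression <- function(config, gene_ids, plan = NULL) {
  set.seed(stage_seed(config$seed, "expression"))
  n <- length(gene_ids)
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  celltypes <- sprintf("celltype_%02d", seq_len(config$n_celltypes))
  expr <- matrix(stats::rlnorm(n * config$n_tissues, 2, 0.5), nrow = n,
                 dimnames = list(gene_ids, tissues))
  mm <- matrix(stats::runif(n * config$n_tissues, -0.2, 0.5), nrow = n,
               dimnames = list(gene_ids, tissues))
  ct <- matrix(stats::rlnorm(n * config$n_celltypes, 0, 0.6), nrow = n,
               dimnames = list(gene_ids, celltypes))
  plant <- function(mat, spec, clip = NULL) {
    if (is.null(spec)) return(mat)
    check_columns(spec, c("gene_id", "column", "fold"), "plan")
    if (!all(spec$gene_id %in% rownames(mat)))
      stopf("plan references unknown gene id(s): %s",
            paste(setdiff(spec$gene_id, rownames(mat)), collapse = ", "))
    if (!all(spec$column %in% colnames(mat)))
      stopf("plan references unknown column(s): %s",
            paste(setdiff(spec$column, colnames(mat)), collapse = ", "))
    for (i in seq_len(nrow(spec))) {
      g <- spec$gene_id[i]; cl <- spec$column[i]
      others <- mat[g, setdiff(colnames(mat), cl)]
      val <- spec$fold[i] * mean(pmax(others, 0))
      mat[g, cl] <- if (is.null(clip)) val else min(clip, val)
    }
    mat
  }
  list(tissue = plant(expr, plan$tissue),
       mm = plant(mm, plan$mm, clip = 0.99),
       celltype = plant(ct, plan$celltype))
}

#' Generate a synthetic proband qualifying-variant table
#'
#' Per-gene carrier counts are Binomial(n, rate) in each cohort, with at most
#' one qualifying variant per proband per gene (dominant model). Emitted rows
#' emulate a post-filtering candidate table: pathogenicity scores in
#' (0.8, 1], dominant-MOI minor allele frequencies below 0.1%, and
#' LoF / constrained-coding-region / de-novo flags.
#'
#' @param config a [sim_config].
#' @param gene_rates data frame with columns `gene_id`, `rate_case`,
#'   `rate_control`, rates in `[0, 1]`.
#' @param case_group `"case_adult"` or `"case_childhood"`; fixes the case
#'   cohort and its size.
#' @return list with `variants` (one row per qualifying variant) and `cohorts`
#'   (one row per proband: `proband_id`, `cohort`, `de_novo_evaluable`).
#' @export
gen_variants <- function(config, gene_rates,
                         case_group = c("case_adult", "case_childhood")) {
  case_group <- match.arg(case_group)
  check_columns(gene_rates, c("gene_id", "rate_case", "rate_control"),
                "gene_rates")
  if (any(gene_rates$rate_case < 0 | gene_rates$rate_case > 1 |
          gene_rates$rate_control < 0 | gene_rates$rate_control > 1))
    stopf("carrier rates must lie in [0, 1]")
  set.seed(stage_seed(config$seed, paste0("variants_", case_group)))
  n_case <- if (case_group == "case_adult") config$n_cases_adult
            else config$n_cases_childhood
  ids_case <- sprintf("%s%05d",
                      if (case_group == "case_adult") "CASEA" else "CASEC",
                      seq_len(n_case))
  ids_ctrl <- sprintf("CTRL%05d", seq_len(config$n_controls))
  cohorts <- data.frame(
    proband_id = c(ids_case, ids_ctrl),
    cohort = c(rep(case_group, n_case), rep("control", config$n_controls)),
    de_novo_evaluable = stats::runif(n_case + config$n_controls) < 0.5,
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(gene_rates))) {
    carriers_case <- ids_case[stats::runif(n_case) < gene_rates$rate_case[i]]
    carriers_ctrl <- ids_ctrl[stats::runif(config$n_controls) <
                                gene_rates$rate_control[i]]
    carriers <- c(carriers_case, carriers_ctrl)
    if (!length(carriers)) next
    evaluable <- cohorts$de_novo_evaluable[match(carriers, cohorts$proband_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      proband_id = carriers,
      cohort = c(rep(case_group, length(carriers_case)),
                 rep("control", length(carriers_ctrl))),
      gene_id = gene_rates$gene_id[i],
      score = stats::runif(length(carriers), 0.801, 0.999),
      lof = stats::runif(length(carriers)) < 0.5,
      ccr = stats::runif(length(carriers)) < 0.35,
      de_novo = evaluable & stats::runif(length(carriers)) < 0.15,
      de_novo_evaluable = evaluable,
      genotype = "het",
      maf = stats::runif(length(carriers), 0, 0.00099),
      moi = "dominant",
      stringsAsFactors = FALSE)
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(proband_id = character(), cohort = character(),
               gene_id = character(), score = numeric(), lof = logical(),
               ccr = logical(), de_novo = logical(),
               de_novo_evaluable = logical(), genotype = character(),
               maf = numeric(), moi = character(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(variants = variants, cohorts = cohorts)
}

#' Generate synthetic STR genotypes with optional case tail inflation
#'
#' Baseline allele sizes are the catalog reference repeat count plus a
#' discretized negative-binomial jitter (right-skewed, floored at one repeat
#' unit). In case cohorts a fraction `tail_inflation_fraction` of alleles is
#' independently inflated by `tail_inflation_repeats` units; control alleles
#' are never inflated.
#'
#' @param catalog STR catalog data frame (from [gen_str_catalog()] or
#'   [read_str_bed()]); must be non-empty.
#' @param config a [sim_config].
#' @param groups named integer vector of cohort sizes; names must be drawn
#'   from `case_adult`, `case_childhood`, `control`. Defaults to the config's
#'   cohort sizes.
#' @param loci optional character vector restricting output to these locus ids.
#' @return data frame `individual_id`, `cohort`, `locus_id`, `allele1`,
#'   `allele2` (repeat units).
#' @export
gen_str_genotypes <- function(catalog, config, groups = NULL, loci = NULL) {
  if (!nrow(catalog)) stopf("catalog must be non-empty")
  if (is.null(groups))
    groups <- c(case_adult = config$n_cases_adult,
                case_childhood = config$n_cases_childhood,
                control = config$n_controls)
  if (!all(names(groups) %in% c("case_adult", "case_childhood", "control")))
    stopf("unknown group name(s) in 'groups'")
  groups <- groups[groups > 0]
  set.seed(stage_seed(config$seed, "str_genotypes"))
  if (!is.null(loci)) catalog <- catalog[catalog$locus_id %in% loci, ]
  if (!nrow(catalog)) stopf("no catalog loci left after 'loci' restriction")
  prefix <- c(case_adult = "SA", case_childhood = "SC", control = "SN")
  ind <- do.call(rbind, lapply(names(groups), function(g) data.frame(
    individual_id = sprintf("%s%05d", prefix[[g]], seq_len(groups[[g]])),
    cohort = g, stringsAsFactors = FALSE)))
  n_ind <- nrow(ind)
  n_loc <- nrow(catalog)
  ref <- rep(catalog$ref_repeats, each = n_ind)
  draw <- function() {
    a <- pmax(1L, ref + stats::rnbinom(n_ind * n_loc, size = 4, mu = 2) - 2L)
    is_case <- rep(ind$cohort != "control", n_loc)
    frac <- config$planted_effects[["tail_inflation_fraction"]]
    bump <- config$planted_effects[["tail_inflation_repeats"]]
    if (bump > 0 && frac > 0) {
      hit <- is_case & stats::runif(n_ind * n_loc) < frac
      a[hit] <- a[hit] + bump
    }
    a
  }
  data.frame(individual_id = rep(ind$individual_id, n_loc),
             cohort = rep(ind$cohort, n_loc),
             locus_id = rep(catalog$locus_id, each = n_ind),
             allele1 = draw(), allele2 = draw(),
             stringsAsFactors = FALSE)
}
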