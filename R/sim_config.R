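#' Simulation configuration
#'
#' Defines the conditions under which synthetic pipeline inputs are generated.
#' Cohort-size defaults mirror the study design the package is built around:
#' 816 adult-onset and 306 childhood-onset cases against 6658 non-neurological
#' controls. Panel fractions keep the relative ordering of the real panels
#' (few adult-onset genes, many childhood-onset, an intermediate overlap set)
#' while reserving enough control genes for the balanced feature-selection
#' stage.
#'
#' @param seed integer root seed; all generator stages derive substream seeds
#'   from it via [stage_seed()].
#' @param n_genes number of genes to simulate.
#' @param n_tissues number of tissues in expression matrices; must be at least
#'   10 so that the 5-fold tissue-specificity rule is satisfiable with margin.
#' @param n_celltypes number of cell types in the mean-expression matrix.
#' @param n_cases_adult,n_cases_childhood,n_controls cohort sizes.
#' @param panel_fractions named fractions over
#'   `adult`, `childhood`, `overlap`, `control`; must sum to 1.
#' @param planted_effects named magnitudes of planted effects:
#'   \describe{
#'     \item{str_density_ratio}{expected STR count in disease-class genes as a
#'       multiple of the control-class expectation (default 2).}
#'     \item{specificity_fold}{fold by which a planted gene's expression in its
#'       target tissue/cell type exceeds its mean elsewhere (default 3).}
#'     \item{carrier_rate_case, carrier_rate_control}{per-gene qualifying-variant
#'       carrier probabilities (defaults 6/816 and 7/6658).}
#'     \item{tail_inflation_repeats}{repeat units added to an inflated case
#'       allele (default 10).}
#'     \item{tail_inflation_fraction}{fraction of case alleles inflated
#'       (default 0.01).}
#'   }
#' @param mean_transcripts,mean_exons expected transcripts per gene and master
#'   exons per gene.
#' @param str_per_gene expected STR count per control-class gene.
#' @param str_exonic_prob probability that a simulated STR is targeted at
#'   exonic sequence rather than placed uniformly in the gene span.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_tissues = 12L,
                       n_celltypes = 10L,
                       n_cases_adult = 816L,
                       n_cases_childhood = 306L,
                       n_controls = 6658L,
                       panel_fractions = c(adult = 0.05, childhood = 0.45,
                                           overlap = 0.15, control = 0.35),
                       planted_effects = c(str_density_ratio = 2,
                                           specificity_fold = 3,
                                           carrier_rate_case = 6 / 816,
                                           carrier_rate_control = 7 / 6658,
                                           tail_inflation_repeats = 10,
                                           tail_inflation_fraction = 0.01),
                       mean_transcripts = 3,
                       mean_exons = 6,
                       str_per_gene = 8,
                       str_exonic_prob = 0.3) {
  check_scalar_number(seed, "seed")
  check_scalar_number(n_genes, "n_genes", min = 1)
  check_scalar_number(n_tissues, "n_tissues", min = 10)
  check_scalar_number(n_celltypes, "n_celltypes", min = 2)
  check_scalar_number(n_cases_adult, "n_cases_adult", min = 1)
  check_scalar_number(n_cases_childhood, "n_cases_childhood", min = 1)
  check_scalar_number(n_controls, "n_controls", min = 1)
  classes <- c("adult", "childhood", "overlap", "control")
  if (!setequal(names(panel_fractions), classes))
    stopf("panel_fractions must be named over: %s",
          paste(classes, collapse = ", "))
  panel_fractions <- panel_fractions[classes]
  if (any(panel_fractions < 0) || abs(sum(panel_fractions) - 1) > 1e-8)
    stopf("panel_fractions must be non-negative and sum to 1")
  defaults <- c(str_density_ratio = 2, specificity_fold = 3,
                carrier_rate_case = 6 / 816, carrier_rate_control = 7 / 6658,
                tail_inflation_repeats = 10, tail_inflation_fraction = 0.01)
  unknown <- setdiff(names(planted_effects), names(defaults))
  if (length(unknown))
    stopf("unknown planted_effects: %s", paste(unknown, collapse = ", "))
  defaults[names(planted_effects)] <- planted_effects
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 n_celltypes = as.integer(n_celltypes),
                 n_cases_adult = as.integer(n_cases_adult),
                 n_cases_childhood = as.integer(n_cases_childhood),
                 n_controls = as.integer(n_controls),
                 panel_fractions = panel_fractions,
                 planted_effects = defaults,
                 mean_transcripts = mean_transcripts,
                 mean_exons = mean_exons,
                 str_per_gene = str_per_gene,
                 str_exonic_prob = str_exonic_prob),
            class = "sim_config")
}

# exact class counts by largest remainder, so rounding-free fractions are hit
# exactly (e.g. n=100 with .05/.5/.2/.25 -> 5/50/20/25)
panel_counts <- function(n_genes, fractions) {
  raw <- n_genes * fractions
  counts <- floor(raw)
  short <- n_genes - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}
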