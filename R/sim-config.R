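#' Simulation configuration for synthetic D-REAM experiments
#'
#' Bundles every tunable of the synthetic data generator. The defaults
#' describe the study design this generator emulates: three tissues (liver,
#' brain, heart) with two array replicates each, restriction (ACGT) sites at
#' roughly one per kb, 25-mer probes tiled every 35 bp, and a planted
#' methylation contrast of 0.8 (hypomethylated 0.1 vs hypermethylated 0.9)
#' at tissue-specific sites inside the -7/+3 kb TSS flanking window.
#'
#' @param n_genes number of non-overlapping genes to place.
#' @param chrom_length length in bp of the single synthetic chromosome.
#' @param tissues character vector of tissue labels.
#' @param replicates_per_tissue array replicates per tissue.
#' @param site_density expected restriction sites per kb.
#' @param probe_spacing tiling step in bp between consecutive 25-mer probes.
#' @param fragment_signal log-intensity units added over amplified fragments
#'   for a fully unmethylated site.
#' @param max_fragment_bp amplified-fragment span cap on each side of a site.
#' @param noise_sd replicate log-intensity noise (sd).
#' @param affinity_intercept baseline log intensity.
#' @param affinity_coefficients 25 x 3 matrix of per-position effects for
#'   bases C, G, T (A is the reference); drawn from the seed when `NULL`.
#' @param affinity_sd spread of drawn per-position effects.
#' @param copy_number_effect log-intensity units per doubling of probe copy
#'   number.
#' @param frac_multicopy fraction of probes with copy number > 1.
#' @param frac_nuclear_mt fraction of genes flagged as nuclear-encoded
#'   mitochondrial ("nuclear mt") genes.
#' @param frac_tissue_hypo_genes fraction of genes, per tissue, given a
#'   planted tissue-specific hypomethylated site; planted sets are disjoint
#'   across tissues.
#' @param hypo_level,hyper_level methylation fraction of a planted site in
#'   its hypomethylated tissue and in every other tissue.
#' @param planted_isolation_bp minimum distance of a planted site to its
#'   neighbouring sites. Amplified-fragment signal is attributed to the
#'   nearest site, so a planted site closer than twice the scoring window
#'   (default +/- 300 bp) to a neighbour both leaks differential signal
#'   into the neighbour's window and loses part of its own; 650 bp keeps
#'   the planted contrast fully resolvable at the default window.
#' @param background_meth_range range of the shared (tissue-invariant)
#'   methylation level of non-planted sites.
#' @param expression_effect log2 units added to a gene's expression in the
#'   tissue where it carries a planted hypo site downstream of its TSS.
#' @param expression_baseline_mean,expression_baseline_sd per-gene log2
#'   expression baseline distribution.
#' @param expression_noise_sd replicate expression noise (sd, log2).
#' @param tf_planted_fold target fold enrichment of simulated TF targets in
#'   the hypo gene set relative to all genes.
#' @param tf_base_rate TF target probability for genes outside the hypo set.
#' @param cobra_noise sd of COBRA fragment-amount noise, on the fraction
#'   scale.
#' @param seed integer master seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, chrom_length = 4e5, seed = 7)
#' cfg$tissues
sim_config <- function(n_genes = 500L,
                       chrom_length = 8e6,
                       tissues = c("liver", "brain", "heart"),
                       replicates_per_tissue = 2L,
                       site_density = 1,
                       probe_spacing = 35L,
                       fragment_signal = 2,
                       max_fragment_bp = 1000L,
                       noise_sd = 0.3,
                       affinity_intercept = 7,
                       affinity_coefficients = NULL,
                       affinity_sd = 0.2,
                       copy_number_effect = 0.8,
                       frac_multicopy = 0.05,
                       frac_nuclear_mt = 0.6,
                       frac_tissue_hypo_genes = 0.12,
                       hypo_level = 0.1,
                       hyper_level = 0.9,
                       planted_isolation_bp = 650L,
                       background_meth_range = c(0.2, 0.95),
                       expression_effect = 2,
                       expression_baseline_mean = 8,
                       expression_baseline_sd = 1,
                       expression_noise_sd = 0.25,
                       tf_planted_fold = 1.6,
                       tf_base_rate = 0.25,
                       cobra_noise = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    chrom_length = assert_scalar_number(chrom_length, "chrom_length", min = 1),
    chrom = "chrS",
    tissues = tissues,
    replicates_per_tissue = assert_count(replicates_per_tissue,
                                         "replicates_per_tissue"),
    site_density = assert_scalar_number(site_density, "site_density", min = 0,
                                        strict_min = TRUE),
    probe_spacing = assert_count(probe_spacing, "probe_spacing"),
    probe_length = 25L,
    fragment_signal = assert_scalar_number(fragment_signal, "fragment_signal",
                                           min = 0),
    max_fragment_bp = assert_count(max_fragment_bp, "max_fragment_bp"),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd", min = 0),
    affinity_intercept = assert_scalar_number(affinity_intercept,
                                              "affinity_intercept"),
    affinity_coefficients = affinity_coefficients,
    affinity_sd = assert_scalar_number(affinity_sd, "affinity_sd", min = 0),
    copy_number_effect = assert_scalar_number(copy_number_effect,
                                              "copy_number_effect"),
    frac_multicopy = assert_fraction(frac_multicopy, "frac_multicopy"),
    frac_nuclear_mt = assert_fraction(frac_nuclear_mt, "frac_nuclear_mt"),
    frac_tissue_hypo_genes = assert_fraction(frac_tissue_hypo_genes,
                                             "frac_tissue_hypo_genes"),
    hypo_level = assert_fraction(hypo_level, "hypo_level"),
    hyper_level = assert_fraction(hyper_level, "hyper_level"),
    planted_isolation_bp = assert_count(planted_isolation_bp,
                                        "planted_isolation_bp"),
    background_meth_range = background_meth_range,
    expression_effect = assert_scalar_number(expression_effect,
                                             "expression_effect"),
    expression_baseline_mean = assert_scalar_number(expression_baseline_mean,
                                                    "expression_baseline_mean"),
    expression_baseline_sd = assert_scalar_number(expression_baseline_sd,
                                                  "expression_baseline_sd",
                                                  min = 0),
    expression_noise_sd = assert_scalar_number(expression_noise_sd,
                                               "expression_noise_sd", min = 0),
    tf_planted_fold = assert_scalar_number(tf_planted_fold, "tf_planted_fold",
                                           min = 0),
    tf_base_rate = assert_fraction(tf_base_rate, "tf_base_rate"),
    cobra_noise = assert_scalar_number(cobra_noise, "cobra_noise", min = 0),
    seed = assert_count(abs(seed) + (seed == 0), "seed")
  )
  if (!is.character(cfg$tissues) || length(cfg$tissues) < 2L ||
      anyDuplicated(cfg$tissues))
    stopf("'tissues' must be >= 2 distinct labels",
          class = "dreamtdmr_validation_error")
  if (any(grepl("_", cfg$tissues)))
    stopf("tissue labels must not contain '_' (reserved for replicate suffix)",
          class = "dreamtdmr_validation_error")
  if (cfg$hypo_level >= cfg$hyper_level)
    stopf("hypo_level must be < hyper_level",
          class = "dreamtdmr_validation_error")
  if (length(cfg$background_meth_range) != 2L ||
      any(cfg$background_meth_range < 0) || any(cfg$background_meth_range > 1) ||
      diff(cfg$background_meth_range) < 0)
    stopf("background_meth_range must be an increasing pair in [0,1]",
          class = "dreamtdmr_validation_error")
  if (is.null(cfg$affinity_coefficients)) {
    set.seed(sim_seed(cfg, 11L))
    cfg$affinity_coefficients <- matrix(
      stats::rnorm(cfg$probe_length * 3L, 0, cfg$affinity_sd),
      nrow = cfg$probe_length, dimnames = list(NULL, c("C", "G", "T")))
  } else {
    ac <- as.matrix(cfg$affinity_coefficients)
    if (!identical(dim(ac), c(cfg$probe_length, 3L)))
      stopf("affinity_coefficients must be a %d x 3 matrix (C, G, T columns)",
            cfg$probe_length, class = "dreamtdmr_validation_error")
    colnames(ac) <- c("C", "G", "T")
    cfg$affinity_coefficients <- ac
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes on", format(x$chrom_length, big.mark = ","),
      "bp;", length(x$tissues), "tissues x", x$replicates_per_tissue,
      "replicates; seed", x$seed, "\n")
  invisible(x)
}
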