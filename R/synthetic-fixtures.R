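# COBRA, expression and TF-target fixtures with recorded ground truth

#' Simulate COBRA measurements for every site and tissue
#'
#' COBRA reports cut and uncut fragment amounts; the digested (cut) fraction
#' of the bisulfite PCR product tracks the methylation level, so the
#' expected cut amount is proportional to methylation and the uncut amount
#' to its complement. Gaussian noise on the fraction scale is added and
#' amounts are truncated at zero.
#'
#' @param truth a `ground_truth`.
#' @param sites site table (`chrom`, `pos`).
#' @param noise sd of amount noise on the fraction scale (>= 0).
#' @param config a [sim_config()] (seeds the noise stream).
#' @param scale nominal total fragment amount (electropherogram units).
#' @return data.table: site, tissue, cut_amount, uncut_amount.
#' @export
simulate_cobra <- function(truth, sites, noise = NULL, config, scale = 100) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  noise <- noise %||% config$cobra_noise
  if (noise < 0) stopf("noise must be >= 0", class = "dreamtdmr_validation_error")
  set.seed(sim_seed(config, 4L))
  meth <- truth$site_methylation[as.character(sites$pos), , drop = FALSE]
  out <- data.table::CJ(site = sites$pos, tissue = colnames(meth), sorted = FALSE)
  m <- meth[cbind(as.character(out$site), out$tissue)]
  n <- nrow(out)
  cut <- pmax(0, m * scale + if (noise > 0) stats::rnorm(n, 0, noise * scale) else 0)
  uncut <- pmax(0, (1 - m) * scale + if (noise > 0) stats::rnorm(n, 0, noise * scale) else 0)
  degenerate <- cut + uncut <= 0
  if (any(degenerate)) {  # unreachable at sane noise; keep measurements usable
    cut[degenerate] <- m[degenerate] * scale
    uncut[degenerate] <- (1 - m[degenerate]) * scale
  }
  out[, `:=`(cut_amount = cut, uncut_amount = uncut)]
  out[]
}

#' Simulate a tissue expression matrix linked to downstream hypo sites
#'
#' Genes carrying a planted hypomethylated site downstream of their TSS in
#' tissue X are expressed `expression_effect` log2 units higher in X;
#' all genes share a common per-gene baseline plus replicate noise.
#'
#' @param truth a `ground_truth`.
#' @param annotation gene annotation table.
#' @param config a [sim_config()].
#' @return Numeric matrix (genes x samples, log2 scale), rows named by
#'   gene_id, columns `<tissue>_<replicate>`.
#' @export
simulate_expression <- function(truth, annotation, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(sim_seed(config, 5L))
  n <- nrow(annotation)
  baseline <- stats::rnorm(n, config$expression_baseline_mean,
                           config$expression_baseline_sd)
  samples <- as.vector(outer(seq_len(config$replicates_per_tissue),
                             config$tissues,
                             function(r, t) paste0(t, "_", r)))
  out <- matrix(0, n, length(samples),
                dimnames = list(annotation$gene_id, samples))
  down <- truth$planted_hypo_genes[truth$planted_hypo_genes$downstream, ]
  for (s in samples) {
    tissue <- sample_tissues(s)
    eff <- config$expression_effect *
      (annotation$gene_id %in% down$gene_id[down$tissue == tissue])
    out[, s] <- baseline + eff +
      if (config$expression_noise_sd > 0)
        stats::rnorm(n, 0, config$expression_noise_sd) else 0
  }
  out
}

#' Simulate a TF target-gene list with a planted fold enrichment
#'
#' Samples target membership so that the expected fold enrichment of targets
#' in `hypo_genes` relative to all genes equals `tf_planted_fold`. With
#' target probability p1 inside the set and p0 = `tf_base_rate` outside,
#' fold = p1 / mean rate gives p1 = fold * p0 * (N - s) / (N - fold * s);
#' an infeasible fold (p1 > 1 or non-positive denominator) is an error.
#'
#' @param annotation gene annotation table.
#' @param hypo_genes character vector of gene ids (subset of annotation).
#' @param config a [sim_config()]; `fold` overrides `config$tf_planted_fold`.
#' @param fold optional fold override.
#' @return character vector of target gene ids.
#' @export
simulate_tf_targets <- function(annotation, hypo_genes, config, fold = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(hypo_genes %in% annotation$gene_id))
    stopf("hypo_genes must be a subset of annotation gene ids",
          class = "dreamtdmr_validation_error")
  fold <- fold %||% config$tf_planted_fold
  p0 <- config$tf_base_rate
  N <- nrow(annotation)
  s <- length(hypo_genes)
  denom <- N - fold * s
  p1 <- if (s == 0L) p0 else fold * p0 * (N - s) / denom
  if (s > 0L && (denom <= 0 || p1 > 1 || p1 < 0))
    stopf("planted fold %.3g infeasible with base rate %.3g and set size %d (needs target probability %.3g)",
          fold, p0, s, p1, class = "dreamtdmr_parameter_error")
  set.seed(sim_seed(config, 6L))
  in_set <- annotation$gene_id %in% hypo_genes
  p <- ifelse(in_set, p1, p0)
  annotation$gene_id[stats::runif(N) < p]
}

#' Run the whole synthetic generator
#'
#' Convenience wrapper chaining [generate_genome()], [plant_methylation()],
#' [simulate_intensities()], [simulate_cobra()], [simulate_expression()] and
#' [simulate_tf_targets()] (targets planted on the first tissue's hypo gene
#' set).
#'
#' @param config a [sim_config()].
#' @return list: config, annotation, sites, probes, truth, intensities,
#'   cobra, expression, tf_targets.
#' @export
simulate_dream <- function(config = sim_config()) {
  g <- generate_genome(config)
  truth <- plant_methylation(g$annotation, g$sites, config)
  intensities <- simulate_intensities(truth, g$probes, g$sites, config)
  cobra <- simulate_cobra(truth, g$sites, config = config)
  expression <- simulate_expression(truth, g$annotation, config)
  hypo1 <- truth$planted_hypo_genes$gene_id[
    truth$planted_hypo_genes$tissue == config$tissues[1L]]
  tf_targets <- simulate_tf_targets(g$annotation, hypo1, config)
  list(config = config, annotation = g$annotation, sites = g$sites,
       probes = g$probes, truth = truth, intensities = intensities,
       cobra = cobra, expression = expression, tf_targets = tf_targets)
}
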