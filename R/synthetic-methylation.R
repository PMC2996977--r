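# ground-truth methylation planting and D-REAM-like intensity simulation

# signed offset of a site from a TSS in transcription direction;
# recycles over either a vector of positions or a vector of genes
tss_offset <- function(pos, tss, strand) {
  ifelse(strand == "+", 1L, -1L) * (pos - tss)
}

#' Plant per-tissue methylation states with recorded ground truth
#'
#' For each tissue, a disjoint fraction `frac_tissue_hypo_genes` of genes
#' receives one restriction site inside its -7/+3 kb TSS flanking window set
#' to `hypo_level` methylation in that tissue and `hyper_level` in every
#' other tissue. All remaining sites get a single background methylation
#' level shared across tissues. Selected genes whose window contains no site
#' are skipped with a warning.
#'
#' @param annotation,sites from [generate_genome()].
#' @param config a [sim_config()].
#' @return An object of class `ground_truth`: list with `site_methylation`
#'   (matrix, sites x tissues, rows named by site position),
#'   `planted_hypo_sites` (data.table: site, tissue, gene_id, offset) and
#'   `planted_hypo_genes` (data.table: gene_id, tissue, site, offset,
#'   downstream).
#' @export
plant_methylation <- function(annotation, sites, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(sites$pos < 0) || any(sites$pos >= config$chrom_length))
    stopf("sites fall outside the chromosome", class = "dreamtdmr_validation_error")
  set.seed(sim_seed(config, 2L))
  tissues <- config$tissues
  n_sites <- nrow(sites)
  meth <- matrix(stats::runif(n_sites, config$background_meth_range[1],
                              config$background_meth_range[2]),
                 nrow = n_sites, ncol = length(tissues),
                 dimnames = list(as.character(sites$pos), tissues))
  meth[] <- meth[, 1L]  # background level shared across tissues

  n_pick <- floor(config$frac_tissue_hypo_genes * nrow(annotation))
  pool <- annotation$gene_id
  planted <- vector("list", length(tissues))
  used_sites <- integer(0)
  # planted sites must be isolated from their neighbours so the planted
  # contrast stays resolvable at the scoring window (see sim_config docs)
  gap_prev <- c(Inf, diff(sites$pos))
  gap_next <- c(diff(sites$pos), Inf)
  isolated <- gap_prev > config$planted_isolation_bp &
    gap_next > config$planted_isolation_bp
  for (ti in seq_along(tissues)) {
    if (n_pick == 0L) { planted[[ti]] <- NULL; next }
    picked <- sample(pool, n_pick)
    pool <- setdiff(pool, picked)  # disjoint across tissues
    rows <- vector("list", length(picked))
    for (k in seq_along(picked)) {
      g <- annotation[annotation$gene_id == picked[k], ]
      off <- tss_offset(sites$pos, g$tss, g$strand)
      in_win <- which(off >= -7000L & off < 3000L & isolated &
                        !(sites$pos %in% used_sites))
      if (!length(in_win)) {
        warnf("gene %s (%s tissue): no free isolated site in its TSS window; skipped",
              picked[k], tissues[ti])
        next
      }
      j <- if (length(in_win) == 1L) in_win else sample(in_win, 1L)
      meth[j, ] <- config$hyper_level
      meth[j, tissues[ti]] <- config$hypo_level
      used_sites <- c(used_sites, sites$pos[j])
      rows[[k]] <- data.table::data.table(
        gene_id = picked[k], tissue = tissues[ti],
        site = sites$pos[j], offset = off[j])
    }
    planted[[ti]] <- data.table::rbindlist(rows)
  }
  planted_genes <- data.table::rbindlist(planted)
  if (nrow(planted_genes)) {
    planted_genes[, `:=`(downstream = offset >= 0L)]
    planted_sites <- planted_genes[, list(site, tissue, gene_id, offset)]
  } else {
    planted_genes <- data.table::data.table(
      gene_id = character(), tissue = character(), site = integer(),
      offset = integer(), downstream = logical())
    planted_sites <- data.table::data.table(
      site = integer(), tissue = character(), gene_id = character(),
      offset = integer())
  }
  structure(list(site_methylation = meth,
                 planted_hypo_sites = planted_sites,
                 planted_hypo_genes = planted_genes),
            class = "ground_truth")
}

#' Simulate D-REAM tiling-array log intensities
#'
#' Each probe reads a sequence/copy-number affinity baseline. A probe whose
#' centre lies within `max_fragment_bp` of its nearest restriction site (and
#' hence inside that site's amplified-fragment span) additionally reads
#' `fragment_signal * (1 - methylation)` of that site in the given tissue:
#' fragments flanking unmethylated sites are selectively amplified.
#' Independent Gaussian noise (`noise_sd`) is added per replicate.
#'
#' @param truth a `ground_truth` from [plant_methylation()].
#' @param probes,sites from [generate_genome()].
#' @param config a [sim_config()].
#' @return Numeric matrix of log intensities, probes x samples; rows named by
#'   probe_id, columns named `<tissue>_<replicate>`.
#' @export
simulate_intensities <- function(truth, probes, sites, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (!all(as.character(sites$pos) %in% rownames(truth$site_methylation)))
    stopf("ground truth does not cover all sites",
          class = "dreamtdmr_validation_error")
  set.seed(sim_seed(config, 3L))
  baseline <- affinity_baseline(probes$sequence, config$affinity_intercept,
                                config$affinity_coefficients) +
    config$copy_number_effect * log2(probes$copy_number)

  centre <- probes$start + config$probe_length %/% 2L
  pos <- sites$pos
  idx <- findInterval(centre, pos)
  left <- ifelse(idx >= 1L, pos[pmax(idx, 1L)], -Inf)
  right <- ifelse(idx < length(pos), pos[pmin(idx + 1L, length(pos))], Inf)
  nearest <- ifelse(centre - left <= right - centre, pmax(idx, 1L),
                    pmin(idx + 1L, length(pos)))
  dist <- abs(centre - pos[nearest])
  in_span <- dist <= config$max_fragment_bp

  meth <- truth$site_methylation[as.character(pos), , drop = FALSE]
  samples <- as.vector(outer(seq_len(config$replicates_per_tissue),
                             config$tissues,
                             function(r, t) paste0(t, "_", r)))
  out <- matrix(0, nrow = nrow(probes), ncol = length(samples),
                dimnames = list(probes$probe_id, samples))
  for (s in samples) {
    tissue <- sample_tissues(s)
    signal <- config$fragment_signal * (1 - meth[nearest, tissue]) * in_span
    out[, s] <- baseline + signal +
      if (config$noise_sd > 0) stats::rnorm(nrow(probes), 0, config$noise_sd) else 0
  }
  out
}

# affinity baseline from per-position nucleotide effects (A = reference)
affinity_baseline <- function(sequences, intercept, coefficients) {
  b <- rep(intercept, length(sequences))
  for (p in seq_len(nrow(coefficients))) {
    base <- substr(sequences, p, p)
    for (nt in c("C", "G", "T"))
      b <- b + coefficients[p, nt] * (base == nt)
  }
  b
}
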