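# shared fixtures; everything is generated in code, nothing on disk

small_config <- function(seed = 3, ...) {
  sim_config(n_genes = 40L, chrom_length = 40L * 13000L, seed = seed, ...)
}

small_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3, ...) {
    key <- paste(seed, ..., sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- suppressWarnings(simulate_dream(small_config(seed, ...)))
    cache[[key]]
  }
})

# scored small world, cached: model, t-values, scores, thresholds, calls, summary
small_run <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      sim <- small_sim(seed)
      model <- fit_affinity_model(sim$probes, sim$intensities)
      tv <- standardize(sim$intensities, model)
      scores <- score_all_sites(tv, sim$probes, sim$sites)
      thresholds <- calibrate_thresholds(scores, sim$cobra)
      calls <- call_hypo_sites(scores, thresholds)
      tissue_hypo <- classify_tissue_hypo(calls, sim$config$tissues)
      assignments <- assign_sites_to_genes(sim$sites, sim$annotation)
      summary <- summarize_genes(assignments, calls, tissue_hypo,
                                 sim$annotation)
      cache[[key]] <- list(sim = sim, model = model, tv = tv, scores = scores,
                           thresholds = thresholds, calls = calls,
                           tissue_hypo = tissue_hypo,
                           assignments = assignments, summary = summary)
    }
    cache[[key]]
  }
})

# hand-built annotation: one gene per row from a compact spec
make_annotation <- function(strand, tss, len = 2000L, chrom = "chrS",
                            is_nuclear_mt = TRUE, categories = "") {
  n <- length(tss)
  strand <- rep_len(strand, n)
  len <- rep_len(len, n)
  span_start <- ifelse(strand == "+", tss, tss - len + 1L)
  span_end <- span_start + len
  data.table::data.table(
    gene_id = sprintf("G%03d", seq_len(n)), chrom = chrom, strand = strand,
    tss = as.integer(tss), span_start = as.integer(span_start),
    span_end = as.integer(span_end),
    three_prime_end = as.integer(ifelse(strand == "+", span_end - 1L,
                                        span_start)),
    is_nuclear_mt = rep_len(is_nuclear_mt, n),
    categories = rep_len(categories, n))
}

make_sites <- function(pos, chrom = "chrS") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos))
}

# independent sort-drop-average oracle for the symmetric trimmed mean
trimmed_mean_oracle <- function(x, trim) {
  k <- floor(trim * length(x))
  s <- sort(x)
  mean(s[(k + 1L):(length(s) - k)])
}

# full-enumeration hypergeometric tail oracle over all C(N, n) draws
hyper_tail_oracle <- function(set_hits, set_size, background_hits,
                              background_size, direction = "over") {
  marked <- seq_len(background_hits)
  draws <- utils::combn(background_size, set_size)
  hits <- colSums(matrix(draws %in% marked, nrow = nrow(draws)))
  if (direction == "over") mean(hits >= set_hits) else mean(hits <= set_hits)
}
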