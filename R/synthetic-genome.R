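#' Generate a synthetic annotated genome, restriction sites and tiling probes
#'
#' Places `n_genes` non-overlapping genes on one synthetic chromosome, each
#' confined (together with its whole -7/+3 kb TSS flanking window) to a
#' private slot of the chromosome so that planted methylation signal is
#' unambiguous at the gene level. Restriction (ACGT) sites are scattered at
#' `site_density` per kb and 25-mer probes tile the chromosome every
#' `probe_spacing` bp with copy number mostly 1.
#'
#' Coordinates are 0-based half-open throughout. For a + strand gene the TSS
#' is `span_start`; for a - strand gene it is `span_end - 1`.
#' `three_prime_end` is the last transcribed base in transcription direction.
#'
#' @param config a [sim_config()].
#' @return A list with elements `annotation` (data.table: gene_id, chrom,
#'   strand, tss, span_start, span_end, three_prime_end, is_nuclear_mt,
#'   categories), `sites` (data.table: chrom, pos) and `probes` (data.table:
#'   probe_id, chrom, start, sequence, copy_number).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  slot <- floor(config$chrom_length / config$n_genes)
  min_len <- 2000L
  # gene body + 10 kb window + margin must fit in the slot
  if (slot < min_len + 10000L + 500L)
    stopf(paste0("chrom_length %g too small for %d genes: each gene needs a ",
                 ">= %d bp slot (gene body plus its 10 kb TSS window)"),
          config$chrom_length, config$n_genes, min_len + 10500L,
          class = "dreamtdmr_sizing_error")
  max_len <- min(8000L, slot - 10500L)

  set.seed(sim_seed(config, 1L))
  n <- config$n_genes
  len <- sample(seq.int(min_len, max_len), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  if (n >= 2L) { strand[1L] <- "+"; strand[2L] <- "-" }  # both strands present
  slot_start <- (seq_len(n) - 1L) * slot

  # keep [tss-7000, tss+3000) and the gene body inside the slot
  span_start <- integer(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      lo <- slot_start[i] + 7000L
      hi <- slot_start[i] + slot - max(len[i], 3000L) - 1L
    } else {
      lo <- slot_start[i] + max(3001L - len[i], 0L)
      hi <- slot_start[i] + slot - 7000L - len[i] - 1L
    }
    span_start[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  }
  span_end <- span_start + len
  tss <- ifelse(strand == "+", span_start, span_end - 1L)
  three_prime_end <- ifelse(strand == "+", span_end - 1L, span_start)

  cats <- c("metabolism", "respiratory_chain", "tca_cycle", "detoxification",
            "mito_ribosome", "protein_sorting")
  categories <- sample(c(cats, ""), n, replace = TRUE,
                       prob = c(rep(0.8 / 6, 6), 0.2))
  annotation <- data.table::data.table(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = config$chrom,
    strand = strand,
    tss = as.integer(tss),
    span_start = as.integer(span_start),
    span_end = as.integer(span_end),
    three_prime_end = as.integer(three_prime_end),
    is_nuclear_mt = stats::runif(n) < config$frac_nuclear_mt,
    categories = categories
  )

  n_sites <- max(1L, round(config$site_density * config$chrom_length / 1000))
  pos <- sort(sample.int(config$chrom_length - 4L, n_sites))
  sites <- data.table::data.table(chrom = config$chrom, pos = as.integer(pos))

  starts <- seq.int(0L, config$chrom_length - config$probe_length,
                    by = config$probe_spacing)
  np <- length(starts)
  seq_mat <- matrix(sample(c("A", "C", "G", "T"), np * config$probe_length,
                           replace = TRUE), nrow = np)
  copy <- rep(1L, np)
  multi <- stats::runif(np) < config$frac_multicopy
  copy[multi] <- sample(2:15, sum(multi), replace = TRUE)
  probes <- data.table::data.table(
    probe_id = sprintf("p%07d", seq_len(np)),
    chrom = config$chrom,
    start = as.integer(starts),
    sequence = do.call(paste0, as.data.frame(seq_mat)),
    copy_number = copy
  )
  list(annotation = annotation, sites = sites, probes = probes)
}
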