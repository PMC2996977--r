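# TSS-window site assignment, hypo T-DMR calling, tissue-hypo classification
# and per-gene summaries

#' Assign restriction sites to strand-aware TSS flanking windows
#'
#' The signed offset of a site from a TSS is measured in transcription
#' direction: `site - tss` for + strand genes, `tss - site` for - strand.
#' A site is assigned to a gene iff `-upstream_bp <= offset < downstream_bp`
#' (half-open downstream bound); offset >= 0 is downstream. A site may fall
#' in several genes' windows and is then assigned to each; sites assigned
#' to no gene are retained with an `NA` gene.
#'
#' @param sites site table (`pos`).
#' @param annotation gene annotation (gene_id, strand, tss).
#' @param upstream_bp,downstream_bp window extent (defaults 7000 and 3000:
#'   the -7/+3 kb TSS flanking region).
#' @return data.table: site, gene_id, offset, region ("upstream" or
#'   "downstream"; NA for unassigned sites).
#' @export
assign_sites_to_genes <- function(sites, annotation,
                                  upstream_bp = 7000L, downstream_bp = 3000L) {
  assert_columns(annotation, c("gene_id", "strand", "tss"), "annotation")
  pos <- sites$pos
  rows <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    off <- tss_offset(pos, annotation$tss[i], annotation$strand[i])
    hit <- which(off >= -upstream_bp & off < downstream_bp)
    if (length(hit))
      rows[[i]] <- data.table::data.table(
        site = pos[hit], gene_id = annotation$gene_id[i],
        offset = as.integer(off[hit]),
        region = ifelse(off[hit] >= 0L, "downstream", "upstream"))
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L)
    out <- data.table::data.table(site = integer(), gene_id = character(),
                                  offset = integer(), region = character())
  orphan <- setdiff(pos, out$site)
  if (length(orphan))
    out <- data.table::rbindlist(list(out, data.table::data.table(
      site = orphan, gene_id = NA_character_, offset = NA_integer_,
      region = NA_character_)))
  data.table::setorder(out, site, na.last = TRUE)
  out[]
}

#' Call directed hypomethylated sites against calibrated thresholds
#'
#' A site is called hypomethylated in tissue a relative to tissue b iff its
#' directed score is `>=` the calibrated threshold of that comparison (the
#' threshold site itself was COBRA-confirmed, so it must be callable).
#'
#' @param scores unordered-pair score table from [score_all_sites()].
#' @param thresholds a [calibrate_thresholds()] table (or any data.frame
#'   with hypo_tissue, vs_tissue, threshold).
#' @return data.table of calls: site, hypo_tissue, vs_tissue, score,
#'   threshold.
#' @export
call_hypo_sites <- function(scores, thresholds) {
  assert_columns(thresholds, c("hypo_tissue", "vs_tissue", "threshold"),
                 "thresholds")
  d <- directed_scores(scores)
  d <- d[d$usable & !is.na(d$score), ]
  key <- paste(d$hypo_tissue, d$vs_tissue)
  tkey <- paste(thresholds$hypo_tissue, thresholds$vs_tissue)
  missing <- setdiff(unique(key), tkey)
  if (length(missing))
    stopf("no threshold for directed comparison(s): %s",
          paste(missing, collapse = "; "), class = "dreamtdmr_validation_error")
  d$threshold <- thresholds$threshold[match(key, tkey)]
  calls <- d[d$score >= d$threshold,
             c("site", "hypo_tissue", "vs_tissue", "score", "threshold")]
  data.table::setorder(calls, site, hypo_tissue, vs_tissue)
  calls[]
}

#' Classify tissue-specific hypomethylated sites
#'
#' A site is tissue-X-hypo iff it is called hypomethylated in X relative to
#' every other tissue. Antisymmetry of the score makes the per-tissue sets
#' disjoint.
#'
#' @param calls table from [call_hypo_sites()].
#' @param tissues all tissue labels of the experiment.
#' @return data.table: site, tissue.
#' @export
classify_tissue_hypo <- function(calls, tissues) {
  if (length(tissues) < 2L)
    stopf("need >= 2 tissues", class = "dreamtdmr_validation_error")
  n_other <- length(tissues) - 1L
  if (nrow(calls) == 0L)
    return(data.table::data.table(site = integer(), tissue = character()))
  cnt <- calls[calls$vs_tissue %in% tissues & calls$hypo_tissue %in% tissues,
               list(n = data.table::uniqueN(vs_tissue)),
               by = c("site", "hypo_tissue")]
  out <- cnt[cnt$n == n_other, list(site, tissue = hypo_tissue)]
  data.table::setorder(out, site, tissue)
  out[]
}

#' Summarize T-DMR calls per gene
#'
#' Computes per-gene flags: `has_tdmr` (at least one assigned site carries
#' at least one directed hypo call, any direction), and per tissue
#' `has_tissue_hypo`, `has_upstream`, `has_downstream` from the
#' tissue-specific hypo sites. The headline statistic is the percentage of
#' nuclear mt genes with T-DMRs, rounded to the nearest integer percent.
#'
#' @param assignments from [assign_sites_to_genes()].
#' @param calls from [call_hypo_sites()].
#' @param tissue_hypo from [classify_tissue_hypo()].
#' @param annotation gene annotation.
#' @return Object of class `gene_summary`: list with `genes` (gene_id,
#'   is_nuclear_mt, has_tdmr), `tissue_flags` (gene_id, tissue,
#'   has_tissue_hypo, has_upstream, has_downstream) and `stats`
#'   (n_genes, n_nuclear_mt, n_nuclear_mt_with_tdmr,
#'   pct_nuclear_mt_with_tdmr, per-tissue gene counts).
#' @export
summarize_genes <- function(assignments, calls, tissue_hypo, annotation) {
  assert_columns(annotation, c("gene_id", "is_nuclear_mt"), "annotation")
  asg <- assignments[!is.na(assignments$gene_id), ]
  tdmr_sites <- unique(calls$site)
  genes <- data.table::data.table(
    gene_id = annotation$gene_id,
    is_nuclear_mt = annotation$is_nuclear_mt,
    has_tdmr = annotation$gene_id %in% asg$gene_id[asg$site %in% tdmr_sites])

  tissues <- sort(unique(tissue_hypo$tissue))
  flags <- data.table::CJ(gene_id = annotation$gene_id, tissue = tissues)
  if (nrow(flags)) {
    hyp <- merge(asg, tissue_hypo, by = "site", allow.cartesian = TRUE)
    agg <- hyp[, list(has_tissue_hypo = .N > 0L,
                      has_upstream = any(region == "upstream"),
                      has_downstream = any(region == "downstream")),
               by = c("gene_id", "tissue")]
    flags <- merge(flags, agg, by = c("gene_id", "tissue"), all.x = TRUE)
    for (cl in c("has_tissue_hypo", "has_upstream", "has_downstream"))
      data.table::set(flags, which(is.na(flags[[cl]])), cl, FALSE)
  } else {
    flags <- data.table::data.table(gene_id = character(), tissue = character(),
                                    has_tissue_hypo = logical(),
                                    has_upstream = logical(),
                                    has_downstream = logical())
  }

  n_mt <- sum(genes$is_nuclear_mt)
  n_mt_tdmr <- sum(genes$is_nuclear_mt & genes$has_tdmr)
  per_tissue <- if (nrow(flags))
    flags[flags$has_tissue_hypo,
          list(n_genes = .N,
               n_nuclear_mt = sum(gene_id %in%
                                    genes$gene_id[genes$is_nuclear_mt])),
          by = "tissue"]
  else data.table::data.table(tissue = character(), n_genes = integer(),
                              n_nuclear_mt = integer())
  stats <- list(
    n_genes = nrow(genes),
    n_with_tdmr = sum(genes$has_tdmr),
    n_nuclear_mt = n_mt,
    n_nuclear_mt_with_tdmr = n_mt_tdmr,
    pct_nuclear_mt_with_tdmr = if (n_mt > 0) round(100 * n_mt_tdmr / n_mt)
    else NA_real_,
    per_tissue = per_tissue)
  structure(list(genes = genes, tissue_flags = flags, stats = stats),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  s <- x$stats
  cat("gene_summary:", s$n_genes, "genes;", s$n_with_tdmr, "with T-DMRs;",
      s$n_nuclear_mt_with_tdmr, "of", s$n_nuclear_mt,
      sprintf("nuclear mt genes with T-DMRs (%s%%)\n",
              s$pct_nuclear_mt_with_tdmr))
  invisible(x)
}

#' Positional density of tissue-hypo sites along the TSS window
#'
#' Average number of focal-tissue hypo sites per gene in each 1 kb bin of
#' the \[-7, +3) kb TSS flanking window.
#'
#' @param tissue_hypo from [classify_tissue_hypo()].
#' @param assignments from [assign_sites_to_genes()].
#' @param gene_ids gene set over which to average (non-empty).
#' @param tissue focal tissue.
#' @param bin_bp bin width (default 1000).
#' @param upstream_bp,downstream_bp window extent.
#' @return named numeric vector of per-gene densities, one per bin, names
#'   like `[-7000,-6000)`.
#' @export
positional_density <- function(tissue_hypo, assignments, gene_ids, tissue,
                               bin_bp = 1000L, upstream_bp = 7000L,
                               downstream_bp = 3000L) {
  if (length(gene_ids) == 0L)
    stopf("empty gene set", class = "dreamtdmr_validation_error")
  breaks <- seq.int(-upstream_bp, downstream_bp, by = bin_bp)
  labels <- sprintf("[%d,%d)", breaks[-length(breaks)], breaks[-1L])
  sites_t <- tissue_hypo$site[tissue_hypo$tissue == tissue]
  asg <- assignments[!is.na(assignments$gene_id) &
                       assignments$gene_id %in% gene_ids &
                       assignments$site %in% sites_t, ]
  counts <- table(factor(
    findInterval(asg$offset, breaks, rightmost.closed = FALSE),
    levels = seq_len(length(breaks) - 1L)))
  stats::setNames(as.numeric(counts) / length(gene_ids), labels)
}
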