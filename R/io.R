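# on-disk schemas: TSV/BED readers and writers with validation
# All coordinates on disk are 0-based; BED intervals are half-open.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path))
    stopf("%s file not found: %s", what, path, class = "dreamtdmr_io_error")
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  assert_columns(dt, required, sprintf("%s (%s)", what, path))
  dt
}

parse_error <- function(path, line, fmt, ...) {
  stopf("parse error in %s, line %d: %s", path, line, sprintf(fmt, ...),
        class = "dreamtdmr_parse_error")
}

#' Read and write the gene annotation table
#'
#' Tab-separated with header: gene_id, chrom, strand, tss, span_start,
#' span_end, three_prime_end, is_nuclear_mt, categories. Coordinates are
#' 0-based; the gene body `[span_start, span_end)` is half-open.
#'
#' @param path file path.
#' @return data.table (for the reader); the written path, invisibly (writer).
#' @export
read_annotation <- function(path) {
  cols <- c("gene_id", "chrom", "strand", "tss", "span_start", "span_end",
            "three_prime_end", "is_nuclear_mt", "categories")
  dt <- read_tsv_checked(path, cols, "annotation")
  dt$categories <- as.character(dt$categories)
  dt$categories[is.na(dt$categories)] <- ""
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    parse_error(path, bad[1L] + 1L, "unknown strand '%s'", dt$strand[bad[1L]])
  dup <- which(duplicated(dt$gene_id))
  if (length(dup))
    parse_error(path, dup[1L] + 1L, "duplicated gene id '%s'",
                dt$gene_id[dup[1L]])
  bad <- which(dt$span_end <= dt$span_start | dt$tss < dt$span_start |
                 dt$tss >= dt$span_end | dt$span_start < 0)
  if (length(bad))
    parse_error(path, bad[1L] + 1L, "invalid gene span/TSS for '%s'",
                dt$gene_id[bad[1L]])
  dt$is_nuclear_mt <- as.logical(dt$is_nuclear_mt)
  dt
}

#' @rdname read_annotation
#' @param annotation the table to write.
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(annotation, path, sep = "\t")
  invisible(path)
}

#' Read and write restriction sites as BED
#'
#' Single-base, 0-based half-open intervals (end = start + 1).
#'
#' @param path file path.
#' @return data.table with chrom, pos (reader); path invisibly (writer).
#' @export
read_sites_bed <- function(path) {
  if (!file.exists(path))
    stopf("sites BED not found: %s", path, class = "dreamtdmr_io_error")
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L)
    parse_error(path, 1L, "BED needs >= 3 columns")
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  bad <- which(dt$end <= dt$start | dt$start < 0)
  if (length(bad))
    parse_error(path, bad[1L], "BED end <= start")
  data.table::data.table(chrom = dt$chrom, pos = as.integer(dt$start))
}

#' @rdname read_sites_bed
#' @param sites site table (chrom, pos).
#' @export
write_sites_bed <- function(sites, path) {
  data.table::fwrite(data.table::data.table(
    chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L,
    name = paste0("ACGT_", sites$pos)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write the probe table
#'
#' Tab-separated with header: probe_id, chrom, start, sequence,
#' copy_number. Sequences are fixed-length strings over ACGT.
#'
#' @param path file path.
#' @export
read_probes <- function(path) {
  dt <- read_tsv_checked(path, c("probe_id", "chrom", "start", "sequence",
                                 "copy_number"), "probes")
  bad <- which(dt$copy_number < 1 | dt$start < 0)
  if (length(bad))
    parse_error(path, bad[1L] + 1L, "invalid start or copy number")
  L <- nchar(dt$sequence[1L])
  bad <- which(nchar(dt$sequence) != L | grepl("[^ACGT]", dt$sequence))
  if (length(bad))
    parse_error(path, bad[1L] + 1L, "probe sequence not a %d-mer over ACGT", L)
  dt
}

#' @rdname read_probes
#' @param probes the table to write.
#' @export
write_probes <- function(probes, path) {
  data.table::fwrite(probes, path, sep = "\t")
  invisible(path)
}

#' Read and write a numeric matrix (intensities, t-values, expression)
#'
#' Tab-separated with header; first column `id` holds row names
#' (probe or gene ids), remaining columns are samples named
#' `<tissue>_<replicate>`.
#'
#' @param path file path.
#' @export
read_matrix_tsv <- function(path) {
  dt <- read_tsv_checked(path, "id", "matrix")
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m))
    parse_error(path, 2L, "non-numeric matrix entries")
  rownames(m) <- dt$id
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix with row and column names.
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table::data.table(id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read and write COBRA measurements
#'
#' Tab-separated with header: site, tissue, cut_amount, uncut_amount.
#'
#' @param path file path.
#' @export
read_cobra <- function(path) {
  dt <- read_tsv_checked(path, c("site", "tissue", "cut_amount",
                                 "uncut_amount"), "COBRA measurements")
  bad <- which(dt$cut_amount < 0 | dt$uncut_amount < 0)
  if (length(bad))
    parse_error(path, bad[1L] + 1L, "negative fragment amount")
  dt
}

#' @rdname read_cobra
#' @param measurements the table to write.
#' @export
write_cobra <- function(measurements, path) {
  data.table::fwrite(measurements, path, sep = "\t")
  invisible(path)
}

#' Read and write site-score tables
#' @param path file path.
#' @export
read_scores <- function(path) {
  read_tsv_checked(path, c("site", "tissue_a", "tissue_b", "score",
                           "n_probes", "n_a", "n_b", "usable"), "scores")
}

#' @rdname read_scores
#' @param scores the table to write.
#' @export
write_scores <- function(scores, path) {
  data.table::fwrite(scores, path, sep = "\t")
  invisible(path)
}

#' Read and write threshold tables
#' @param path file path.
#' @export
read_thresholds <- function(path) {
  read_tsv_checked(path, c("hypo_tissue", "vs_tissue", "threshold"),
                   "thresholds")
}

#' @rdname read_thresholds
#' @param thresholds the table to write.
#' @export
write_thresholds <- function(thresholds, path) {
  data.table::fwrite(thresholds, path, sep = "\t")
  invisible(path)
}

#' Write tissue-hypo T-DMR calls as BED6+
#'
#' One row per (site, gene, hypo tissue): chrom, start, end, name
#' `gene:tissue`, score (directed score vs the weakest comparison), strand
#' of the gene, then offset, region and `versus` (comma-separated
#' comparison tissues).
#'
#' @param tissue_hypo from [classify_tissue_hypo()].
#' @param calls from [call_hypo_sites()].
#' @param assignments from [assign_sites_to_genes()].
#' @param annotation gene annotation.
#' @param path file path.
#' @export
write_calls_bed <- function(tissue_hypo, calls, assignments, annotation,
                            path) {
  asg <- assignments[!is.na(assignments$gene_id), ]
  th <- merge(tissue_hypo, asg, by = "site", allow.cartesian = TRUE)
  cs <- calls[, list(score = min(score), versus = paste(sort(vs_tissue),
                                                        collapse = ",")),
              by = c("site", "hypo_tissue")]
  th <- merge(th, cs, by.x = c("site", "tissue"),
              by.y = c("site", "hypo_tissue"), all.x = TRUE)
  th$strand <- annotation$strand[match(th$gene_id, annotation$gene_id)]
  th$chrom <- annotation$chrom[match(th$gene_id, annotation$gene_id)]
  bed <- data.table::data.table(
    chrom = th$chrom, start = th$site, end = th$site + 1L,
    name = paste0(th$gene_id, ":", th$tissue),
    score = round(th$score, 4), strand = th$strand,
    offset = th$offset, region = th$region, versus = th$versus)
  data.table::setorder(bed, start, name)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read tissue-hypo calls written by [write_calls_bed()]
#' @param path file path.
#' @export
read_calls_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "offset",
                                        "region", "versus"))
  bad <- which(dt$end <= dt$start)
  if (length(bad)) parse_error(path, bad[1L], "BED end <= start")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) parse_error(path, bad[1L], "unknown strand")
  dt[, c("gene_id", "tissue") := data.table::tstrsplit(name, ":", fixed = TRUE)]
  dt[]
}

#' Write the per-gene summary table
#'
#' Wide table: gene_id, is_nuclear_mt, has_tdmr, then
#' hypo_/up_/down_<tissue> flag columns.
#'
#' @param gene_summary a [summarize_genes()] result.
#' @param path file path.
#' @export
write_gene_summary <- function(gene_summary, path) {
  g <- data.table::copy(gene_summary$genes)
  fl <- gene_summary$tissue_flags
  for (t in sort(unique(fl$tissue))) {
    sub <- fl[fl$tissue == t, ]
    i <- match(g$gene_id, sub$gene_id)
    g[[paste0("hypo_", t)]] <- sub$has_tissue_hypo[i] %in% TRUE
    g[[paste0("up_", t)]] <- sub$has_upstream[i] %in% TRUE
    g[[paste0("down_", t)]] <- sub$has_downstream[i] %in% TRUE
  }
  data.table::fwrite(g, path, sep = "\t")
  invisible(path)
}

#' Read and write one-gene-per-line target lists
#' @param path file path.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path))
    stopf("target list not found: %s", path, class = "dreamtdmr_io_error")
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_target_list
#' @param targets character vector of gene ids.
#' @export
write_target_list <- function(targets, path) {
  writeLines(targets, path)
  invisible(path)
}

#' Write every synthetic artifact of a simulation to a directory
#'
#' Produces annotation.tsv, sites.bed, probes.tsv, intensities.tsv,
#' cobra.tsv, expression.tsv, tf_targets.txt, truth_methylation.tsv and
#' truth_planted.tsv.
#'
#' @param sim a [simulate_dream()] result.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_annotation(sim$annotation, p("annotation.tsv"))
  write_sites_bed(sim$sites, p("sites.bed"))
  write_probes(sim$probes, p("probes.tsv"))
  write_matrix_tsv(sim$intensities, p("intensities.tsv"))
  write_cobra(sim$cobra, p("cobra.tsv"))
  write_matrix_tsv(sim$expression, p("expression.tsv"))
  write_target_list(sim$tf_targets, p("tf_targets.txt"))
  meth <- sim$truth$site_methylation
  data.table::fwrite(cbind(data.table::data.table(site = rownames(meth)),
                           data.table::as.data.table(meth)),
                     p("truth_methylation.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$planted_hypo_genes, p("truth_planted.tsv"),
                     sep = "\t")
  invisible(outdir)
}
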