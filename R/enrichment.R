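# exact-test enrichment machinery: categories, TF targets, downstream
# fractions and nuclear-mt composition ratios

#' One-sided Fisher exact (hypergeometric tail) p-value
#'
#' Probability, under the hypergeometric null given the background
#' composition, that a random subset of `set_size` genes contains at least
#' (`direction = "over"`) or at most (`"under"`) `set_hits` of the
#' `background_hits` marked genes.
#'
#' @param set_hits,set_size,background_hits,background_size 2x2 counts; the
#'   set must be a subset of the background.
#' @param direction "over" or "under".
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact(3, 4, 4, 8)  # 17/70
fisher_exact <- function(set_hits, set_size, background_hits, background_size,
                         direction = c("over", "under")) {
  direction <- match.arg(direction)
  check_counts(set_hits, set_size, background_hits, background_size)
  if (direction == "over")
    stats::phyper(set_hits - 1, background_hits,
                  background_size - background_hits, set_size,
                  lower.tail = FALSE)
  else
    stats::phyper(set_hits, background_hits,
                  background_size - background_hits, set_size)
}

check_counts <- function(set_hits, set_size, background_hits, background_size) {
  counts <- c(set_hits, set_size, background_hits, background_size)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers",
          class = "dreamtdmr_validation_error")
  if (set_size > background_size || set_hits > set_size ||
      set_hits > background_hits ||
      (set_size - set_hits) > (background_size - background_hits))
    stopf("inconsistent 2x2 counts: set (%d/%d) vs background (%d/%d)",
          set_hits, set_size, background_hits, background_size,
          class = "dreamtdmr_validation_error")
  invisible(TRUE)
}

#' Build an enrichment result (counts, fold, exact p)
#'
#' Fold enrichment is `(set_hits/set_size) / (background_hits/
#' background_size)`, computed as a single ratio of integer products so the
#' rational identity `fold * background fraction = set fraction` holds
#' exactly.
#'
#' @inheritParams fisher_exact
#' @return Object of class `enrichment_result`: the four counts, `fold`,
#'   `p_value`, `direction`.
#' @export
enrichment_result <- function(set_hits, set_size, background_hits,
                              background_size, direction = "over") {
  check_counts(set_hits, set_size, background_hits, background_size)
  fold <- if (set_size == 0 || background_hits == 0) NA_real_
  else (set_hits * background_size) / (set_size * background_hits)
  structure(list(set_hits = set_hits, set_size = set_size,
                 background_hits = background_hits,
                 background_size = background_size,
                 fold = fold,
                 p_value = fisher_exact(set_hits, set_size, background_hits,
                                        background_size, direction),
                 direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment (%s): %d/%d vs %d/%d, fold %.3g, p = %.3g\n",
              x$direction, x$set_hits, x$set_size, x$background_hits,
              x$background_size, x$fold, x$p_value))
  invisible(x)
}

#' Functional-category enrichment in tissue-hypo genes
#'
#' For each functional category: set = nuclear mt genes with tissue-hypo
#' T-DMRs in `tissue`, background = all nuclear mt genes; both over- and
#' underrepresentation are reported. Categories requested but absent from
#' the annotation are skipped with a warning.
#'
#' @param gene_summary a [summarize_genes()] result.
#' @param annotation gene annotation with a `categories` column
#'   (comma-separated labels).
#' @param tissue focal tissue.
#' @param categories categories to test (default: all in the annotation).
#' @return data.table: category, direction, set_hits, set_size,
#'   background_hits, background_size, fold, p_value.
#' @export
category_enrichment <- function(gene_summary, annotation, tissue,
                                categories = NULL) {
  stopifnot(inherits(gene_summary, "gene_summary"))
  assert_columns(annotation, c("gene_id", "is_nuclear_mt", "categories"),
                 "annotation")
  mt <- annotation[annotation$is_nuclear_mt, ]
  fl <- gene_summary$tissue_flags
  hypo <- fl$gene_id[fl$tissue == tissue & fl$has_tissue_hypo]
  hypo <- intersect(hypo, mt$gene_id)
  if (length(hypo) == 0L)
    stopf("no nuclear mt genes with %s-hypo T-DMRs", tissue,
          class = "dreamtdmr_validation_error")
  cat_list <- strsplit(mt$categories, ",", fixed = TRUE)
  present <- sort(unique(unlist(cat_list)))
  present <- present[nzchar(present)]
  categories <- categories %||% present
  absent <- setdiff(categories, present)
  if (length(absent)) {
    warnf("category(ies) absent from annotation, skipped: %s",
          paste(absent, collapse = ", "))
    categories <- setdiff(categories, absent)
  }
  in_hypo <- mt$gene_id %in% hypo
  rows <- lapply(categories, function(cc) {
    has_cat <- vapply(cat_list, function(x) cc %in% x, logical(1))
    data.table::rbindlist(lapply(c("over", "under"), function(dir) {
      r <- enrichment_result(sum(has_cat & in_hypo), sum(in_hypo),
                             sum(has_cat), nrow(mt), dir)
      data.table::data.table(category = cc, direction = dir,
                             set_hits = r$set_hits, set_size = r$set_size,
                             background_hits = r$background_hits,
                             background_size = r$background_size,
                             fold = r$fold, p_value = r$p_value)
    }))
  })
  data.table::rbindlist(rows)
}

#' Flag TF target genes from binding-site intervals
#'
#' A gene is a target iff at least one binding-site interval (ChIP peak)
#' overlaps its extended gene region: from `upstream_bp` upstream of the
#' TSS to `downstream_of_3prime_bp` beyond the 3' end, in transcription
#' direction (mirrored for - strand genes). Intervals are 0-based
#' half-open.
#'
#' @param binding_sites interval table (chrom, start, end).
#' @param annotation gene annotation (gene_id, chrom, strand, tss,
#'   three_prime_end).
#' @param upstream_bp extension upstream of the TSS (default 10000).
#' @param downstream_of_3prime_bp extension beyond the 3' end (default
#'   1000).
#' @return character vector of target gene ids.
#' @export
flag_target_genes <- function(binding_sites, annotation,
                              upstream_bp = 10000L,
                              downstream_of_3prime_bp = 1000L) {
  assert_columns(binding_sites, c("chrom", "start", "end"), "binding sites")
  assert_columns(annotation, c("gene_id", "chrom", "strand", "tss",
                               "three_prime_end"), "annotation")
  plus <- annotation$strand == "+"
  region_start <- ifelse(plus, annotation$tss - upstream_bp,
                         annotation$three_prime_end - downstream_of_3prime_bp)
  region_end <- ifelse(plus,
                       annotation$three_prime_end + downstream_of_3prime_bp + 1L,
                       annotation$tss + upstream_bp + 1L)
  hit <- vapply(seq_len(nrow(annotation)), function(i) {
    same <- binding_sites$chrom == annotation$chrom[i]
    any(same & binding_sites$start < region_end[i] &
          binding_sites$end > region_start[i])
  }, logical(1))
  annotation$gene_id[hit]
}

#' TF target enrichment in a focal gene set
#'
#' @param targets character vector of target gene ids.
#' @param focal focal gene set (non-empty, subset of background).
#' @param background background gene set.
#' @param direction "over" or "under".
#' @return an [enrichment_result()].
#' @export
tf_target_enrichment <- function(targets, focal, background,
                                 direction = "over") {
  if (length(focal) == 0L)
    stopf("empty focal gene set", class = "dreamtdmr_validation_error")
  if (!all(focal %in% background))
    stopf("focal set must be a subset of the background",
          class = "dreamtdmr_validation_error")
  enrichment_result(sum(focal %in% targets), length(focal),
                    sum(background %in% targets), length(background),
                    direction)
}

#' Compare downstream-hypo fractions between two tissues
#'
#' Among genes with tissue-hypo T-DMRs in each tissue, tests whether the
#' `tissue_a` group contains a larger proportion of genes whose hypo
#' T-DMRs lie downstream of the TSS (one-sided exact test on the 2x2
#' tissue x has-downstream table; set = `tissue_a` group, background = the
#' pooled groups).
#'
#' @param gene_summary a [summarize_genes()] result.
#' @param tissue_a,tissue_b tissue labels.
#' @param nuclear_mt_only restrict to nuclear mt genes (default TRUE).
#' @param annotation required when `nuclear_mt_only`.
#' @return an [enrichment_result()].
#' @export
downstream_fraction_test <- function(gene_summary, tissue_a, tissue_b,
                                     nuclear_mt_only = TRUE,
                                     annotation = NULL) {
  stopifnot(inherits(gene_summary, "gene_summary"))
  fl <- gene_summary$tissue_flags
  if (nuclear_mt_only) {
    keep <- gene_summary$genes$gene_id[gene_summary$genes$is_nuclear_mt]
    fl <- fl[fl$gene_id %in% keep, ]
  }
  ga <- fl[fl$tissue == tissue_a & fl$has_tissue_hypo, ]
  gb <- fl[fl$tissue == tissue_b & fl$has_tissue_hypo, ]
  if (nrow(ga) == 0L || nrow(gb) == 0L)
    stopf("empty hypo gene set for '%s'",
          if (nrow(ga) == 0L) tissue_a else tissue_b,
          class = "dreamtdmr_validation_error")
  enrichment_result(sum(ga$has_downstream), nrow(ga),
                    sum(ga$has_downstream) + sum(gb$has_downstream),
                    nrow(ga) + nrow(gb), "over")
}

#' Nuclear-mt gene ratio among all genes and among hypo-T-DMR genes
#'
#' @param gene_summary a [summarize_genes()] result.
#' @param tissue focal tissue whose hypo genes form the second group
#'   (NULL: genes with any tissue-hypo T-DMR).
#' @param downstream_only restrict the hypo group to genes whose hypo
#'   T-DMRs include a downstream site.
#' @return list: `all` (nuclear-mt fraction of all genes), `hypo`
#'   (nuclear-mt fraction of the hypo group), `n_all`, `n_hypo`.
#' @export
nuclear_mt_ratio <- function(gene_summary, tissue = NULL,
                             downstream_only = FALSE) {
  stopifnot(inherits(gene_summary, "gene_summary"))
  g <- gene_summary$genes
  fl <- gene_summary$tissue_flags
  if (!is.null(tissue)) fl <- fl[which(fl$tissue == tissue), ]
  fl <- fl[fl$has_tissue_hypo & (!downstream_only | fl$has_downstream), ]
  hypo_genes <- unique(fl$gene_id)
  if (length(hypo_genes) == 0L)
    stopf("no genes with the requested hypo T-DMRs",
          class = "dreamtdmr_validation_error")
  list(all = mean(g$is_nuclear_mt),
       hypo = mean(g$is_nuclear_mt[g$gene_id %in% hypo_genes]),
       n_all = nrow(g), n_hypo = length(hypo_genes))
}
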