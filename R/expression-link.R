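# linkage of hypo T-DMR position classes to tissue expression ratios

#' Per-gene log2 expression ratios between two tissues
#'
#' Mean over replicates of `tissue_a` minus mean over replicates of
#' `tissue_b` (values are already log2). Genes lacking values in either
#' tissue are excluded with a warning.
#'
#' @param expr expression matrix (genes x samples, log2), columns
#'   `<tissue>_<replicate>`, rows named by gene id.
#' @param gene_ids genes to report.
#' @param tissue_a,tissue_b tissue labels.
#' @return named numeric vector of ratios.
#' @export
expression_log2_ratio <- function(expr, gene_ids, tissue_a, tissue_b) {
  expr <- as.matrix(expr)
  tiss <- sample_tissues(colnames(expr))
  if (!any(tiss == tissue_a) || !any(tiss == tissue_b))
    stopf("tissue '%s' absent from expression matrix",
          if (any(tiss == tissue_a)) tissue_b else tissue_a,
          class = "dreamtdmr_validation_error")
  present <- gene_ids %in% rownames(expr)
  if (!all(present)) {
    warnf("%d gene(s) missing from the expression matrix; excluded",
          sum(!present))
    gene_ids <- gene_ids[present]
  }
  a <- rowMeans(expr[gene_ids, tiss == tissue_a, drop = FALSE], na.rm = TRUE)
  b <- rowMeans(expr[gene_ids, tiss == tissue_b, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(a) | !is.finite(b)
  if (any(bad)) {
    warnf("%d gene(s) lack values in one tissue; excluded", sum(bad))
    a <- a[!bad]; b <- b[!bad]
  }
  a - b
}

#' Rank-sum shift test of a ratio subset against a reference
#'
#' Two-sample Wilcoxon rank-sum test of `ratios_subset` against
#' `ratios_reference`, with exact enumeration when the pooled sample size
#' is at most 20 and tie-free, and the normal approximation with tie
#' correction otherwise. Degenerate all-tied input returns p = 1 with a
#' warning. Quartile summaries are returned for boxplot-style reporting.
#'
#' @param ratios_subset,ratios_reference numeric vectors (each length >= 3).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list: p_value, statistic, n_subset, n_reference, median, q1, q3.
#' @export
ratio_shift_test <- function(ratios_subset, ratios_reference,
                             alternative = "two.sided") {
  if (length(ratios_subset) < 3L || length(ratios_reference) < 3L)
    stopf("both ratio lists need >= 3 values (got %d and %d)",
          length(ratios_subset), length(ratios_reference),
          class = "dreamtdmr_validation_error")
  pooled <- c(ratios_subset, ratios_reference)
  qs <- stats::quantile(ratios_subset, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(pooled)) == 1L) {
    warnf("all ratios tied; shift test degenerate, p = 1")
    return(list(p_value = 1, statistic = NA_real_,
                n_subset = length(ratios_subset),
                n_reference = length(ratios_reference),
                median = qs[2L], q1 = qs[1L], q3 = qs[3L]))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- length(pooled) <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    ratios_subset, ratios_reference, alternative = alternative,
    exact = exact, correct = !exact))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_subset = length(ratios_subset),
       n_reference = length(ratios_reference),
       median = qs[2L], q1 = qs[1L], q3 = qs[3L])
}

#' Expression-ratio report by hypo T-DMR position class
#'
#' For each ordered tissue pair (hypo tissue vs comparison tissue), builds
#' three ratio distributions over nuclear mt genes -- All (every nuclear mt
#' gene), U (genes with upstream tissue-hypo T-DMRs) and D (genes with
#' downstream tissue-hypo T-DMRs) -- and rank-sum p-values of U and D
#' against All (the reference row itself carries no p). Genes belonging to
#' both U and D are counted in both.
#'
#' @param gene_summary a [summarize_genes()] result.
#' @param expr expression matrix (see [expression_log2_ratio()]).
#' @param pairs list of c(hypo_tissue, vs_tissue) pairs; default every
#'   ordered pair of tissues present in the summary flags.
#' @param alternative test sidedness (default "two.sided").
#' @param min_genes minimum class size for a testable row (default 3).
#' @return data.table: hypo_tissue, vs_tissue, class ("All"/"U"/"D"), n,
#'   median, q1, q3, p_value (NA for All and for classes below
#'   `min_genes`).
#' @export
position_class_report <- function(gene_summary, expr, pairs = NULL,
                                  alternative = "two.sided", min_genes = 3L) {
  stopifnot(inherits(gene_summary, "gene_summary"))
  g <- gene_summary$genes
  fl <- gene_summary$tissue_flags
  mt_genes <- g$gene_id[g$is_nuclear_mt]
  tissues <- sort(unique(fl$tissue))
  if (is.null(pairs)) {
    pairs <- list()
    for (a in tissues) for (b in setdiff(tissues, a))
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  rows <- list()
  for (pr in pairs) {
    a <- pr[1L]; b <- pr[2L]
    ref <- suppressWarnings(expression_log2_ratio(expr, mt_genes, a, b))
    fa <- fl[fl$tissue == a & fl$has_tissue_hypo, ]
    classes <- list(
      All = mt_genes,
      U = intersect(fa$gene_id[fa$has_upstream], mt_genes),
      D = intersect(fa$gene_id[fa$has_downstream], mt_genes))
    for (cl in names(classes)) {
      ids <- classes[[cl]]
      ids <- ids[ids %in% names(ref)]
      if (length(ids) == 0L) next  # class absent for this pair
      r <- ref[ids]
      p <- NA_real_
      if (cl != "All" && length(r) >= min_genes)
        p <- ratio_shift_test(r, ref, alternative)$p_value
      qs <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        hypo_tissue = a, vs_tissue = b, class = cl, n = length(r),
        median = qs[2L], q1 = qs[1L], q3 = qs[3L], p_value = p)
    }
  }
  data.table::rbindlist(rows)
}
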