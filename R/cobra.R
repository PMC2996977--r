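# COBRA quantification, confirmation, and score-threshold calibration

#' Methylation level from COBRA fragment amounts
#'
#' COBRA digests the bisulfite PCR product at sites whose CpG was methylated
#' (and hence retained after conversion), so the methylation level is the
#' cut fraction: `cut / (cut + uncut)`.
#'
#' @param cut_amount,uncut_amount non-negative fragment amounts
#'   (electropherogram units); vectorized.
#' @return methylation fraction(s) in \[0, 1\].
#' @export
#' @examples
#' methylation_level(30, 70)  # 0.3
methylation_level <- function(cut_amount, uncut_amount) {
  if (any(cut_amount < 0) || any(uncut_amount < 0))
    stopf("fragment amounts must be non-negative",
          class = "dreamtdmr_validation_error")
  tot <- cut_amount + uncut_amount
  if (any(tot <= 0))
    stopf("undefined COBRA measurement: cut + uncut amounts are zero",
          class = "dreamtdmr_measurement_error")
  cut_amount / tot
}

cobra_level_at <- function(measurements, site, tissue) {
  assert_columns(measurements, c("site", "tissue", "cut_amount", "uncut_amount"),
                 "COBRA measurements")
  sel <- which(measurements$site == site & measurements$tissue == tissue)
  row <- as.data.frame(measurements)[sel, ]
  if (nrow(row) == 0L)
    stopf("no COBRA measurement for site %s in tissue '%s'", site, tissue,
          class = "dreamtdmr_measurement_error")
  mean(methylation_level(row$cut_amount, row$uncut_amount))
}

#' Decide whether COBRA confirms hypomethylation
#'
#' Confirmed when the level in `tissue_a` is at least `delta` below the
#' level in `tissue_b` (`level_a <= level_b - delta`). With `delta = 0` the
#' inequality is strict, so equal levels never confirm.
#'
#' @param measurements COBRA table (site, tissue, cut_amount, uncut_amount).
#' @param site site position.
#' @param tissue_a candidate hypomethylated tissue.
#' @param tissue_b comparison tissue.
#' @param delta required methylation-difference margin (default 0.2).
#' @return logical.
#' @export
confirm_hypomethylation <- function(measurements, site, tissue_a, tissue_b,
                                    delta = 0.2) {
  assert_fraction(delta, "delta")
  la <- cobra_level_at(measurements, site, tissue_a)
  lb <- cobra_level_at(measurements, site, tissue_b)
  if (delta == 0) la < lb else la <= lb - delta
}

#' Sites eligible for COBRA validation in a directed comparison
#'
#' Candidates are the usable sites whose directed score strictly exceeds
#' `prefilter_score` (default 2) for the given hypomethylated-tissue
#' direction.
#'
#' @param scores unordered-pair score table from [score_all_sites()].
#' @param prefilter_score strict lower bound on the directed score.
#' @return data.table: site, hypo_tissue, vs_tissue, score.
#' @export
select_validation_candidates <- function(scores, prefilter_score = 2) {
  d <- directed_scores(scores)
  d[d$usable & !is.na(d$score) & d$score > prefilter_score,
    c("site", "hypo_tissue", "vs_tissue", "score")]
}

#' Calibrate the score threshold of one directed comparison
#'
#' The threshold is the lowest score among validation candidates
#' (directed score > `prefilter_score`) whose hypomethylation COBRA
#' confirms. Zero confirmed candidates is a calibration error instructing
#' fallback to a user-supplied threshold.
#'
#' @inheritParams confirm_hypomethylation
#' @param scores unordered-pair score table.
#' @param hypo_tissue,vs_tissue the directed comparison.
#' @param prefilter_score strict candidate prefilter (default 2).
#' @param max_candidates at most this many top-scoring candidates are
#'   assayed (COBRA is a low-throughput validation; `Inf` assays all).
#' @return list: hypo_tissue, vs_tissue, threshold, confirmed_sites,
#'   n_candidates.
#' @export
calibrate_threshold <- function(scores, measurements, hypo_tissue, vs_tissue,
                                delta = 0.2, prefilter_score = 2,
                                max_candidates = Inf) {
  cand <- select_validation_candidates(scores, prefilter_score)
  sel <- which(cand$hypo_tissue == hypo_tissue & cand$vs_tissue == vs_tissue)
  cand <- cand[sel, ]
  if (is.finite(max_candidates) && nrow(cand) > max_candidates) {
    data.table::setorder(cand, -score)
    cand <- cand[seq_len(max_candidates), ]
  }
  confirmed <- logical(nrow(cand))
  for (i in seq_len(nrow(cand)))
    confirmed[i] <- confirm_hypomethylation(measurements, cand$site[i],
                                            hypo_tissue, vs_tissue, delta)
  if (!any(confirmed))
    stopf(paste0("no COBRA-confirmed candidate for %s vs %s: calibration ",
                 "impossible, supply a threshold manually"),
          hypo_tissue, vs_tissue, class = "dreamtdmr_calibration_error")
  list(hypo_tissue = hypo_tissue, vs_tissue = vs_tissue,
       threshold = min(cand$score[confirmed]),
       confirmed_sites = cand$site[confirmed],
       n_candidates = nrow(cand))
}

#' Calibrate thresholds for every directed tissue comparison
#'
#' @inheritParams calibrate_threshold
#' @param tissues tissue labels (default: all present in `measurements`).
#' @return data.table of class `threshold_set`: hypo_tissue, vs_tissue,
#'   threshold, n_candidates, n_confirmed, provenance (comma-separated
#'   confirmed site positions).
#' @export
calibrate_thresholds <- function(scores, measurements, tissues = NULL,
                                 delta = 0.2, prefilter_score = 2,
                                 max_candidates = Inf) {
  tissues <- tissues %||% sort(unique(c(scores$tissue_a, scores$tissue_b)))
  out <- list()
  for (a in tissues) for (b in setdiff(tissues, a)) {
    th <- calibrate_threshold(scores, measurements, a, b, delta,
                              prefilter_score, max_candidates)
    out[[paste(a, b)]] <- data.table::data.table(
      hypo_tissue = a, vs_tissue = b, threshold = th$threshold,
      n_candidates = th$n_candidates,
      n_confirmed = length(th$confirmed_sites),
      provenance = paste(th$confirmed_sites, collapse = ","))
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class", c("threshold_set", class(res)))
  res[]
}
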