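# probe affinity model, standardization and windowed trimmed-mean site scores

probe_design_matrix <- function(sequences, copy_number) {
  L <- nchar(sequences[1L])
  if (any(nchar(sequences) != L))
    stopf("probe sequences must all have length %d", L,
          class = "dreamtdmr_validation_error")
  X <- matrix(0, length(sequences), 3L * L + 2L)
  X[, 1L] <- 1
  cn <- c("intercept", as.vector(outer(c("C", "G", "T"), seq_len(L),
                                       function(b, p) paste0("pos", p, b))),
          "log2_copy")
  k <- 2L
  for (p in seq_len(L)) {
    base <- substr(sequences, p, p)
    for (nt in c("C", "G", "T")) {
      X[, k] <- base == nt
      k <- k + 1L
    }
  }
  X[, k] <- log2(copy_number)
  colnames(X) <- cn
  X
}

#' Fit the probe-affinity baseline model
#'
#' Least-squares fit of log intensity on positional nucleotide indicators
#' (base A is the reference at each of the 25 positions) and log2 copy
#' number. The model is fitted per sample and the coefficients are averaged
#' across samples, which absorbs sample-specific brightness; the residual
#' scale is the median absolute deviation (x 1.4826) of the pooled
#' residuals. A rank-deficient design (for instance all-identical
#' sequences) degenerates gracefully: unidentifiable coefficients are set
#' to zero with a warning, leaving an intercept-dominated baseline.
#'
#' @param probes probe table (probe_id, sequence, copy_number).
#' @param intensities log-intensity matrix, rows matching `probes`.
#' @param min_probes minimum number of probes for a reliable calibration.
#' @return Object of class `affinity_model`: coefficients, residual_scale,
#'   probe_ids, fitted baseline.
#' @export
fit_affinity_model <- function(probes, intensities, min_probes = 200L) {
  assert_columns(probes, c("probe_id", "sequence", "copy_number"), "probes")
  intensities <- as.matrix(intensities)
  if (nrow(probes) != nrow(intensities))
    stopf("probes and intensities disagree on probe count",
          class = "dreamtdmr_validation_error")
  if (nrow(probes) < min_probes)
    stopf("affinity calibration needs >= %d probes, got %d", min_probes,
          nrow(probes), class = "dreamtdmr_validation_error")
  X <- probe_design_matrix(probes$sequence, probes$copy_number)
  qx <- qr(X)
  betas <- qr.coef(qx, intensities)  # one column per sample
  if (anyNA(betas)) {
    warnf("affinity design is rank deficient; %d coefficient(s) set to 0",
          sum(is.na(betas[, 1L])))
    betas[is.na(betas)] <- 0
  }
  beta <- rowMeans(betas)
  baseline <- drop(X %*% beta)
  resid <- intensities - baseline
  scale <- stats::mad(resid, center = 0)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 residual_scale = max(scale, 1e-8),
                 probe_ids = probes$probe_id,
                 baseline = stats::setNames(baseline, probes$probe_id)),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat("affinity_model:", length(x$probe_ids), "probes; residual scale",
      signif(x$residual_scale, 4), "\n")
  invisible(x)
}

#' Standardize intensities against a fitted affinity model
#'
#' t-value = (log intensity - predicted baseline) / residual scale, per
#' probe per sample.
#'
#' @param intensities log-intensity matrix, rows named by probe_id.
#' @param model an [fit_affinity_model()] result fitted on the same probes.
#' @return t-value matrix of the same shape.
#' @export
standardize <- function(intensities, model) {
  stopifnot(inherits(model, "affinity_model"))
  intensities <- as.matrix(intensities)
  ids <- rownames(intensities) %||% model$probe_ids[seq_len(nrow(intensities))]
  unknown <- setdiff(ids, model$probe_ids)
  if (length(unknown))
    stopf("probe(s) absent from the affinity model universe: %s",
          paste(utils::head(unknown, 3L), collapse = ", "),
          class = "dreamtdmr_validation_error")
  (intensities - model$baseline[ids]) / model$residual_scale
}

trimmed_mean <- function(x, trim) mean(x, trim = trim)

site_score_core <- function(tv_a, tv_b, n_probes, trim, min_probes) {
  usable <- n_probes >= min_probes
  n_a <- length(tv_a); n_b <- length(tv_b)
  score <- if (usable)
    sqrt(n_a + n_b) * (trimmed_mean(tv_a, trim) - trimmed_mean(tv_b, trim))
  else NA_real_
  list(score = score, n_probes = n_probes, n_a = n_a, n_b = n_b,
       usable = usable)
}

#' Differential methylation score at one restriction site
#'
#' Pools the t-values of all probes (x replicates) of each tissue within
#' `window_bp` of the site, takes symmetric trimmed means and returns
#' `sqrt(n_a + n_b) * (TM_a - TM_b)`. Positive scores indicate relative
#' hypomethylation of `tissue_a` (its amplified-fragment signal is higher).
#' Windows holding fewer than `min_probes` probes are flagged unusable
#' (score `NA`) rather than silently zero.
#'
#' @param tvalues t-value matrix from [standardize()], columns
#'   `<tissue>_<replicate>`.
#' @param probes probe table with `start` (and `copy_number` for repeat
#'   suppression).
#' @param site site position (bp).
#' @param tissue_a,tissue_b tissue labels.
#' @param window_bp half-window around the site (default 300).
#' @param trim symmetric trim fraction of the trimmed mean (default 0.10).
#' @param min_probes minimum probes in the window (default 4).
#' @param copy_max probes with copy number above this are excluded (default
#'   10; repeat suppression).
#' @return list: site, tissue_a, tissue_b, score, n_probes, n_a, n_b, usable.
#' @export
site_score <- function(tvalues, probes, site, tissue_a, tissue_b,
                       window_bp = 300L, trim = 0.10, min_probes = 4L,
                       copy_max = 10L) {
  keep <- probes$copy_number <= copy_max
  centre <- probes$start + nchar(probes$sequence[1L]) %/% 2L
  in_win <- keep & abs(centre - site) <= window_bp
  tiss <- sample_tissues(colnames(tvalues))
  tv_a <- as.vector(tvalues[in_win, tiss == tissue_a, drop = FALSE])
  tv_b <- as.vector(tvalues[in_win, tiss == tissue_b, drop = FALSE])
  if (!any(tiss == tissue_a) || !any(tiss == tissue_b))
    stopf("tissue '%s' has no sample columns",
          if (any(tiss == tissue_a)) tissue_b else tissue_a,
          class = "dreamtdmr_validation_error")
  c(list(site = site, tissue_a = tissue_a, tissue_b = tissue_b),
    site_score_core(tv_a, tv_b, sum(in_win), trim, min_probes))
}

#' Score every site for every unordered tissue pair
#'
#' Scores are stored once per unordered pair in a fixed direction:
#' alphabetical tissue order, positive meaning the alphabetically first
#' tissue is relatively hypomethylated. Directed scores for the opposite
#' direction are obtained by sign flip (see [directed_scores()]).
#'
#' @inheritParams site_score
#' @param sites site table (`pos`).
#' @param tissues tissue labels to use; default all found in `tvalues`.
#' @return data.table: site, tissue_a, tissue_b (a < b), score, n_probes,
#'   n_a, n_b, usable. `length(sites) * choose(n_tissues, 2)` rows.
#' @export
score_all_sites <- function(tvalues, probes, sites, tissues = NULL,
                            window_bp = 300L, trim = 0.10, min_probes = 4L,
                            copy_max = 10L) {
  tiss_of_col <- sample_tissues(colnames(tvalues))
  tissues <- sort(tissues %||% unique(tiss_of_col))
  if (length(tissues) < 2L)
    stopf("need >= 2 tissues", class = "dreamtdmr_validation_error")
  keep <- probes$copy_number <= copy_max
  centre <- probes$start + nchar(probes$sequence[1L]) %/% 2L
  ord <- order(centre)
  ord <- ord[keep[ord]]
  centre_s <- centre[ord]
  cols_by_tissue <- lapply(tissues, function(t) which(tiss_of_col == t))
  names(cols_by_tissue) <- tissues
  pairs <- utils::combn(tissues, 2L)

  pos <- sites$pos
  lo <- findInterval(pos - window_bp - 0.5, centre_s) + 1L
  hi <- findInterval(pos + window_bp + 0.5, centre_s)
  n_pairs <- ncol(pairs)
  n_sites <- length(pos)
  res_score <- matrix(NA_real_, n_sites, n_pairs)
  res_n <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    if (hi[i] < lo[i]) { res_n[i] <- 0L; next }
    rows <- ord[lo[i]:hi[i]]
    res_n[i] <- length(rows)
    if (res_n[i] < min_probes) next
    tm <- vapply(tissues, function(t)
      trimmed_mean(as.vector(tvalues[rows, cols_by_tissue[[t]], drop = FALSE]),
                   trim), numeric(1))
    nv <- vapply(tissues, function(t)
      res_n[i] * length(cols_by_tissue[[t]]), numeric(1))
    for (p in seq_len(n_pairs)) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      res_score[i, p] <- sqrt(nv[a] + nv[b]) * (tm[a] - tm[b])
    }
  }
  out <- data.table::rbindlist(lapply(seq_len(n_pairs), function(p) {
    nv_a <- res_n * length(cols_by_tissue[[pairs[1L, p]]])
    nv_b <- res_n * length(cols_by_tissue[[pairs[2L, p]]])
    data.table::data.table(
      site = pos, tissue_a = pairs[1L, p], tissue_b = pairs[2L, p],
      score = res_score[, p], n_probes = res_n,
      n_a = nv_a, n_b = nv_b, usable = res_n >= min_probes)
  }))
  data.table::setorder(out, site, tissue_a, tissue_b)
  out[]
}

#' Expand unordered pair scores to directed comparisons
#'
#' @param scores table from [score_all_sites()].
#' @return data.table: site, hypo_tissue, vs_tissue, score (positive means
#'   hypo_tissue hypomethylated relative to vs_tissue), n_probes, usable.
#' @export
directed_scores <- function(scores) {
  assert_columns(scores, c("site", "tissue_a", "tissue_b", "score"), "scores")
  fwd <- data.table::data.table(site = scores$site,
                                hypo_tissue = scores$tissue_a,
                                vs_tissue = scores$tissue_b,
                                score = scores$score,
                                n_probes = scores$n_probes,
                                usable = scores$usable)
  rev <- data.table::data.table(site = scores$site,
                                hypo_tissue = scores$tissue_b,
                                vs_tissue = scores$tissue_a,
                                score = -scores$score,
                                n_probes = scores$n_probes,
                                usable = scores$usable)
  out <- data.table::rbindlist(list(fwd, rev))
  data.table::setorder(out, site, hypo_tissue, vs_tissue)
  out[]
}
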