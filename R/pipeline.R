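# pipeline configuration, end-to-end orchestration and the CLI entry point

pipeline_defaults <- list(
  window_bp = 300, trim = 0.10, min_probes = 4, copy_max = 10,
  prefilter = 2.0, cobra_delta = 0.2,
  upstream = 7000, downstream = 3000,
  tf_upstream = 10000, tf_downstream_of_3prime = 1000,
  bin_bp = 1000, alpha = 0.05, seed = 1
)

#' Pipeline configuration
#'
#' All analysis tunables with their defaults: scoring window (+/- 300 bp),
#' trim fraction 0.10, minimum 4 probes per window, repeat-suppression copy
#' cutoff 10, strict COBRA candidate prefilter score 2, COBRA confirmation
#' margin 0.2, TSS window -7000/+3000 bp, extended TF gene region 10 kb
#' upstream / 1 kb beyond the 3' end, 1 kb positional bins, alpha 0.05.
#' Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return Object of class `pipeline_config` (named list).
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "),
          class = "dreamtdmr_validation_error")
  cfg <- utils::modifyList(pipeline_defaults, over)
  assert_scalar_number(cfg$window_bp, "window_bp", min = 1)
  assert_fraction(cfg$trim, "trim")
  assert_count(cfg$min_probes, "min_probes")
  assert_scalar_number(cfg$prefilter, "prefilter")
  assert_fraction(cfg$cobra_delta, "cobra_delta")
  assert_scalar_number(cfg$upstream, "upstream", min = 0)
  assert_scalar_number(cfg$downstream, "downstream", min = 0)
  assert_fraction(cfg$alpha, "alpha")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full T-DMR analysis on a directory of input files
#'
#' Executes score -> calibrate -> call -> enrich -> express on the schema
#' files written by [write_simulation()] (or user-supplied files of the
#' same schemas): annotation.tsv, sites.bed, probes.tsv, intensities.tsv,
#' cobra.tsv, and optionally expression.tsv and tf_targets.txt. Writes
#' scores.tsv, thresholds.tsv, calls.bed, gene_summary.tsv, enrichment.tsv,
#' expression_report.tsv, a machine-readable manifest.json (package
#' version, configuration, input/output checksums) and a human-readable
#' summary.txt with the headline percentage of nuclear mt genes carrying
#' T-DMRs. Per-stage timing goes to stderr.
#'
#' @param input_dir directory of input files.
#' @param output_dir report directory (created).
#' @param config a [pipeline_config()].
#' @return list: gene_summary, scores, thresholds, calls, tissue_hypo,
#'   enrichment, expression_report (possibly NULL), manifest.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline aborted at stage '%s': %s", stage, conditionMessage(e),
            class = "dreamtdmr_pipeline_error"))
    stage_msg(stage, t0)
    res
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p_in <- function(f) file.path(input_dir, f)
  p_out <- function(f) file.path(output_dir, f)

  inputs <- run_stage("read", {
    list(annotation = read_annotation(p_in("annotation.tsv")),
         sites = read_sites_bed(p_in("sites.bed")),
         probes = read_probes(p_in("probes.tsv")),
         intensities = read_matrix_tsv(p_in("intensities.tsv")),
         cobra = read_cobra(p_in("cobra.tsv")))
  })

  scores <- run_stage("score", {
    model <- fit_affinity_model(inputs$probes, inputs$intensities)
    tv <- standardize(inputs$intensities, model)
    score_all_sites(tv, inputs$probes, inputs$sites,
                    window_bp = config$window_bp, trim = config$trim,
                    min_probes = config$min_probes,
                    copy_max = config$copy_max)
  })
  write_scores(scores, p_out("scores.tsv"))

  thresholds <- run_stage("calibrate", {
    calibrate_thresholds(scores, inputs$cobra, delta = config$cobra_delta,
                         prefilter_score = config$prefilter)
  })
  write_thresholds(thresholds, p_out("thresholds.tsv"))

  tissues <- sort(unique(c(scores$tissue_a, scores$tissue_b)))
  res_call <- run_stage("call", {
    calls <- call_hypo_sites(scores, thresholds)
    tissue_hypo <- classify_tissue_hypo(calls, tissues)
    assignments <- assign_sites_to_genes(inputs$sites, inputs$annotation,
                                         upstream_bp = config$upstream,
                                         downstream_bp = config$downstream)
    summary <- summarize_genes(assignments, calls, tissue_hypo,
                               inputs$annotation)
    list(calls = calls, tissue_hypo = tissue_hypo,
         assignments = assignments, summary = summary)
  })
  write_calls_bed(res_call$tissue_hypo, res_call$calls, res_call$assignments,
                  inputs$annotation, p_out("calls.bed"))
  write_gene_summary(res_call$summary, p_out("gene_summary.tsv"))

  enrich <- run_stage("enrich", {
    rows <- list()
    for (t in tissues) {
      tab <- tryCatch(category_enrichment(res_call$summary,
                                          inputs$annotation, t),
                      dreamtdmr_error = function(e) NULL)
      if (!is.null(tab)) { tab$tissue <- t; rows[[t]] <- tab }
    }
    tf_path <- p_in("tf_targets.txt")
    if (file.exists(tf_path)) {
      targets <- read_target_list(tf_path)
      mt <- inputs$annotation$gene_id[inputs$annotation$is_nuclear_mt]
      for (t in tissues) {
        fl <- res_call$summary$tissue_flags
        focal <- intersect(fl$gene_id[fl$tissue == t & fl$has_tissue_hypo], mt)
        if (length(focal) == 0L) next
        r <- tf_target_enrichment(targets, focal, mt)
        rows[[paste0("tf_", t)]] <- data.table::data.table(
          category = "tf_targets", direction = "over",
          set_hits = r$set_hits, set_size = r$set_size,
          background_hits = r$background_hits,
          background_size = r$background_size, fold = r$fold,
          p_value = r$p_value, tissue = t)
      }
    }
    data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  })
  if (nrow(enrich)) data.table::fwrite(enrich, p_out("enrichment.tsv"),
                                       sep = "\t")

  expr_report <- NULL
  if (file.exists(p_in("expression.tsv"))) {
    expr_report <- run_stage("express", {
      expr <- read_matrix_tsv(p_in("expression.tsv"))
      position_class_report(res_call$summary, expr)
    })
    data.table::fwrite(expr_report, p_out("expression_report.tsv"), sep = "\t")
  }

  manifest <- list(
    package = "dreamtdmr",
    version = as.character(utils::packageVersion("dreamtdmr")),
    config = unclass(config),
    inputs = as.list(tools::md5sum(list.files(input_dir, full.names = TRUE))),
    outputs = as.list(tools::md5sum(sort(setdiff(
      list.files(output_dir, full.names = TRUE),
      file.path(output_dir, c("manifest.json", "summary.txt")))))))
  jsonlite::write_json(manifest, p_out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  s <- res_call$summary$stats
  writeLines(c(
    sprintf("dreamtdmr run: %d genes, %d sites, %d tissues",
            s$n_genes, length(inputs$sites$pos), length(tissues)),
    sprintf("genes with T-DMRs: %d", s$n_with_tdmr),
    sprintf("nuclear mt genes with T-DMRs: %d of %d (%s%%)",
            s$n_nuclear_mt_with_tdmr, s$n_nuclear_mt,
            s$pct_nuclear_mt_with_tdmr),
    sprintf("tissue-hypo genes: %s",
            paste(sprintf("%s=%d", s$per_tissue$tissue, s$per_tissue$n_genes),
                  collapse = ", "))),
    p_out("summary.txt"))

  invisible(list(gene_summary = res_call$summary, scores = scores,
                 thresholds = thresholds, calls = res_call$calls,
                 tissue_hypo = res_call$tissue_hypo, enrichment = enrich,
                 expression_report = expr_report, manifest = manifest))
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stopf("expected --flag, got '%s'", a, class = "dreamtdmr_validation_error")
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `simulate --outdir DIR [--seed N] [--genes N]`,
#' `run --indir DIR --outdir DIR [--config FILE]`, and
#' `score`, `calibrate`, `call` for stage-wise use. Returns (and, under
#' `Rscript`, exits with) 0 on success and 2 on validation errors.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly.
#' @export
tdmr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stopf("usage: tdmr <simulate|run|score|calibrate|call> [--flags]",
            class = "dreamtdmr_validation_error")
    cmd <- args[1L]
    opts <- parse_cli_flags(args[-1L])
    cfgfile <- opts$config
    cfg <- if (!is.null(cfgfile)) read_pipeline_config(cfgfile)
    else pipeline_config()
    switch(
      cmd,
      simulate = {
        n_genes <- as.integer(opts$genes %||% 500L)
        sc <- sim_config(
          n_genes = n_genes,
          chrom_length = as.numeric(opts[["chrom-length"]] %||%
                                      (16000 * n_genes)),
          seed = as.integer(opts$seed %||% 1L))
        write_simulation(simulate_dream(sc), opts$outdir %||%
                           stopf("simulate needs --outdir",
                                 class = "dreamtdmr_validation_error"))
      },
      run = run_pipeline(opts$indir, opts$outdir, cfg),
      score = {
        probes <- read_probes(opts$probes)
        intens <- read_matrix_tsv(opts$intensities)
        sites <- read_sites_bed(opts$sites)
        model <- fit_affinity_model(probes, intens)
        tv <- standardize(intens, model)
        write_scores(score_all_sites(tv, probes, sites,
                                     window_bp = cfg$window_bp,
                                     trim = cfg$trim,
                                     min_probes = cfg$min_probes,
                                     copy_max = cfg$copy_max),
                     opts$out %||% "scores.tsv")
      },
      calibrate = {
        write_thresholds(
          calibrate_thresholds(read_scores(opts$scores),
                               read_cobra(opts$cobra),
                               delta = as.numeric(opts$delta %||%
                                                    cfg$cobra_delta),
                               prefilter_score = as.numeric(
                                 opts$prefilter %||% cfg$prefilter)),
          opts$out %||% "thresholds.tsv")
      },
      call = {
        scores <- read_scores(opts$scores)
        thresholds <- read_thresholds(opts$thresholds)
        annotation <- read_annotation(opts$annotation)
        sites <- read_sites_bed(opts$sites)
        calls <- call_hypo_sites(scores, thresholds)
        tissues <- sort(unique(c(scores$tissue_a, scores$tissue_b)))
        tissue_hypo <- classify_tissue_hypo(calls, tissues)
        assignments <- assign_sites_to_genes(sites, annotation,
                                             upstream_bp = cfg$upstream,
                                             downstream_bp = cfg$downstream)
        write_calls_bed(tissue_hypo, calls, assignments, annotation,
                        opts$out %||% "calls.bed")
      },
      stopf("unknown subcommand '%s'", cmd,
            class = "dreamtdmr_validation_error")
    )
    0L
  },
  dreamtdmr_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
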