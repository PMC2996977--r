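# synthetic data generator: determinism, planted ground truth, fixtures

test_that("generate_genome is deterministic and respects counts and tiling", {
  cfg <- small_config(seed = 11)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)

  expect_equal(nrow(g1$annotation), cfg$n_genes)
  expect_true(all(g1$annotation$tss >= 0 &
                    g1$annotation$tss < cfg$chrom_length))
  expect_setequal(unique(g1$annotation$strand), c("+", "-"))
  # non-overlapping gene bodies
  ann <- g1$annotation[order(g1$annotation$span_start), ]
  expect_true(all(ann$span_start[-1L] >= ann$span_end[-nrow(ann)]))
  # TSS inside the span, 3' end consistent with strand
  expect_true(all(ann$tss >= ann$span_start & ann$tss < ann$span_end))
  expect_identical(ann$three_prime_end,
                   ifelse(ann$strand == "+", ann$span_end - 1L,
                          ann$span_start))

  # probes tile at the configured spacing with monotone starts
  cfg2 <- sim_config(n_genes = 1, chrom_length = 35000, probe_spacing = 35,
                     seed = 1)
  pr <- generate_genome(cfg2)$probes
  expect_equal(nrow(pr), length(seq(0, 35000 - 25, by = 35)))
  expect_true(all(diff(pr$start) == 35))
  expect_true(all(nchar(pr$sequence) == 25))
  expect_true(all(pr$copy_number >= 1))
  expect_gt(mean(pr$copy_number == 1), 0.8)
})

test_that("generate_genome errors when the chromosome cannot hold the genes", {
  expect_error(generate_genome(sim_config(n_genes = 100, chrom_length = 1e5)),
               class = "dreamtdmr_sizing_error")
})

test_that("plant_methylation plants disjoint per-tissue hypo genes with the stated contrast", {
  cfg <- small_config(seed = 5)
  g <- generate_genome(cfg)
  truth <- suppressWarnings(plant_methylation(g$annotation, g$sites, cfg))
  ph <- truth$planted_hypo_genes
  # ~ frac * n_genes per tissue (minus the occasional skipped gene)
  n_target <- floor(cfg$frac_tissue_hypo_genes * cfg$n_genes)
  cnt <- table(ph$tissue)
  expect_true(all(cnt <= n_target) && all(cnt >= n_target - 2))
  # disjoint gene sets across tissues
  expect_false(anyDuplicated(ph$gene_id) > 0)

  # planted (site, tissue) strictly hypomethylated vs every other tissue
  m <- truth$site_methylation
  for (i in seq_len(nrow(truth$planted_hypo_sites))) {
    s <- as.character(truth$planted_hypo_sites$site[i])
    ti <- truth$planted_hypo_sites$tissue[i]
    expect_true(all(m[s, ti] < m[s, setdiff(colnames(m), ti)]))
    expect_equal(unname(m[s, ti]), cfg$hypo_level)
  }
  # non-planted sites share one level across tissues
  bg <- setdiff(rownames(m), as.character(truth$planted_hypo_sites$site))
  expect_true(all(apply(m[bg, , drop = FALSE], 1L,
                        function(r) diff(range(r)) == 0)))
})

test_that("plant_methylation zero fraction plants nothing", {
  cfg <- small_config(seed = 5, frac_tissue_hypo_genes = 0)
  g <- generate_genome(cfg)
  truth <- plant_methylation(g$annotation, g$sites, cfg)
  expect_equal(nrow(truth$planted_hypo_sites), 0L)
})

test_that("simulate_intensities matches its construction in the noise-free limits", {
  cfg <- small_config(seed = 7, noise_sd = 0, fragment_signal = 0)
  g <- generate_genome(cfg)
  truth <- suppressWarnings(plant_methylation(g$annotation, g$sites, cfg))
  ii <- simulate_intensities(truth, g$probes, g$sites, cfg)
  # zero signal, zero noise: pure affinity baseline, equal across samples
  expect_true(all(abs(ii - ii[, 1L]) < 1e-12))

  # fully unmethylated single site: its fragment probes read baseline + signal
  cfg2 <- small_config(seed = 7, noise_sd = 0, fragment_signal = 1.5)
  site <- make_sites(260000L)
  truth2 <- truth
  truth2$site_methylation <- matrix(0, 1, 3,
                                    dimnames = list("260000", cfg2$tissues))
  ii0 <- simulate_intensities(truth2, g$probes, site, cfg2)
  base <- ii[, 1L]  # affinity baseline from the zero-signal run
  centre <- g$probes$start + 12L
  onfrag <- abs(centre - 260000L) <= cfg2$max_fragment_bp
  expect_equal(unname(ii0[onfrag, 1L]), unname(base[onfrag] + 1.5),
               tolerance = 1e-12)
  expect_equal(unname(ii0[!onfrag, 2L]), unname(base[!onfrag]),
               tolerance = 1e-12)
})

test_that("replicate intensities correlate strongly at default noise", {
  sim <- small_sim()
  for (t in sim$config$tissues) {
    r <- cor(sim$intensities[, paste0(t, "_1")],
             sim$intensities[, paste0(t, "_2")])
    expect_gt(r, 0.9)
  }
})

test_that("simulate_cobra inverts exactly without noise and deterministically", {
  cfg <- small_config(seed = 9)
  g <- generate_genome(cfg)
  truth <- suppressWarnings(plant_methylation(g$annotation, g$sites, cfg))
  cb0 <- simulate_cobra(truth, g$sites, noise = 0, config = cfg)
  lev <- methylation_level(cb0$cut_amount, cb0$uncut_amount)
  expect_equal(lev, truth$site_methylation[cbind(as.character(cb0$site),
                                                 cb0$tissue)],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(simulate_cobra(truth, g$sites, noise = 0.05, config = cfg),
                   simulate_cobra(truth, g$sites, noise = 0.05, config = cfg))
})

test_that("COBRA quantification error stays small at 5% amount noise", {
  cfg <- sim_config(n_genes = 30, chrom_length = 30 * 13000,
                    site_density = 3, seed = 13)
  g <- generate_genome(cfg)  # ~1170 sites
  truth <- suppressWarnings(plant_methylation(g$annotation, g$sites, cfg))
  cb <- simulate_cobra(truth, g$sites, noise = 0.05, config = cfg)
  lev <- methylation_level(cb$cut_amount, cb$uncut_amount)
  err <- abs(lev - truth$site_methylation[cbind(as.character(cb$site),
                                                cb$tissue)])
  expect_gt(length(err), 1000)
  expect_lt(mean(err), 0.06)
})

test_that("simulate_expression plants the log2 effect on downstream-hypo genes only", {
  sim <- small_sim()
  cfg <- sim$config
  ph <- sim$truth$planted_hypo_genes
  down <- ph[ph$downstream & ph$tissue == "liver", ]
  expect_gt(nrow(down), 0L)
  other <- setdiff(cfg$tissues, "liver")[1L]
  r <- expression_log2_ratio(sim$expression, down$gene_id, "liver", other)
  expect_equal(median(r), cfg$expression_effect, tolerance = 0.2)
  # zero effect: ratios centred at 0
  cfg0 <- small_config(seed = 3, expression_effect = 0)
  g <- generate_genome(cfg0)
  truth <- suppressWarnings(plant_methylation(g$annotation, g$sites, cfg0))
  ex0 <- simulate_expression(truth, g$annotation, cfg0)
  r0 <- expression_log2_ratio(ex0, g$annotation$gene_id, "liver", other)
  expect_lt(abs(median(r0)), 0.2)
  expect_identical(simulate_expression(truth, g$annotation, cfg0),
                   simulate_expression(truth, g$annotation, cfg0))
})

test_that("simulate_tf_targets plants the requested fold and rejects infeasible folds", {
  cfg <- sim_config(n_genes = 2000, chrom_length = 2000 * 13000,
                    site_density = 0.05, probe_spacing = 5000, seed = 17)
  g <- generate_genome(cfg)
  hypo <- sample(g$annotation$gene_id, 600)
  targets <- simulate_tf_targets(g$annotation, hypo, cfg, fold = 1.6)
  r <- tf_target_enrichment(targets, hypo, g$annotation$gene_id)
  expect_equal(r$fold, 1.6, tolerance = 0.2)

  # fold 1: equal rates in expectation
  t1 <- simulate_tf_targets(g$annotation, hypo, cfg, fold = 1)
  r1 <- tf_target_enrichment(t1, hypo, g$annotation$gene_id)
  expect_equal(r1$fold, 1, tolerance = 0.2)

  # infeasible: would need target probability > 1
  cfg2 <- sim_config(n_genes = 100, chrom_length = 100 * 13000,
                     tf_base_rate = 0.3, seed = 1)
  g2 <- generate_genome(cfg2)
  expect_error(simulate_tf_targets(g2$annotation, g2$annotation$gene_id[1:30],
                                   cfg2, fold = 10),
               class = "dreamtdmr_parameter_error")
})

test_that("whole simulation is byte-identical under a fixed seed", {
  s1 <- suppressWarnings(simulate_dream(small_config(seed = 21)))
  s2 <- suppressWarnings(simulate_dream(small_config(seed = 21)))
  expect_identical(s1, s2)
  s3 <- suppressWarnings(simulate_dream(small_config(seed = 22)))
  expect_false(identical(s1$intensities, s3$intensities))
})
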