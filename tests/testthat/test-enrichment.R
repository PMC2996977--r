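# exact-test enrichment machinery

test_that("fisher_exact matches the worked table and degenerate cases", {
  expect_equal(fisher_exact(3, 4, 4, 8), 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(4, 8, 4, 8), 1)        # set = background
  expect_equal(fisher_exact(0, 4, 0, 8), 1)        # zero hits everywhere
  expect_error(fisher_exact(5, 4, 4, 8), class = "dreamtdmr_validation_error")
  expect_error(fisher_exact(2, 9, 4, 8), class = "dreamtdmr_validation_error")
})

test_that("fisher_exact agrees with full enumeration on random small tables", {
  set.seed(41)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    x <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    for (dir in c("over", "under"))
      expect_equal(fisher_exact(x, n, K, N, dir),
                   hyper_tail_oracle(x, n, K, N, dir), tolerance = 1e-10,
                   info = sprintf("x=%d n=%d K=%d N=%d %s", x, n, K, N, dir))
  }
})

test_that("p_value(over) is at least 0.5 when the set is not enriched", {
  set.seed(42)
  for (i in 1:30) {
    N <- sample(5:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    x <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (x / n <= K / N)
      expect_gte(fisher_exact(x, n, K, N, "over"), 0.5)
  }
})

test_that("fold enrichment satisfies the rational identity", {
  r <- enrichment_result(6, 10, 30, 100)
  expect_equal(r$fold, 2)
  # fold * background fraction = set fraction, exactly in integer arithmetic
  expect_identical(r$fold * (r$background_hits / r$background_size) *
                     r$set_size, r$set_hits * 1)
  expect_true(is.na(enrichment_result(0, 5, 0, 10)$fold))
})

test_that("category_enrichment tests over and under against nuclear mt background", {
  ann <- make_annotation(strand = "+",
                         tss = seq(10000L, by = 20000L, length.out = 8),
                         is_nuclear_mt = TRUE,
                         categories = c(rep("detox", 4), rep("ribo", 4)))
  # hypo set = genes 1..4 (all detox)
  fl <- data.table::CJ(gene_id = ann$gene_id, tissue = "liver")
  fl$has_tissue_hypo <- fl$gene_id %in% ann$gene_id[1:4]
  fl$has_upstream <- FALSE; fl$has_downstream <- fl$has_tissue_hypo
  gs <- structure(list(
    genes = data.table::data.table(gene_id = ann$gene_id,
                                   is_nuclear_mt = TRUE,
                                   has_tdmr = fl$has_tissue_hypo),
    tissue_flags = fl, stats = list()), class = "gene_summary")
  res <- category_enrichment(gs, ann, "liver")
  detox_over <- res[res$category == "detox" & res$direction == "over", ]
  expect_equal(detox_over$fold, 2)  # 4/4 vs 4/8
  expect_equal(detox_over$p_value, hyper_tail_oracle(4, 4, 4, 8),
               tolerance = 1e-10)
  ribo_under <- res[res$category == "ribo" & res$direction == "under", ]
  expect_equal(ribo_under$p_value, hyper_tail_oracle(0, 4, 4, 8, "under"),
               tolerance = 1e-10)
  # category covering all genes: fold 1, p 1
  ann2 <- data.table::copy(ann); ann2$categories <- "all"
  res2 <- category_enrichment(gs, ann2, "liver")
  expect_equal(res2$fold[res2$direction == "over"], 1)
  expect_equal(res2$p_value[res2$direction == "over"], 1)
  # absent category skipped with warning
  expect_warning(category_enrichment(gs, ann, "liver",
                                     categories = c("detox", "nope")),
                 "nope")
  # empty hypo set errors
  fl0 <- data.table::copy(fl); fl0$has_tissue_hypo <- FALSE
  gs0 <- gs; gs0$tissue_flags <- fl0
  expect_error(category_enrichment(gs0, ann, "liver"),
               class = "dreamtdmr_validation_error")
})

test_that("flag_target_genes honours the extended gene region and strand", {
  ann <- make_annotation(strand = c("+", "-"), tss = c(50000L, 150000L),
                         len = 5000L)
  # + gene: region [tss-10000, 3'end + 1000]; 3' end = 54999
  peak_at_tss <- data.table::data.table(chrom = "chrS", start = 50000L,
                                        end = 50001L)
  expect_equal(flag_target_genes(peak_at_tss, ann[1L, ]), "G001")
  just_out <- data.table::data.table(chrom = "chrS", start = 39999L,
                                     end = 40000L)  # 10001 bp upstream
  expect_equal(length(flag_target_genes(just_out, ann[1L, ])), 0L)
  at_bound <- data.table::data.table(chrom = "chrS", start = 40000L,
                                     end = 40001L)  # exactly 10 kb upstream
  expect_equal(flag_target_genes(at_bound, ann[1L, ]), "G001")
  past_3p <- data.table::data.table(chrom = "chrS", start = 56000L,
                                    end = 56001L)  # 1001 bp past 3' end
  expect_equal(length(flag_target_genes(past_3p, ann[1L, ])), 0L)

  # minus-strand mirror: reflect everything, flags must be preserved
  L <- 200000L
  peaks <- data.table::data.table(chrom = "chrS",
                                  start = c(45000L, 160000L, 120000L),
                                  end = c(45200L, 160200L, 120200L))
  fwd <- flag_target_genes(peaks, ann)
  ann_r <- make_annotation(strand = c("-", "+"), tss = L - c(50000L, 150000L),
                           len = 5000L)
  # exact half-open mirror: [s, e) maps to [L - e + 1, L - s + 1)
  peaks_r <- data.table::data.table(chrom = "chrS", start = L - peaks$end + 1L,
                                    end = L - peaks$start + 1L)
  expect_setequal(flag_target_genes(peaks_r, ann_r), fwd)

  # other chromosome never hits
  off_chrom <- data.table::data.table(chrom = "chr2", start = 50000L,
                                      end = 50001L)
  expect_equal(length(flag_target_genes(off_chrom, ann)), 0L)
})

test_that("tf_target_enrichment computes fold and guards its inputs", {
  bg <- sprintf("G%03d", 1:100)
  focal <- bg[1:20]
  targets <- c(bg[1:10], bg[21:40])  # 10/20 in focal, 30/100 overall
  r <- tf_target_enrichment(targets, focal, bg)
  expect_equal(r$fold, (10 / 20) / (30 / 100))
  expect_equal(r$p_value, phyper(9, 30, 70, 20, lower.tail = FALSE))
  expect_equal(tf_target_enrichment(targets, bg, bg)$fold, 1)
  # all targets inside the focal set: maximal fold = N / n
  r2 <- tf_target_enrichment(bg[1:20], focal, bg)
  expect_equal(r2$fold, 100 / 20)
  expect_error(tf_target_enrichment(targets, character(0), bg),
               class = "dreamtdmr_validation_error")
  expect_error(tf_target_enrichment(targets, "nope", bg),
               class = "dreamtdmr_validation_error")
})

test_that("downstream_fraction_test builds the 2x2 table and flips with tissues", {
  fl <- data.table::rbindlist(list(
    data.table::data.table(gene_id = sprintf("a%02d", 1:10), tissue = "liver",
                           has_tissue_hypo = TRUE, has_upstream = FALSE,
                           has_downstream = c(rep(TRUE, 8), FALSE, FALSE)),
    data.table::data.table(gene_id = sprintf("b%02d", 1:10), tissue = "brain",
                           has_tissue_hypo = TRUE, has_upstream = TRUE,
                           has_downstream = c(rep(TRUE, 2), rep(FALSE, 8)))))
  gs <- structure(list(
    genes = data.table::data.table(gene_id = c(fl$gene_id),
                                   is_nuclear_mt = TRUE, has_tdmr = TRUE),
    tissue_flags = fl, stats = list()), class = "gene_summary")
  r <- downstream_fraction_test(gs, "liver", "brain")
  expect_equal(r$set_hits, 8); expect_equal(r$set_size, 10)
  expect_equal(r$background_hits, 10); expect_equal(r$background_size, 20)
  r_rev <- downstream_fraction_test(gs, "brain", "liver")
  expect_lt(r$p_value, 0.05)
  expect_gt(r_rev$p_value, 0.5)
  # identical fractions: p >= 0.5
  fl2 <- data.table::copy(fl)
  fl2$has_downstream <- rep(c(TRUE, FALSE), 10)
  gs2 <- gs; gs2$tissue_flags <- fl2
  expect_gte(downstream_fraction_test(gs2, "liver", "brain")$p_value, 0.5)
  expect_error(downstream_fraction_test(gs, "liver", "heart"),
               class = "dreamtdmr_validation_error")
})

test_that("nuclear_mt_ratio reports both compositions", {
  genes <- data.table::data.table(gene_id = sprintf("G%03d", 1:10),
                                  is_nuclear_mt = c(rep(TRUE, 4),
                                                    rep(FALSE, 6)),
                                  has_tdmr = TRUE)
  fl <- data.table::data.table(gene_id = genes$gene_id, tissue = "liver",
                               has_tissue_hypo = genes$gene_id %in%
                                 sprintf("G%03d", 1:4),
                               has_upstream = FALSE, has_downstream = TRUE)
  gs <- structure(list(genes = genes, tissue_flags = fl, stats = list()),
                  class = "gene_summary")
  r <- nuclear_mt_ratio(gs, "liver", downstream_only = TRUE)
  expect_equal(r$all, 0.4)
  expect_equal(r$hypo, 1)  # only nuclear mt genes carry the planted sites
  fl0 <- data.table::copy(fl); fl0$has_tissue_hypo <- FALSE
  gs0 <- gs; gs0$tissue_flags <- fl0
  expect_error(nuclear_mt_ratio(gs0, "liver"),
               class = "dreamtdmr_validation_error")
})
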