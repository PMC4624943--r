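test_that("feature coverage reports hits and covered proportions", {
  anno <- tiny_annotation()   # gC: single 100 bp exon on chr2

  one <- tibble::tibble(chrom = "chr2", start = 40L, end = 50L)
  cov <- feature_clip_coverage(anno, one)
  gC_ex <- cov[cov$gene_id == "gC" & cov$feature_class == "exon", ]
  expect_equal(gC_ex$hit_count, 1L)
  expect_equal(gC_ex$covered_bases, 10L)
  expect_equal(gC_ex$proportion, 0.1)

  none <- feature_clip_coverage(anno, one[0, ])
  expect_true(all(none$hit_count == 0))
  expect_true(all(none$proportion == 0))

  two <- tibble::tibble(chrom = "chr2", start = c(0L, 10L), end = c(20L, 30L))
  cov2 <- feature_clip_coverage(anno, two)
  gC_ex2 <- cov2[cov2$gene_id == "gC" & cov2$feature_class == "exon", ]
  expect_equal(gC_ex2$hit_count, 2L)
  expect_equal(gC_ex2$covered_bases, 30L)   # union of [0,20) and [10,30)
  expect_equal(gC_ex2$proportion, 0.3)
  # both clusters also fall in gC's 5' UTR [0,20)
  gC_u5 <- cov2[cov2$gene_id == "gC" & cov2$feature_class == "utr5", ]
  expect_equal(gC_u5$hit_count, 2L)
  expect_equal(gC_u5$covered_bases, 20L)

  # a cluster spanning the first exon-intron boundary of gA hits both classes
  span <- tibble::tibble(chrom = "chr1", start = 190L, end = 210L)
  cov3 <- feature_clip_coverage(anno, span)
  expect_equal(
    cov3$covered_bases[cov3$gene_id == "gA" & cov3$feature_class == "exon"],
    10L)
  expect_equal(
    cov3$covered_bases[cov3$gene_id == "gA" & cov3$feature_class == "intron"],
    10L)
})

test_that("covered bases match the per-base oracle on generated data", {
  cfg <- small_config(seed = 31)
  anno <- build_toy_genome(cfg)
  sim <- simulate_clip_peaks(anno, anno$gene_id[1:20], 0.9, 0.3, seed = 5)
  cov <- feature_clip_coverage(anno, sim$peaks)
  introns <- introns_of(anno)
  feats_of <- function(gid, cls) {
    i <- match(gid, anno$gene_id)
    switch(cls,
           exon = anno$exons[[i]], utr5 = anno$utr5[[i]],
           utr3 = anno$utr3[[i]],
           intron = introns[introns$gene_id == gid, c("start", "end")])
  }
  check <- cov[anno$end[match(cov$gene_id, anno$gene_id)] -
                 anno$start[match(cov$gene_id, anno$gene_id)] <= 1000, ]
  check <- head(check[order(-check$hit_count), ], 40)
  for (r in seq_len(nrow(check))) {
    row <- check[r, ]
    fe <- feats_of(row$gene_id, row$feature_class)
    chrom <- anno$chrom[match(row$gene_id, anno$gene_id)]
    pk <- sim$peaks[sim$peaks$chrom == chrom, ]
    bases <- unlist(purrr::map2(fe$start, fe$end, ~ seq(.x, .y - 1)))
    covered <- vapply(bases, function(b) any(b >= pk$start & b < pk$end),
                      logical(1))
    expect_identical(row$covered_bases, as.integer(sum(covered)),
                     label = paste(row$gene_id, row$feature_class))
  }
})

test_that("splitting a cluster preserves the proportion but not hits", {
  anno <- tiny_annotation()
  whole <- tibble::tibble(chrom = "chr2", start = 10L, end = 40L)
  split2 <- tibble::tibble(chrom = "chr2", start = c(10L, 25L),
                           end = c(25L, 40L))
  cw <- feature_clip_coverage(anno, whole)
  cs <- feature_clip_coverage(anno, split2)
  ex <- function(x) x[x$gene_id == "gC" & x$feature_class == "exon", ]
  expect_equal(ex(cw)$proportion, ex(cs)$proportion)
  expect_equal(ex(cw)$hit_count, 1L)
  expect_equal(ex(cs)$hit_count, 2L)
})

test_that("binding flags mirror the generator's ground truth", {
  anno <- tiny_annotation()
  utr3_only <- tibble::tibble(chrom = "chr2", start = c(85L, 90L),
                              end = c(88L, 95L))
  cov <- feature_clip_coverage(anno, utr3_only)
  expect_true(binding_flag(cov, "gC"))     # hits confined to the 3' UTR
  expect_false(binding_flag(cov, "gA"))
  expect_error(binding_flag(cov, "nope"), "unknown gene")

  cfg <- small_config(seed = 17)
  toy <- build_toy_genome(cfg)
  enr <- toy$gene_id[toy$class_label == "unchanging_candidate"][1:30]
  sim <- simulate_clip_peaks(toy, enr, 1, 0, seed = 2)
  flags <- bound_genes(feature_clip_coverage(toy, sim$peaks))
  truth <- sim$truth[match(flags$gene_id, sim$truth$gene_id), ]
  expect_identical(flags$bound, truth$bound)
})

test_that("enrichment matches the cross-product OR and hypergeometric tail", {
  mk_flags <- function(set_bound, set_n, rest_bound, rest_n) {
    tibble::tibble(
      gene_id = c(sprintf("s%03d", seq_len(set_n)),
                  sprintf("r%03d", seq_len(rest_n))),
      bound = c(seq_len(set_n) <= set_bound, seq_len(rest_n) <= rest_bound)
    )
  }
  flags <- mk_flags(10, 20, 10, 80)   # table [10,10;10,70]
  gene_set <- sprintf("s%03d", 1:20)
  bg <- flags$gene_id
  res <- binding_enrichment(gene_set, bg, flags)
  expect_equal(res$odds_ratio, 7)
  expect_equal(res$p_value, fisher_oracle(10, 10, 10, 70), tolerance = 1e-9)

  flat <- mk_flags(5, 20, 20, 80)     # equal 25% binding in set and rest
  res2 <- binding_enrichment(sprintf("s%03d", 1:20), flat$gene_id, flat)
  expect_equal(res2$odds_ratio, 1)
  expect_gte(res2$p_value, 0.5)

  withr::with_seed(77, {
    for (i in 1:25) {
      a <- sample(0:12, 1); b <- sample(0:12, 1)
      c_ <- sample(0:30, 1); d <- sample(0:30, 1)
      if (a + b == 0 || c_ + d == 0) next
      fl <- mk_flags(a, a + b, c_, c_ + d)
      r <- binding_enrichment(sprintf("s%03d", seq_len(a + b)), fl$gene_id, fl)
      expect_equal(r$p_value, fisher_oracle(a, b, c_, d), tolerance = 1e-9)
    }
  })
  expect_error(binding_enrichment(bg, bg, flags), "complement")
  expect_error(binding_enrichment(c("zzz"), bg, flags), "subset")
})

test_that("the enrichment test has power at realistic effect sizes", {
  withr::with_seed(4242, {
    rejections <- vapply(1:50, function(i) {
      flags <- tibble::tibble(
        gene_id = sprintf("g%04d", 1:1000),
        bound = c(stats::rbinom(500, 1, 0.8), stats::rbinom(500, 1, 0.2)) == 1
      )
      binding_enrichment(sprintf("g%04d", 1:500), flags$gene_id,
                         flags)$p_value < 0.05
    }, logical(1))
    expect_equal(mean(rejections), 1)
  })
})
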