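test_that("toy genome honours configured gene counts and structure", {
  cfg <- sim_config(seed = 11)
  anno <- build_toy_genome(cfg)
  tab <- table(anno$class_label)
  expect_equal(unname(tab[["canonical_histone"]]), 34)
  expect_equal(unname(tab[["variant_histone"]]), 15)
  expect_equal(unname(tab[["unchanging_candidate"]]), 200)
  expect_equal(unname(tab[["other"]]), 100)

  # family copies share identical exon lengths
  fams <- split(seq_len(nrow(anno)), anno$family)
  fams <- fams[lengths(fams) > 1]
  expect_gt(length(fams), 0)
  for (members in fams) {
    lens <- lapply(anno$exons[members], function(e) e$end - e$start)
    expect_true(all(vapply(lens, identical, TRUE, y = lens[[1]])))
  }
  # every class has at least one multi-exon gene with both UTRs
  for (cls in unique(anno$class_label)) {
    sub <- anno[anno$class_label == cls, ]
    multi <- vapply(sub$exons, nrow, 1L) > 1 &
      vapply(sub$utr5, nrow, 1L) > 0 & vapply(sub$utr3, nrow, 1L) > 0
    expect_true(any(multi), label = paste("multi-exon gene in", cls))
  }
  expect_error(sim_config(n_canonical = 0), "n_canonical")
})

test_that("generation is a pure function of the config seed", {
  cfg <- small_config(seed = 5)
  a1 <- build_toy_genome(cfg)
  a2 <- build_toy_genome(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_annotation(a1, p1); write_annotation(a2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(
    build_toy_genome(small_config(seed = 6))$base_mean, a1$base_mean))

  r1 <- simulate_alignments(a1, cfg, "case", 2)
  r2 <- simulate_alignments(a1, cfg, "case", 2)
  expect_identical(r1, r2)
  expect_false(identical(r1, simulate_alignments(a1, cfg, "case", 3)))
})

test_that("multimapping structure mirrors the family layout", {
  cfg <- small_config(seed = 2)
  anno <- build_toy_genome(cfg)
  aln <- simulate_alignments(anno, cfg, "control", 1)
  # weights of one read sum to exactly 1
  per_read <- tapply(1 / aln$n_mappings, aln$read_id, sum)
  expect_true(all(abs(per_read - 1) < 1e-12))
  # family reads appear once per copy, with n_mappings = family size
  fam_sizes <- table(anno$family[!is.na(anno$family)])
  expect_true(all(fam_sizes == 2))
  fam_reads <- aln[aln$n_mappings == 2, ]
  expect_equal(unname(table(table(fam_reads$read_id))[["2"]]),
               length(unique(fam_reads$read_id)))

  # degenerate repetition: single-copy families imply no multimapping
  cfg1 <- small_config(seed = 2, canonical_copies = 1)
  anno1 <- build_toy_genome(cfg1)
  aln1 <- simulate_alignments(anno1, cfg1, "case", 1)
  expect_true(all(aln1$n_mappings == 1))
})

test_that("counts follow the configured negative-binomial means", {
  # near-zero dispersion: control counts of an unchanging gene are Poisson
  cfg <- sim_config(n_canonical = 1, canonical_copies = 1, n_variant = 1,
                    n_unchanging = 4, n_de = 0, baseline_mean = 100,
                    baseline_sdlog = 0, dispersion = 1e-6, seed = 9)
  anno <- build_toy_genome(cfg)
  gid <- anno$gene_id[anno$class_label == "unchanging_candidate"][1]
  counts <- vapply(1:120, function(s) {
    aln <- simulate_alignments(anno, cfg, "control", 1, seed = s)
    sum(grepl(paste0("_", gid, "_"), aln$read_id))
  }, numeric(1))
  # mean of 120 Poisson(100) draws: se = sqrt(100/120) ~ 0.91
  expect_lt(abs(mean(counts) - 100), 4 * sqrt(100 / 120))

  # fc = 1 genes: case and control means agree within sampling error
  case_counts <- vapply(1:60, function(s) {
    aln <- simulate_alignments(anno, cfg, "case", 1, seed = s)
    sum(grepl(paste0("_", gid, "_"), aln$read_id))
  }, numeric(1))
  se <- sqrt(100 / 60 + 100 / 120)
  expect_lt(abs(mean(case_counts) - mean(counts)), 4 * se)
})

test_that("clip peak simulation respects enrichment probabilities", {
  cfg <- sim_config(n_unchanging = 200, n_de = 0, n_variant = 1,
                    canonical_copies = 1, n_canonical = 1, seed = 4)
  anno <- build_toy_genome(cfg)
  pool <- anno$gene_id[anno$class_label == "unchanging_candidate"]
  enr <- pool[1:100]; bg <- pool[101:200]

  empty <- simulate_clip_peaks(anno, enr, 0, 0, seed = 1)
  expect_equal(nrow(empty$peaks), 0)
  expect_false(any(empty$truth$bound))

  exact <- simulate_clip_peaks(anno, enr, 1, 0, seed = 1)
  bound <- exact$truth$gene_id[exact$truth$bound]
  expect_setequal(bound, enr)
  # peaks fall inside their host gene
  gene_of <- sub("^peak_(.*)_\\d+$", "\\1", exact$peaks$name)
  spans <- tibble::as_tibble(anno)[match(gene_of, anno$gene_id), ]
  expect_true(all(exact$peaks$start >= spans$start &
                    exact$peaks$end <= spans$end))

  probs <- simulate_clip_peaks(anno, enr, 0.8, 0.2, seed = 12)
  tr <- probs$truth[probs$truth$gene_id %in% pool, ]
  p_enr <- mean(tr$bound[tr$gene_id %in% enr])
  p_bg <- mean(tr$bound[tr$gene_id %in% bg])
  expect_lt(abs(p_enr - 0.8), 4 * sqrt(0.8 * 0.2 / 100))
  expect_lt(abs(p_bg - 0.2), 4 * sqrt(0.2 * 0.8 / 100))
  expect_error(simulate_clip_peaks(anno, enr, 0.2, 0.8, seed = 1),
               "p_background")
})

test_that("ct table encodes ratios on the Ct scale", {
  cfg <- sim_config(n_case = 2, n_control = 2, seed = 3)
  ratios <- tibble::tibble(gene = c("tg1", "tg2"), ratio = c(1, 2))
  ct <- simulate_ct_table(cfg, ratios, hk_ct = c(Gapdh = 18, Actb = 22),
                          noise_sd = 0)
  hk_mean <- 20
  case1 <- ct[ct$sample_id == "case_1", ]
  expect_equal(case1$ct[case1$gene == "tg1"], hk_mean)
  expect_equal(case1$ct[case1$gene == "tg2"], hk_mean - 1)
  ctrl1 <- ct[ct$sample_id == "control_1", ]
  expect_equal(ctrl1$ct[ctrl1$gene == "tg2"], hk_mean)  # control ratio 1

  # noisy ratios recovered without bias across repeated draws
  est <- vapply(1:100, function(s) {
    tab <- simulate_ct_table(cfg, ratios, noise_sd = 0.2, seed = s)
    rel <- relative_expression(tab, "tg2", priming = "random_hexamer")
    mean(rel$relative_expression[rel$group == "case"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 0.1)
})
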