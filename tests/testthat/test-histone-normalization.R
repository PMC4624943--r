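test_that("geometric mean is exact and guarded", {
  expect_equal(geometric_mean(c(1, 1, 1)), 1)
  expect_equal(geometric_mean(c(2, 8)), 4)
  withr::with_seed(21, {
    for (i in 1:5) {
      x <- stats::runif(sample(2:64, 1), 0.5, 5)
      expect_equal(geometric_mean(x), prod(x)^(1 / length(x)),
                   tolerance = 1e-9)
    }
  })
  expect_error(geometric_mean(c(1, 0, 2)), "> 0")
  expect_error(geometric_mean(numeric()), "empty")
})

test_that("unchanging-gene selection is seeded and validated", {
  n_genes <- 500
  de <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n_genes),
    adj_p_value = c(rep(0.9, 300), rep(0.1, 200))
  )
  counts <- tidyr::crossing(sample_id = c("a", "b"), gene_id = de$gene_id) |>
    dplyr::mutate(count = 5)
  s1 <- select_unchanging_genes(de, counts, n = 50, seed = 42)
  s2 <- select_unchanging_genes(de, counts, n = 50, seed = 42)
  s3 <- select_unchanging_genes(de, counts, n = 50, seed = 43)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_length(s1, 50)
  expect_true(all(s1 %in% de$gene_id[de$adj_p_value > 0.5]))

  # genes with a zero in any sample are ineligible
  counts0 <- dplyr::mutate(
    counts, count = ifelse(gene_id == "g001" & sample_id == "a", 0, count))
  expect_false("g001" %in%
                 select_unchanging_genes(de, counts0, n = 50, seed = 1))

  # exactly n eligible: returned in full, seed-independent
  de50 <- dplyr::mutate(de, adj_p_value = c(rep(0.9, 50), rep(0.1, 450)))
  expect_identical(select_unchanging_genes(de50, counts, n = 50, seed = 1),
                   select_unchanging_genes(de50, counts, n = 50, seed = 99))
  de49 <- dplyr::mutate(de, adj_p_value = c(rep(0.9, 49), rep(0.1, 451)))
  expect_error(select_unchanging_genes(de49, counts, n = 50, seed = 1),
               "49 eligible")
  expect_error(select_unchanging_genes(de, counts, n = 50), "seed")
})

test_that("normalization factors are anchored to the control mean", {
  # one reference gene: per-sample geometric mean equals the count
  counts <- tibble::tibble(
    sample_id = c("ctrl1", "ctrl2", "case1"),
    gene_id = "u", count = c(2, 4, 6)
  )
  nf <- normalization_factors(counts, c("ctrl1", "ctrl2"))
  expect_equal(nf$factor[match(c("ctrl1", "ctrl2", "case1"), nf$sample_id)],
               c(2 / 3, 4 / 3, 2))

  same <- tibble::tibble(sample_id = rep(c("a", "b", "c"), each = 2),
                         gene_id = rep(c("u1", "u2"), 3), count = 7)
  expect_true(all(normalization_factors(same, c("a", "b"))$factor == 1))

  withr::with_seed(99, {
    for (i in 1:20) {
      m <- matrix(stats::rlnorm(60, 3, 1), nrow = 10,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
      ctrl <- sample(colnames(m), 3)
      nf <- normalization_factors(counts_from_matrix(m), ctrl)
      expect_equal(mean(nf$factor[nf$sample_id %in% ctrl]), 1,
                   tolerance = 1e-12)
    }
  })
  expect_error(normalization_factors(same, character()), "non-empty")
})

test_that("the floor touches exact zeros only, before division", {
  counts <- tibble::tibble(sample_id = "s", gene_id = c("a", "b", "c"),
                           count = c(0, 0.05, 7.3))
  floored <- floor_zeros(counts)
  expect_equal(floored$count, c(0.1, 0.05, 7.3))
  expect_error(floor_zeros(dplyr::mutate(counts, count = -1)), "negative")
  expect_error(floor_zeros(counts, floor = 0), "floor")

  nf <- tibble::tibble(sample_id = "s", geomean = 2, factor = 2)
  norm <- normalize_histone_counts(floored, nf)
  expect_equal(norm$count, c(0.1 / 2, 0.05 / 2, 7.3 / 2))
})

test_that("gene-set summaries match hand-worked fold changes and Welch p", {
  mk_counts <- function(case_vals, ctrl_vals) {
    tibble::tibble(
      sample_id = c(paste0("case", seq_along(case_vals)),
                    paste0("ctrl", seq_along(ctrl_vals))),
      gene_id = "h", count = c(case_vals, ctrl_vals)
    )
  }
  case_ids <- paste0("case", 1:4); ctrl_ids <- paste0("ctrl", 1:4)

  doubled <- geneset_summary(mk_counts(c(4, 4, 4, 4), c(2, 2, 2, 2)), "h",
                             case_ids, ctrl_ids) |> suppressWarnings()
  expect_equal(doubled$fold_change, 2)

  equal <- suppressWarnings(
    geneset_summary(mk_counts(c(3, 3, 3, 3), c(3, 3, 3, 3)), "h",
                    case_ids, ctrl_ids))
  expect_equal(equal$fold_change, 1)
  expect_equal(equal$p_value, 1)
  expect_warning(
    geneset_summary(mk_counts(c(3, 3, 3, 3), c(3, 3, 3, 3)), "h",
                    case_ids, ctrl_ids), "constant")

  x <- c(8.1, 9.4, 7.7, 8.9); y <- c(4.2, 5.1, 3.9, 4.6)
  fit <- geneset_summary(mk_counts(x, y), "h", case_ids, ctrl_ids)
  expect_equal(fit$fold_change, mean(x) / mean(y), tolerance = 1e-12)
  expect_equal(fit$p_value, welch_oracle(x, y), tolerance = 1e-9)

  # geometric-mean fold change and Student flavor behind flags
  fitg <- geneset_summary(mk_counts(x, y), "h", case_ids, ctrl_ids,
                          fold_change = "geometric", var_equal = TRUE)
  expect_equal(fitg$fold_change, geometric_mean(x) / geometric_mean(y))
  expect_equal(fitg$p_value,
               stats::t.test(x, y, var.equal = TRUE)$p.value)

  expect_error(geneset_summary(mk_counts(x, y), "h", case_ids[1], ctrl_ids),
               "2 samples")
  expect_error(geneset_summary(mk_counts(x, y), character(), case_ids,
                               ctrl_ids), "non-empty")

  gl <- glance(fit)
  expect_equal(gl$fold_change, fit$fold_change)
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the procedure is invariant to a common count rescaling", {
  withr::with_seed(7, {
    m <- matrix(stats::rlnorm(12 * 8, 4, 0.6), nrow = 12,
                dimnames = list(paste0("g", 1:12), paste0("s", 1:8)))
  })
  groups <- stats::setNames(rep(c("case", "control"), each = 4),
                            paste0("s", 1:8))
  run <- function(m) {
    counts <- counts_from_matrix(m)
    refs <- paste0("g", 1:6); hist <- paste0("g", 7:12)
    nf <- normalization_factors(
      dplyr::filter(counts, gene_id %in% refs), paste0("s", 5:8))
    norm <- normalize_histone_counts(
      floor_zeros(dplyr::filter(counts, gene_id %in% hist)), nf)
    geneset_summary(norm, hist, paste0("s", 1:4), paste0("s", 5:8))
  }
  base <- run(m)
  scaled <- run(m * 3.7)
  expect_equal(scaled$fold_change, base$fold_change, tolerance = 1e-12)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-12)
  # normalized values scale with the counts (factors are dimensionless);
  # everything downstream of the ratio is unchanged
  expect_equal(scaled$samples$geomean, 3.7 * base$samples$geomean,
               tolerance = 1e-12)
})
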