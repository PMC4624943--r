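#' Run the histone quantification pipeline on one synthetic experiment
#'
#' End-to-end single-seed run of the core procedure: build the toy genome,
#' simulate and quantify all samples with multimapping-weighted counting,
#' filter by expression, derive a lightweight DE table, select the random
#' unchanging reference genes, compute control-anchored geometric-mean
#' normalization factors, floor and normalize the histone counts, and
#' summarise the canonical and variant gene sets with fold changes and
#' two-sided t-tests.
#'
#' @param config A [sim_config()] (default: the packaged Scenario S1).
#' @param seed Master seed for this run (defaults to `config$seed`).
#' @param cap Multimapping cap (default 10).
#' @param n_unchanging Number of random reference genes (default 50).
#' @param min_adj_p Unchanging-gene eligibility threshold (default 0.5).
#' @param rpm_threshold Expression filter threshold (default 10).
#' @param floor Zero-coverage floor (default 0.1).
#'
#' @return A list of class `histone_pipeline` with elements `annotation`,
#'   `counts` (weighted, long), `expressed`, `de`, `unchanging`, `factors`,
#'   `normalized` (floored + normalized histone counts), `canonical` and
#'   `variant` ([geneset_summary()] objects), `config`, `seed`, `params`.
#'   [glance()] gives a two-row fold-change summary, [tidy()] the
#'   per-sample set geometric means, [autoplot()] a two-panel dot plot.
#' @export
run_histone_pipeline <- function(config = scenario_s1(), seed = config$seed,
                                 cap = 10, n_unchanging = 50,
                                 min_adj_p = 0.5, rpm_threshold = 10,
                                 floor = 0.1) {
  annotation <- build_toy_genome(replace_seed(config, seed))
  counts <- quantify_experiment(annotation, config, seed = seed, cap = cap)
  case_ids <- unique(counts$sample_id[counts$group == "case"])
  control_ids <- unique(counts$sample_id[counts$group == "control"])

  expressed <- rpm_filter(counts, threshold = rpm_threshold)
  # median-of-ratios scaling: unchanging-gene eligibility needs effect
  # estimates that are not composition-shifted by the histone upregulation
  de <- de_lite(counts[counts$gene_id %in% expressed, ],
                case_ids, control_ids, normalization = "median_ratio")
  unchanging <- select_unchanging_genes(
    de, counts, n = n_unchanging, min_adj_p = min_adj_p,
    seed = derive_seed(seed, seed_streams$unchanging)
  )
  factors <- normalization_factors(
    counts[counts$gene_id %in% unchanging, ], control_ids
  )

  hist_ids <- annotation$gene_id[
    annotation$class_label %in% c("canonical_histone", "variant_histone")]
  normalized <- normalize_histone_counts(
    floor_zeros(counts[counts$gene_id %in% hist_ids, ], floor = floor),
    factors
  )
  canonical_ids <- annotation$gene_id[
    annotation$class_label == "canonical_histone"]
  variant_ids <- annotation$gene_id[
    annotation$class_label == "variant_histone"]
  canonical <- geneset_summary(normalized, canonical_ids, case_ids,
                               control_ids, set_name = "canonical")
  variant <- geneset_summary(normalized, variant_ids, case_ids,
                             control_ids, set_name = "variant")

  structure(
    list(annotation = annotation, counts = counts, expressed = expressed,
         de = de, unchanging = unchanging, factors = factors,
         normalized = normalized, canonical = canonical, variant = variant,
         config = config, seed = as.integer(seed),
         params = list(cap = cap, n_unchanging = n_unchanging,
                       min_adj_p = min_adj_p, rpm_threshold = rpm_threshold,
                       floor = floor)),
    class = "histone_pipeline"
  )
}

replace_seed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' @export
print.histone_pipeline <- function(x, ...) {
  cat(sprintf(
    "<histone_pipeline: seed %d>\n  %d genes, %d samples, cap %d, %d unchanging refs\n  canonical fold change %.3f (p = %.3g)\n  variant   fold change %.3f (p = %.3g)\n",
    x$seed, nrow(x$annotation), dplyr::n_distinct(x$counts$sample_id),
    x$params$cap, length(x$unchanging),
    x$canonical$fold_change, x$canonical$p_value,
    x$variant$fold_change, x$variant$p_value
  ))
  invisible(x)
}

#' @export
glance.histone_pipeline <- function(x, ...) {
  dplyr::bind_rows(glance(x$canonical), glance(x$variant)) |>
    dplyr::mutate(seed = x$seed, .before = 1)
}

#' @export
tidy.histone_pipeline <- function(x, ...) {
  dplyr::bind_rows(tidy(x$canonical), tidy(x$variant)) |>
    dplyr::mutate(seed = x$seed, .before = 1)
}

#' @export
autoplot.histone_pipeline <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$geomean)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~set_name, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-sample geometric mean (normalized)") +
    ggplot2::theme_minimal()
}

#' Multi-seed fold-change recovery
#'
#' Runs [run_histone_pipeline()] once per master seed and collects the
#' canonical and variant gene-set estimates, the basis for parameter-
#' recovery checks of the whole procedure.
#'
#' @param config A [sim_config()].
#' @param seeds Integer vector of master seeds (>= 20 recommended).
#' @param ... Passed to [run_histone_pipeline()].
#'
#' @return A tibble with one row per seed: `seed`, `canonical_fc`,
#'   `canonical_p`, `variant_fc`, `variant_p`.
#' @export
estimate_histone_foldchanges <- function(config = scenario_s1(), seeds,
                                         ...) {
  purrr::map_dfr(seeds, function(s) {
    fit <- run_histone_pipeline(config, seed = s, ...)
    tibble(seed = as.integer(s),
           canonical_fc = fit$canonical$fold_change,
           canonical_p = fit$canonical$p_value,
           variant_fc = fit$variant$fold_change,
           variant_p = fit$variant$p_value)
  })
}

output_header <- function(config, seed) {
  c(paste0("# histoquant ",
           as.character(utils::packageVersion("histoquant"))),
    paste0("# config_hash: ", rlang::hash(config)),
    paste0("# seed: ", seed))
}

write_report_tsv <- function(df, path, config, seed) {
  writeLines(output_header(config, seed), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the full synthetic scenario and write all reports
#'
#' Orchestrates every stage on one configuration and seed: the histone
#' pipeline (counts, normalization report, canonical/variant summaries), a
#' CLIP simulation with per-feature coverage and binding enrichment of the
#' other-DE gene set, a second independently simulated experiment compared
#' against the first (log2FC correlation and significance-overlap
#' categories), and a qPCR polyadenylation readout of the first canonical
#' histone. When `out_dir` is given, every table is written as TSV with a
#' header comment carrying the tool version, config hash and seed, plus a
#' machine-readable `summary.json`; identical config and seed produce
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param out_dir Optional output directory (created if needed).
#'
#' @return A list of class `scenario_run` with elements `pipeline`, `clip`
#'   (list: `coverage`, `enrichment`, `truth`), `comparison` (list:
#'   `correlation`, `overlap`), `qpcr` (tibble of per-sample
#'   polyadenylation ratios), `summary` (the JSON-ready list).
#' @export
run_scenario <- function(config = scenario_s1(), seed = config$seed,
                         out_dir = NULL) {
  fit <- run_histone_pipeline(config, seed = seed)
  annotation <- fit$annotation

  # CLIP: the "other" DE genes stand in for the regulatory target set
  target_set <- annotation$gene_id[annotation$class_label == "other" &
                                     annotation$true_fc != 1]
  clip_sim <- simulate_clip_peaks(
    annotation, target_set,
    p_enriched = config$clip_p_enriched,
    p_background = config$clip_p_background,
    seed = derive_seed(seed, seed_streams$clip)
  )
  coverage <- feature_clip_coverage(annotation, clip_sim$peaks)
  flags <- bound_genes(coverage)
  enrichment <- binding_enrichment(target_set, annotation$gene_id, flags)

  # a replicate experiment with independent noise for concordance analysis
  seed_b <- derive_seed(seed, seed_streams$experiment_b)
  counts_b <- quantify_experiment(annotation, config, seed = seed_b,
                                  cap = fit$params$cap)
  case_ids <- unique(counts_b$sample_id[counts_b$group == "case"])
  control_ids <- unique(counts_b$sample_id[counts_b$group == "control"])
  expressed_b <- rpm_filter(counts_b, threshold = fit$params$rpm_threshold)
  de_b <- de_lite(counts_b[counts_b$gene_id %in% expressed_b, ],
                  case_ids, control_ids)
  res_a <- experiment_result("experiment_a", fit$de, fit$expressed)
  res_b <- experiment_result("experiment_b", de_b, expressed_b)
  correlation <- match_and_correlate(res_a, res_b)
  overlap <- overlap_counts(res_a, res_b)

  # qPCR: polyadenylation readout of the first canonical histone
  target <- annotation$gene_id[annotation$class_label == "canonical_histone"][1]
  ratios <- dplyr::bind_rows(
    tibble(gene = target, group = "case", priming = "oligo_dT",
           ratio = config$fc_canonical),
    tibble(gene = target, group = "control", priming = "oligo_dT", ratio = 1),
    tibble(gene = target, group = "case", priming = "random_hexamer",
           ratio = 1),
    tibble(gene = target, group = "control", priming = "random_hexamer",
           ratio = 1)
  )
  ct <- simulate_ct_table(config, ratios, seed = seed)
  qpcr <- polyadenylation_ratio(ct, target)

  summary <- list(
    seed = as.integer(seed),
    config_hash = rlang::hash(config),
    canonical = list(fold_change = fit$canonical$fold_change,
                     p_value = fit$canonical$p_value),
    variant = list(fold_change = fit$variant$fold_change,
                   p_value = fit$variant$p_value),
    n_expressed = length(fit$expressed),
    n_unchanging = length(fit$unchanging),
    clip_enrichment = list(odds_ratio = enrichment$odds_ratio,
                           p_value = enrichment$p_value),
    comparison = list(n_common = correlation$n_common,
                      pearson_r = correlation$pearson_r),
    qpcr_mean_case_ratio = mean(qpcr$ratio[qpcr$group == "case"])
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      write_report_tsv(df, file.path(out_dir, name), config, seed)
    }
    w(fit$counts, "counts.tsv")
    w(fit$factors, "normalization_factors.tsv")
    w(dplyr::bind_rows(glance(fit$canonical), glance(fit$variant)),
      "geneset_summary.tsv")
    w(tibble(gene_id = fit$unchanging), "unchanging_genes.tsv")
    w(fit$de, "de_table.tsv")
    w(coverage, "clip_coverage.tsv")
    w(enrichment, "clip_enrichment.tsv")
    w(correlation, "comparison_correlation.tsv")
    w(overlap, "comparison_overlap.tsv")
    w(qpcr, "qpcr_polyA_ratio.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(pipeline = fit,
         clip = list(coverage = coverage, enrichment = enrichment,
                     truth = clip_sim$truth),
         comparison = list(correlation = correlation, overlap = overlap),
         qpcr = qpcr, summary = summary),
    class = "scenario_run"
  )
}

#' @export
print.scenario_run <- function(x, ...) {
  print(x$pipeline)
  cat(sprintf(
    "  CLIP enrichment OR %.3g (p = %.3g); replicate concordance r = %.3f over %d genes\n",
    x$clip$enrichment$odds_ratio, x$clip$enrichment$p_value,
    x$comparison$correlation$pearson_r, x$comparison$correlation$n_common
  ))
  invisible(x)
}
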