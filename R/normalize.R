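#' Geometric mean of positive values
#'
#' Computed in the log domain (`exp(mean(log(x)))`) so that long vectors of
#' large counts cannot overflow the intermediate product. Values must be
#' strictly positive; callers dealing with zero coverage are expected to
#' apply [floor_zeros()] first.
#'
#' @param values Numeric vector of positive values.
#' @return A positive scalar.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0) abort("geometric_mean of an empty vector")
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("geometric_mean requires finite values > 0; floor zeros first")
  }
  exp(mean(log(values)))
}

#' Select random unchanging reference genes
#'
#' Reference genes are defined as "unchanging": adjusted differential-
#' expression p-value above `min_adj_p` (0.5 by default), and strictly
#' positive counts in every sample (a geometric mean of zero is
#' undefined). Exactly `n` eligible genes are sampled uniformly without
#' replacement under the given seed, making the random choice
#' reproducible.
#'
#' @param de A DE result tibble with columns `gene_id` and `adj_p_value`.
#' @param counts Long count tibble (`sample_id`, `gene_id`, `count`)
#'   sharing the DE table's gene universe.
#' @param n Number of reference genes to draw (default 50).
#' @param min_adj_p Eligibility threshold on the adjusted p-value.
#' @param seed Integer seed; required so the draw is reproducible.
#'
#' @return Sorted character vector of `n` gene ids.
#' @export
select_unchanging_genes <- function(de, counts, n = 50, min_adj_p = 0.5,
                                    seed) {
  if (missing(seed)) abort("a selection seed is required for reproducibility")
  pos <- dplyr::summarise(dplyr::group_by(counts, .data$gene_id),
                          all_pos = all(.data$count > 0), .groups = "drop")
  eligible <- de$gene_id[de$adj_p_value > min_adj_p &
                           de$gene_id %in% pos$gene_id[pos$all_pos]]
  eligible <- sort(unique(eligible))
  if (length(eligible) < n) {
    abort(paste0("only ", length(eligible), " eligible unchanging genes; ",
                 n, " requested"))
  }
  if (length(eligible) == n) return(eligible)
  withr::with_seed(as.integer(seed), sort(sample(eligible, n)))
}

#' Control-anchored normalization factors
#'
#' For each sample, the factor is the geometric mean of the unchanging-gene
#' counts divided by the mean of the control samples' geometric means, so
#' the control factors average exactly 1 and normalized values are on the
#' control scale.
#'
#' @param counts Long count tibble restricted to the unchanging genes; all
#'   entries must be positive.
#' @param control_ids Character vector of control `sample_id`s.
#'
#' @return A tibble with `sample_id`, `geomean`, `factor`, and attribute
#'   `control_ids`.
#' @export
normalization_factors <- function(counts, control_ids) {
  if (length(control_ids) == 0) abort("control_ids must be non-empty")
  missing_ctrl <- setdiff(control_ids, unique(counts$sample_id))
  if (length(missing_ctrl) > 0) {
    abort(paste0("control samples absent from counts: ",
                 paste(missing_ctrl, collapse = ", ")))
  }
  gm <- dplyr::summarise(dplyr::group_by(counts, .data$sample_id),
                         geomean = geometric_mean(.data$count),
                         .groups = "drop")
  anchor <- mean(gm$geomean[gm$sample_id %in% control_ids])
  out <- dplyr::mutate(gm, factor = .data$geomean / anchor)
  attr(out, "control_ids") <- control_ids
  out
}

#' Floor zero coverage
#'
#' Entries that are exactly zero ("no coverage") are replaced by the floor
#' (0.1 by default, the lowest observable coverage); positive entries below
#' the floor are deliberately left untouched.
#'
#' @param counts Long count tibble with a `count` column.
#' @param floor Positive replacement value for exact zeros.
#'
#' @return The tibble with zeros floored.
#' @export
floor_zeros <- function(counts, floor = 0.1) {
  if (floor <= 0) abort("floor must be > 0")
  if (any(counts$count < 0)) abort("negative counts are invalid")
  dplyr::mutate(counts, count = ifelse(.data$count == 0, floor, .data$count))
}

#' Apply normalization factors to histone counts
#'
#' Divides each sample's (already floored) counts by its normalization
#' factor. The order of operations is fixed: floor first, then divide, so a
#' zero entry becomes `floor / factor`, not `floor`.
#'
#' @param counts Long count tibble (`sample_id`, `gene_id`, `count`),
#'   floored via [floor_zeros()].
#' @param factors Output of [normalization_factors()].
#'
#' @return The tibble with `count` replaced by normalized values.
#' @export
normalize_histone_counts <- function(counts, factors) {
  if (any(factors$factor <= 0)) abort("normalization factors must be > 0")
  missing_s <- setdiff(unique(counts$sample_id), factors$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("no factor for sample(s): ",
                 paste(missing_s, collapse = ", ")))
  }
  joined <- dplyr::left_join(
    counts, dplyr::select(factors, "sample_id", "factor"), by = "sample_id"
  )
  dplyr::select(
    dplyr::mutate(joined, count = .data$count / .data$factor), -"factor"
  )
}

#' Gene-set summary: per-sample geometric means, fold change, t-test
#'
#' Collapses a gene set (e.g. all canonical histones) to one geometric mean
#' per sample, then compares the expressing and control groups: the fold
#' change is the ratio of the group means of those per-sample geometric
#' means (arithmetic means by default, geometric behind a flag) and the
#' p-value comes from a two-sided two-sample t-test on the same per-sample
#' values (Welch by default, equal-variance behind a flag).
#'
#' @param counts Normalized long count tibble (`sample_id`, `gene_id`,
#'   `count`), all values positive.
#' @param gene_set Non-empty character vector of gene ids.
#' @param case_ids,control_ids Sample ids of the two groups (at least 2
#'   each; the t-test is undefined otherwise).
#' @param set_name Label stored in the result (e.g. `"canonical"`).
#' @param fold_change `"arithmetic"` (ratio of group arithmetic means of
#'   the per-sample geometric means) or `"geometric"`.
#' @param var_equal Use the pooled-variance Student t-test instead of
#'   Welch.
#'
#' @return An object of class `geneset_summary` with fields `set_name`,
#'   `gene_ids`, `samples` (tibble: `sample_id`, `group`, `geomean`),
#'   `fold_change`, `p_value`, `method`. [tidy()] returns the per-sample
#'   tibble, [glance()] a one-row summary, [autoplot()] a dot plot.
#' @export
geneset_summary <- function(counts, gene_set, case_ids, control_ids,
                            set_name = "custom",
                            fold_change = c("arithmetic", "geometric"),
                            var_equal = FALSE) {
  fold_change <- match.arg(fold_change)
  if (length(gene_set) == 0) abort("gene_set must be non-empty")
  if (length(case_ids) < 2 || length(control_ids) < 2) {
    abort("need at least 2 samples per group for the t-test")
  }
  sub <- counts[counts$gene_id %in% gene_set &
                  counts$sample_id %in% c(case_ids, control_ids), ]
  missing_g <- setdiff(gene_set, unique(sub$gene_id))
  if (length(missing_g) > 0) {
    abort(paste0("gene_set genes absent from counts: ",
                 paste(missing_g, collapse = ", ")))
  }
  gm <- dplyr::summarise(dplyr::group_by(sub, .data$sample_id),
                         geomean = geometric_mean(.data$count),
                         .groups = "drop")
  gm$group <- ifelse(gm$sample_id %in% case_ids, "case", "control")
  x <- gm$geomean[gm$group == "case"]
  y <- gm$geomean[gm$group == "control"]
  fc <- if (fold_change == "arithmetic") {
    mean(x) / mean(y)
  } else {
    geometric_mean(x) / geometric_mean(y)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      warn("both groups constant and equal; p-value set to 1")
      p <- 1
    } else {
      warn("both groups constant; t-test undefined, p-value set to NA")
      p <- NA_real_
    }
  } else {
    p <- t.test(x, y, var.equal = var_equal)$p.value
  }
  structure(
    list(set_name = set_name, gene_ids = sort(unique(gene_set)),
         samples = dplyr::arrange(gm, dplyr::desc(.data$group == "case"),
                                  .data$sample_id),
         fold_change = fc, p_value = p,
         method = list(fold_change = fold_change, var_equal = var_equal)),
    class = "geneset_summary"
  )
}

#' @export
print.geneset_summary <- function(x, ...) {
  test <- if (x$method$var_equal) "Student" else "Welch"
  cat(sprintf(
    "<geneset_summary: %s>\n  %d genes, %d samples\n  fold change (%s mean ratio): %.4g\n  two-sided %s t-test p = %.4g\n",
    x$set_name, length(x$gene_ids), nrow(x$samples),
    x$method$fold_change, x$fold_change, test, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.geneset_summary <- function(x, ...) {
  dplyr::mutate(x$samples, set_name = x$set_name, .before = 1)
}

#' @export
glance.geneset_summary <- function(x, ...) {
  tibble(set_name = x$set_name, n_genes = length(x$gene_ids),
         fold_change = x$fold_change, p_value = x$p_value,
         fold_change_type = x$method$fold_change,
         var_equal = x$method$var_equal)
}

#' @export
autoplot.geneset_summary <- function(object, ...) {
  df <- object$samples
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$geomean)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = paste0(object$set_name, " gene set"),
      subtitle = sprintf("fold change = %.3g, p = %.3g",
                         object$fold_change, object$p_value),
      x = NULL, y = "per-sample geometric mean (normalized)"
    ) +
    ggplot2::theme_minimal()
}
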