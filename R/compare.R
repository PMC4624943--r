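#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort ascending, take `adj_(i) = min over j >= i of
#' (m/j) * p_(j)` capped at 1, and restore the input order. Delegates to
#' `stats::p.adjust(method = "BH")`, which implements exactly this; input
#' validation is added so out-of-range p-values fail loudly.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Lightweight differential-expression substitute
#'
#' A deliberately simple DE table generator for synthetic data: per gene,
#' the effect is the difference of group means of `log2(RPM + pseudo)` and
#' the p-value comes from a two-sided Welch t-test on the same transformed
#' values, BH-adjusted across genes. This is plumbing that stands in for a
#' full count-model DE analysis at desk scale; no equivalence with
#' negative-binomial DE methods is claimed, and outputs are labelled
#' accordingly.
#'
#' @param counts Long count tibble (`sample_id`, `gene_id`, `count`).
#' @param case_ids,control_ids Sample ids of the two groups (>= 2 each).
#' @param pseudo Pseudocount added on the RPM scale before log2.
#' @param normalization Per-sample denominator for the RPM-like scaling:
#'   `"total"` (reads per million of the sample's assigned total) or
#'   `"median_ratio"` (median-of-ratios size factors, rescaled to the mean
#'   library size). Total-count scaling is composition-sensitive: when a
#'   large gene family genuinely changes, every other gene appears shifted
#'   in the opposite direction. Median-of-ratios is robust to that and is
#'   what count-model DE tools use internally.
#'
#' @return A tibble with `gene_id`, `base_mean` (mean RPM),
#'   `log2_fold_change`, `p_value`, `adj_p_value`, plus attribute
#'   `method = "de_lite"`.
#' @export
de_lite <- function(counts, case_ids, control_ids, pseudo = 0.5,
                    normalization = c("total", "median_ratio")) {
  normalization <- match.arg(normalization)
  if (length(case_ids) < 2 || length(control_ids) < 2) {
    abort("need at least 2 samples per group")
  }
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$sample_id),
                             total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) abort("sample with zero total counts")
  if (normalization == "median_ratio") {
    sf <- median_ratio_size_factors(counts)
    totals <- dplyr::mutate(
      dplyr::left_join(totals, sf, by = "sample_id"),
      total = .data$size_factor * mean(.data$total)
    )[, c("sample_id", "total")]
  }
  rpm <- dplyr::mutate(
    dplyr::left_join(counts, totals, by = "sample_id"),
    rpm = .data$count / .data$total * 1e6,
    logv = log2(.data$rpm + pseudo)
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(rpm, "gene_id", "sample_id", "logv"),
    names_from = "sample_id", values_from = "logv"
  )
  rpm_wide <- tidyr::pivot_wider(
    dplyr::select(rpm, "gene_id", "sample_id", "rpm"),
    names_from = "sample_id", values_from = "rpm"
  )
  X <- as.matrix(wide[, case_ids, drop = FALSE])
  Y <- as.matrix(wide[, control_ids, drop = FALSE])
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warn(paste0(sum(degenerate),
                " gene(s) with zero variance in both groups; p set to 1"))
    p[degenerate] <- 1
  }
  tibble(
    gene_id = wide$gene_id,
    base_mean = rowMeans(as.matrix(
      rpm_wide[, c(case_ids, control_ids), drop = FALSE])),
    log2_fold_change = mx - my,
    p_value = p,
    adj_p_value = bh_adjust(p)
  ) |>
    structure(method = "de_lite")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across genes of the ratio of the gene's
#' count to its across-sample geometric mean; only genes positive in every
#' sample enter the reference. Robust against composition shifts caused by
#' a minority of strongly changing genes.
#'
#' @param counts Long count tibble (`sample_id`, `gene_id`, `count`).
#' @return A tibble with `sample_id` and `size_factor`.
#' @export
median_ratio_size_factors <- function(counts) {
  wide <- tidyr::pivot_wider(
    dplyr::select(counts, "gene_id", "sample_id", "count"),
    names_from = "sample_id", values_from = "count"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  keep <- rowSums(m <= 0) == 0
  if (!any(keep)) abort("no gene is positive in every sample")
  logm <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(logm)
  tibble(sample_id = colnames(m),
         size_factor = exp(apply(logm - ref, 2, stats::median)))
}

#' Bundle a DE table with its expressed-gene set
#'
#' @param experiment_id Label for the experiment.
#' @param de A DE result tibble (`gene_id`, `log2_fold_change`, `p_value`,
#'   `adj_p_value`, ...).
#' @param expressed_genes Character vector (e.g. from [rpm_filter()]); must
#'   be a subset of the DE table's genes.
#' @return A list of class `experiment_result`.
#' @export
experiment_result <- function(experiment_id, de, expressed_genes) {
  extra <- setdiff(expressed_genes, de$gene_id)
  if (length(extra) > 0) {
    abort("expressed_genes must be a subset of the DE table's genes")
  }
  structure(list(experiment_id = experiment_id, de = as_tibble(de),
                 expressed_genes = sort(unique(expressed_genes))),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s>\n  %d genes tested, %d expressed\n",
              x$experiment_id, nrow(x$de), length(x$expressed_genes)))
  invisible(x)
}

common_expressed <- function(res_a, res_b) {
  intersect(res_a$expressed_genes, res_b$expressed_genes)
}

#' Match two experiments and correlate their effects
#'
#' Restricts both experiments to the genes expressed in each (the
#' intersection of their filtered sets) and reports the Pearson correlation
#' of the two log2 fold-change vectors over those genes. Symmetric in its
#' arguments.
#'
#' @param res_a,res_b [experiment_result()] objects sharing a gene
#'   namespace.
#' @return A one-row tibble: `n_common`, `pearson_r`.
#' @export
match_and_correlate <- function(res_a, res_b) {
  genes <- common_expressed(res_a, res_b)
  if (length(genes) < 3) {
    abort(paste0("only ", length(genes),
                 " common expressed genes; need at least 3"))
  }
  lfc_a <- setNames(res_a$de$log2_fold_change, res_a$de$gene_id)[genes]
  lfc_b <- setNames(res_b$de$log2_fold_change, res_b$de$gene_id)[genes]
  tibble(n_common = length(genes), pearson_r = cor(lfc_a, lfc_b))
}

de_status <- function(de, genes, alpha) {
  lfc <- setNames(de$log2_fold_change, de$gene_id)[genes]
  adj <- setNames(de$adj_p_value, de$gene_id)[genes]
  dplyr::case_when(
    adj < alpha & lfc > 0 ~ "up",
    adj < alpha & lfc < 0 ~ "down",
    TRUE ~ "ns"  # includes significant genes with zero (directionless) lfc
  )
}

#' Joint significance/direction categories of two experiments
#'
#' Over the common expressed gene set, classifies each gene in each
#' experiment as `up` (adjusted p < alpha, positive log2FC), `down`
#' (adjusted p < alpha, negative log2FC) or `ns` (all else; a zero log2FC
#' is directionless even when significant) and cross-tabulates. The nine
#' category counts partition the common set: e.g. `a_status == "up" &
#' b_status == "up"` are the genes significantly up-regulated in both.
#'
#' @param res_a,res_b [experiment_result()] objects.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A 9-row tibble: `a_status`, `b_status`, `n`.
#' @export
overlap_counts <- function(res_a, res_b, alpha = 0.05) {
  genes <- common_expressed(res_a, res_b)
  df <- tibble(
    a_status = factor(de_status(res_a$de, genes, alpha),
                      levels = c("up", "down", "ns")),
    b_status = factor(de_status(res_b$de, genes, alpha),
                      levels = c("up", "down", "ns"))
  )
  out <- dplyr::count(df, .data$a_status, .data$b_status, .drop = FALSE,
                      name = "n")
  dplyr::mutate(out, a_status = as.character(.data$a_status),
                b_status = as.character(.data$b_status))
}

#' Direction concordance against per-probe effects
#'
#' A gene is concordant when at least one of its probes changes in the
#' same direction as the sequencing result; genes with a zero sequencing
#' log2FC are directionless and never concordant.
#'
#' @param de A DE result tibble (`gene_id`, `log2_fold_change`).
#' @param probe_table Tibble with `gene_id` and `probe_log2fc` (one row per
#'   probe); its genes must be a subset of the DE table's.
#' @return A tibble with `gene_id` and logical `concordant`, one row per
#'   gene of `probe_table`; `sum(x$concordant)` is the concordant count.
#' @export
direction_concordance <- function(de, probe_table) {
  extra <- setdiff(unique(probe_table$gene_id), de$gene_id)
  if (length(extra) > 0) {
    abort("probe_table genes must be a subset of the DE table's genes")
  }
  lfc <- setNames(de$log2_fold_change, de$gene_id)
  dplyr::summarise(
    dplyr::group_by(probe_table, .data$gene_id),
    concordant = {
      s <- sign(lfc[[dplyr::cur_group()$gene_id]])
      s != 0 && any(sign(.data$probe_log2fc) == s)
    },
    .groups = "drop"
  )
}
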