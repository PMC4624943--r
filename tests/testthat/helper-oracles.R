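# Shared fixtures and independent brute-force oracles.

# hand-built annotation with a multi-exon gene, a single-exon gene, and a
# gene with a 100 bp exon for coverage arithmetic
tiny_annotation <- function() {
  gene_annotation(tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    symbol = c("gA", "gB", "gC"),
    class_label = c("other", "unchanging_candidate", "canonical_histone"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "+", "-"),
    start = c(0L, 2000L, 0L),
    end = c(1000L, 2500L, 100L),
    exons = list(
      data.frame(start = c(0L, 400L, 800L), end = c(200L, 600L, 1000L)),
      data.frame(start = 2000L, end = 2500L),
      data.frame(start = 0L, end = 100L)
    ),
    utr5 = list(
      data.frame(start = 0L, end = 50L),
      data.frame(start = integer(), end = integer()),
      data.frame(start = 0L, end = 20L)
    ),
    utr3 = list(
      data.frame(start = 950L, end = 1000L),
      data.frame(start = integer(), end = integer()),
      data.frame(start = 80L, end = 100L)
    )
  ))
}

# an alignment record table, one row per mapping
aln_row <- function(read_id, chrom, start, end, n) {
  tibble::tibble(read_id = read_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), n_mappings = as.integer(n))
}

# per-base membership oracle: for each base of the exon-bounded span,
# TRUE if exonic
per_base_exonic <- function(ex, span_start, span_end) {
  bases <- seq(span_start, span_end - 1L)
  vapply(bases, function(b) any(b >= ex$start & b < ex$end), logical(1))
}

# direct O(m^2) step-up oracle for BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min((m / seq(i, m)) * ps[seq(i, m)]))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hypergeometric tail oracle for the one-sided Fisher test on
# [a, b; c, d] with alternative "greater"
fisher_oracle <- function(a, b, c_, d) {
  kmax <- min(a + b, a + c_)
  sum(stats::dhyper(a:kmax, a + b, c_ + d, a + c_))
}

# textbook Welch statistic and p-value
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

# small long-format count table from a matrix (genes x samples)
counts_from_matrix <- function(m, groups = NULL) {
  df <- tibble::as_tibble(m, rownames = "gene_id")
  out <- tidyr::pivot_longer(df, -"gene_id", names_to = "sample_id",
                             values_to = "count")
  if (!is.null(groups)) {
    out$group <- unname(groups[out$sample_id])
  }
  out
}

small_config <- function(seed = 1L, ...) {
  args <- list(n_canonical = 4, canonical_copies = c(2, 2), n_variant = 3,
               n_unchanging = 80, n_de = 10, baseline_mean = 60, seed = seed)
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(sim_config, args)
}
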