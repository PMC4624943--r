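check_alignments <- function(alignments) {
  req <- c("read_id", "chrom", "start", "end", "n_mappings")
  missing <- setdiff(req, names(alignments))
  if (length(missing) > 0) {
    abort(paste0("alignment table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(alignments$n_mappings < 1)) abort("n_mappings must be >= 1")
  first <- match(alignments$read_id, alignments$read_id)
  if (any(alignments$n_mappings != alignments$n_mappings[first])) {
    abort("records sharing a read_id must share n_mappings")
  }
  invisible(alignments)
}

exon_granges <- function(annotation) {
  ex <- tidyr::unnest(
    dplyr::select(as_tibble(annotation), "gene_id", "chrom", "exons"),
    "exons"
  )
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    gene_id = ex$gene_id
  )
}

#' Multimapping-weighted gene counts for one sample
#'
#' Each alignment record with `n_mappings <= cap` contributes
#' `1/n_mappings` to every gene whose exon union it overlaps by at least
#' one base; records exceeding the cap are discarded entirely. A read whose
#' every mapping lands in annotated exons therefore contributes a total
#' weight of exactly 1 across the genome. Records overlapping no annotated
#' exon are accumulated in an `"unassigned"` attribute rather than raising
#' an error; a mapping overlapping the exons of two genes adds its weight
#' to both.
#'
#' @param alignments Tibble with `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `n_mappings`.
#' @param annotation An [gene_annotation()].
#' @param cap Maximum multiplicity retained (default 10).
#'
#' @return A tibble with one row per annotated gene (`gene_id`, `count`),
#'   zero-filled, with attribute `unassigned` holding the total weight of
#'   unassignable records.
#' @export
weighted_gene_counts <- function(alignments, annotation, cap = 10) {
  if (cap < 1) abort("cap must be >= 1")
  check_alignments(alignments)
  kept <- alignments[alignments$n_mappings <= cap, ]
  zero <- tibble(gene_id = annotation$gene_id, count = 0)
  if (nrow(kept) == 0) {
    attr(zero, "unassigned") <- 0
    return(zero)
  }
  reads <- GenomicRanges::GRanges(
    seqnames = kept$chrom,
    ranges = IRanges::IRanges(start = kept$start + 1L, end = kept$end)
  )
  exons <- exon_granges(annotation)
  hits <- GenomicRanges::findOverlaps(reads, exons, minoverlap = 1L,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  gidx <- match(exons$gene_id[S4Vectors::subjectHits(hits)],
                annotation$gene_id)
  # one record may overlap several exons of the same gene: count it once
  uniq <- !duplicated((q - 1) * nrow(annotation) + gidx)
  q <- q[uniq]; gidx <- gidx[uniq]
  acc <- numeric(nrow(annotation))
  agg <- rowsum(1 / kept$n_mappings[q], gidx)
  acc[as.integer(rownames(agg))] <- agg[, 1]
  out <- tibble(gene_id = annotation$gene_id, count = acc)
  assigned <- logical(nrow(kept))
  assigned[q] <- TRUE
  attr(out, "unassigned") <- sum(1 / kept$n_mappings[!assigned])
  out
}

#' Uniquely-mapping gene counts for one sample
#'
#' Counts only records with `n_mappings = 1`; integer-valued. This mirrors
#' a standard unique-reads analysis, which systematically misses genes in
#' repetitive families.
#'
#' @inheritParams weighted_gene_counts
#' @return A tibble (`gene_id`, `count`) with an `unassigned` attribute.
#' @export
unique_gene_counts <- function(alignments, annotation) {
  check_alignments(alignments)
  out <- weighted_gene_counts(alignments[alignments$n_mappings == 1, ],
                              annotation, cap = 1)
  out$count <- as.integer(round(out$count))
  out
}

#' Expression filter in reads per million
#'
#' Keeps a gene if its count reaches `threshold` reads per million of the
#' sample's assigned total in at least one sample (boundary inclusive).
#' The denominator is the per-sample total of assigned counts in the
#' matrix being filtered.
#'
#' @param counts Long count tibble with columns `sample_id`, `gene_id`,
#'   `count` (one row per gene per sample).
#' @param threshold Minimum reads per million (default 10).
#'
#' @return Character vector of retained gene ids (annotation order not
#'   guaranteed; sorted).
#' @export
rpm_filter <- function(counts, threshold = 10) {
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$sample_id),
                             total = sum(.data$count), .groups = "drop")
  zero_tot <- totals$sample_id[totals$total <= 0]
  if (length(zero_tot) > 0) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(zero_tot, collapse = ", ")))
  }
  rpm <- dplyr::mutate(
    dplyr::left_join(counts, totals, by = "sample_id"),
    rpm = .data$count / .data$total * 1e6
  )
  kept <- dplyr::summarise(dplyr::group_by(rpm, .data$gene_id),
                           keep = any(.data$rpm >= threshold),
                           .groups = "drop")
  sort(kept$gene_id[kept$keep])
}

#' Quantify all samples of a simulated experiment
#'
#' Convenience wrapper: simulates one alignment table per sample from the
#' configuration and reduces each to weighted gene counts, returning the
#' long count table the downstream normalization consumes.
#'
#' @param annotation Output of [build_toy_genome()].
#' @param config The matching [sim_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param cap Multimapping cap passed to [weighted_gene_counts()].
#'
#' @return A long tibble with `sample_id`, `group`, `gene_id`, `count`.
#' @export
quantify_experiment <- function(annotation, config, seed = config$seed,
                                cap = 10) {
  design <- tibble(
    group = c(rep("case", config$n_case), rep("control", config$n_control)),
    index = c(seq_len(config$n_case), seq_len(config$n_control))
  )
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    g <- design$group[i]; idx <- design$index[i]
    aln <- simulate_alignments(annotation, config, g, idx, seed = seed)
    cnt <- weighted_gene_counts(aln, annotation, cap = cap)
    tibble(sample_id = paste0(g, "_", idx), group = g,
           gene_id = cnt$gene_id, count = cnt$count)
  })
}
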