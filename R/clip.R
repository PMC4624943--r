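feature_intervals <- function(annotation) {
  introns <- introns_of(annotation)
  base <- as_tibble(annotation)
  pull_class <- function(col, label) {
    out <- tidyr::unnest(dplyr::select(base, "gene_id", "chrom",
                                       intervals = dplyr::all_of(col)),
                         "intervals")
    out$feature_class <- label
    out
  }
  dplyr::bind_rows(
    pull_class("exons", "exon"),
    pull_class("utr5", "utr5"),
    pull_class("utr3", "utr3"),
    dplyr::mutate(introns, feature_class = "intron")
  )
}

#' Per-gene, per-feature CLIP cluster coverage
#'
#' For every gene and feature class (exon, intron, 5' UTR, 3' UTR) with at
#' least one annotated interval, reports the number of CLIP clusters
#' overlapping the class by at least one base (`hit_count`), the number of
#' feature bases covered by the union of the cluster intersections
#' (`covered_bases`), the total feature length, and the covered proportion.
#' A cluster spanning an exon-intron boundary is a hit for both classes,
#' with its bases apportioned by intersection. UTR bases also lie in exons,
#' so a UTR cluster is counted for both the UTR and the exon class.
#'
#' @param annotation An [gene_annotation()].
#' @param clusters Tibble of CLIP clusters with `chrom`, `start`, `end`
#'   (0-based half-open; e.g. the `peaks` element of
#'   [simulate_clip_peaks()] or a BED file read with [read_bed()]).
#'
#' @return A tibble with `gene_id`, `feature_class`, `hit_count`,
#'   `covered_bases`, `feature_length`, `proportion`.
#' @export
feature_clip_coverage <- function(annotation, clusters) {
  feats <- feature_intervals(annotation)
  lens <- dplyr::summarise(
    dplyr::group_by(feats, .data$gene_id, .data$feature_class),
    feature_length = sum(.data$end - .data$start), .groups = "drop"
  )
  if (nrow(clusters) == 0) {
    return(dplyr::mutate(lens, hit_count = 0L, covered_bases = 0L,
                         proportion = 0)[
      , c("gene_id", "feature_class", "hit_count", "covered_bases",
          "feature_length", "proportion")])
  }
  feat_gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end)
  )
  clus_gr <- GenomicRanges::GRanges(
    seqnames = clusters$chrom,
    ranges = IRanges::IRanges(start = clusters$start + 1L, end = clusters$end)
  )
  hits <- GenomicRanges::findOverlaps(feat_gr, clus_gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  inter <- IRanges::pintersect(IRanges::ranges(feat_gr)[q],
                               IRanges::ranges(clus_gr)[s])
  ov <- tibble(
    gene_id = feats$gene_id[q],
    feature_class = feats$feature_class[q],
    cluster = s,
    start = IRanges::start(inter), end = IRanges::end(inter) + 1L
  )
  per_class <- dplyr::group_by(ov, .data$gene_id, .data$feature_class)
  hit_tbl <- dplyr::summarise(per_class,
                              hit_count = dplyr::n_distinct(.data$cluster),
                              covered_bases = union_width(.data$start,
                                                          .data$end),
                              .groups = "drop")
  out <- dplyr::left_join(lens, hit_tbl,
                          by = c("gene_id", "feature_class"))
  out <- dplyr::mutate(
    out,
    hit_count = dplyr::coalesce(.data$hit_count, 0L),
    covered_bases = dplyr::coalesce(.data$covered_bases, 0L),
    proportion = .data$covered_bases / .data$feature_length
  )
  out[, c("gene_id", "feature_class", "hit_count", "covered_bases",
          "feature_length", "proportion")]
}

# width of the union of half-open intervals given as parallel vectors
union_width <- function(start, end) {
  r <- IRanges::reduce(IRanges::IRanges(start = start, end = end - 1L))
  as.integer(sum(IRanges::width(r)))
}

#' Does a gene carry any CLIP cluster?
#'
#' @param coverage Output of [feature_clip_coverage()].
#' @param gene A single gene id present in the coverage table.
#' @return `TRUE` iff any feature class of the gene has `hit_count > 0`.
#' @export
binding_flag <- function(coverage, gene) {
  sub <- coverage[coverage$gene_id == gene, ]
  if (nrow(sub) == 0) abort(paste0("unknown gene: ", gene))
  any(sub$hit_count > 0)
}

#' Per-gene binding flags
#'
#' @param coverage Output of [feature_clip_coverage()].
#' @return A tibble with `gene_id` and logical `bound`.
#' @export
bound_genes <- function(coverage) {
  dplyr::summarise(dplyr::group_by(coverage, .data$gene_id),
                   bound = any(.data$hit_count > 0), .groups = "drop")
}

#' Binding enrichment of a gene set
#'
#' One-sided Fisher exact test (alternative "greater") on the 2x2 table of
#' binding presence/absence in the gene set versus the rest of the
#' background. The reported odds ratio is the sample cross-product
#' `(a*d)/(b*c)`; with an empty cell it is `Inf` (or `NaN` when the
#' numerator is also zero), not a conditional maximum-likelihood estimate.
#'
#' @param gene_set Character vector, a subset of `background_set`.
#' @param background_set Character vector of all genes considered.
#' @param flags Tibble from [bound_genes()] covering the background.
#'
#' @return A one-row tibble: `n_set`, `n_background`, `set_bound`,
#'   `rest_bound`, `odds_ratio`, `p_value`.
#' @export
binding_enrichment <- function(gene_set, background_set, flags) {
  if (length(gene_set) < 1) abort("gene_set must be non-empty")
  if (length(setdiff(gene_set, background_set)) > 0) {
    abort("gene_set must be a subset of background_set")
  }
  rest <- setdiff(background_set, gene_set)
  if (length(rest) == 0) {
    abort("gene_set equals background_set: empty complement")
  }
  lut <- setNames(flags$bound, flags$gene_id)
  missing_g <- setdiff(background_set, flags$gene_id)
  if (length(missing_g) > 0) {
    abort(paste0("no binding flag for: ",
                 paste(head(missing_g, 5), collapse = ", ")))
  }
  a <- sum(lut[gene_set]); b <- length(gene_set) - a
  c_ <- sum(lut[rest]); d <- length(rest) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "greater")$p.value
  tibble(
    n_set = length(gene_set), n_background = length(background_set),
    set_bound = a, rest_bound = c_,
    odds_ratio = (a * d) / (b * c_),
    p_value = p
  )
}

#' Read and write BED interval files
#'
#' Minimal BED6 support for CLIP clusters and peaks: the first three
#' columns are required, `name`, `score` and `strand` default to `"."`,
#' `0`, `"."`.
#'
#' @param path File path.
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return `read_bed()` returns a tibble; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  purrr::map_dfr(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort(paste0("malformed BED line ", i, " of ", path))
    start <- as.integer(f[2]); end <- as.integer(f[3])
    if (is.na(start) || is.na(end) || end <= start) {
      abort(paste0("invalid interval at BED line ", i, " of ", path))
    }
    tibble(chrom = f[1], start = start, end = end,
           name = if (length(f) >= 4) f[4] else ".",
           score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0,
           strand = if (length(f) >= 6) f[6] else ".")
  })
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  df <- dplyr::mutate(
    as_tibble(intervals),
    name = if ("name" %in% names(intervals)) .data$name else ".",
    score = if ("score" %in% names(intervals)) .data$score else 0,
    strand = if ("strand" %in% names(intervals)) .data$strand else "."
  )
  writeLines(paste(df$chrom, df$start, df$end, df$name, df$score, df$strand,
                   sep = "\t"), path)
  invisible(path)
}
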