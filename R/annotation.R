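#' Gene class labels used throughout the pipeline
#'
#' Genes are partitioned into canonical (replication-dependent, normally
#' non-polyadenylated) histones, variant (replication-independent,
#' polyadenylated) histones, candidate unchanging reference genes, and
#' everything else.
#'
#' @export
gene_classes <- c("canonical_histone", "variant_histone",
                  "unchanging_candidate", "other")

new_annotation <- function(genes) {
  structure(genes, class = c("hq_annotation", class(tibble())))
}

#' Build a validated gene annotation
#'
#' An annotation is a tibble with one row per gene and list-columns holding
#' the exon and UTR intervals. All coordinates are 0-based half-open (BED
#' convention). Each gene carries a flattened exon model: exons must be
#' sorted, pairwise disjoint and contained in the gene span; UTR intervals
#' must lie inside the exon union. Introns are derived, never stored.
#'
#' @param genes A data frame with columns `gene_id`, `symbol`, `class_label`
#'   (one of [gene_classes]), `chrom`, `strand` (`+`, `-` or `.`), `start`,
#'   `end`, and list-columns `exons`, `utr5`, `utr3`, each element a data
#'   frame with integer `start`/`end` columns (possibly zero rows for UTRs).
#'   Extra columns (e.g. `family`, `base_mean`, `true_fc` from the synthetic
#'   generator) are carried through untouched.
#'
#' @return A tibble of class `hq_annotation`.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   gene_id = "g1", symbol = "G1", class_label = "other",
#'   chrom = "chr1", strand = "+", start = 0L, end = 300L,
#'   exons = list(data.frame(start = c(0L, 200L), end = c(100L, 300L))),
#'   utr5 = list(data.frame(start = 0L, end = 50L)),
#'   utr3 = list(data.frame(start = integer(), end = integer()))
#' )
#' anno <- gene_annotation(g)
#' introns_of(anno)
gene_annotation <- function(genes) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "symbol", "class_label", "chrom", "strand",
                "start", "end", "exons", "utr5", "utr3")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    abort(paste0("duplicate gene_id: ", paste(dup, collapse = ", ")))
  }
  bad_class <- setdiff(unique(genes$class_label), gene_classes)
  if (length(bad_class) > 0) {
    abort(paste0("unknown class_label: ", paste(bad_class, collapse = ", ")))
  }
  for (i in seq_len(nrow(genes))) {
    validate_gene_row(genes[i, ])
  }
  new_annotation(genes)
}

validate_gene_row <- function(g) {
  id <- g$gene_id
  if (g$start < 0 || g$end <= g$start) {
    abort(paste0("gene ", id, ": span must satisfy 0 <= start < end"))
  }
  ex <- as_tibble(g$exons[[1]])
  if (nrow(ex) < 1) abort(paste0("gene ", id, ": needs at least one exon"))
  if (any(ex$end <= ex$start)) {
    abort(paste0("gene ", id, ": zero- or negative-length exon"))
  }
  if (is.unsorted(ex$start, strictly = TRUE) ||
      any(ex$start[-1] < ex$end[-nrow(ex)])) {
    abort(paste0("gene ", id, ": exons must be sorted and pairwise disjoint"))
  }
  if (min(ex$start) < g$start || max(ex$end) > g$end) {
    abort(paste0("gene ", id, ": exons outside gene span"))
  }
  for (cls in c("utr5", "utr3")) {
    u <- as_tibble(g[[cls]][[1]])
    if (nrow(u) == 0) next
    if (any(u$end <= u$start)) {
      abort(paste0("gene ", id, ": zero-length ", cls, " interval"))
    }
    # every UTR base must fall inside the exon union
    cov <- purrr::map2(u$start, u$end, function(s, e) {
      sum(pmax(0, pmin(ex$end, e) - pmax(ex$start, s)))
    })
    if (any(unlist(cov) != u$end - u$start)) {
      abort(paste0("gene ", id, ": ", cls, " not contained in exon union"))
    }
  }
  invisible(TRUE)
}

#' Derive intron intervals from an annotation
#'
#' Introns are the maximal gaps between consecutive exons inside the gene
#' span; a single-exon gene contributes no rows. Union(exons, introns)
#' covers the exon-bounded span exactly and the two sets are disjoint.
#'
#' @param annotation An [gene_annotation()] object.
#' @param gene_id Optional character vector restricting the genes.
#'
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
introns_of <- function(annotation, gene_id = NULL) {
  genes <- annotation
  if (!is.null(gene_id)) {
    unknown <- setdiff(gene_id, genes$gene_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown gene_id: ", paste(unknown, collapse = ", ")))
    }
    genes <- genes[genes$gene_id %in% gene_id, ]
  }
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    ex <- as_tibble(genes$exons[[i]])
    if (nrow(ex) < 2) {
      return(tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer()))
    }
    tibble(
      gene_id = genes$gene_id[i],
      chrom = genes$chrom[i],
      start = ex$end[-nrow(ex)],
      end = ex$start[-1]
    )
  })
}

#' Overlap length of genomic intervals
#'
#' Half-open interval intersection size in bases; intervals on different
#' chromosomes overlap by 0. Vectorized over rows (inputs are recycled to a
#' common length).
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`.
#'
#' @return Integer vector of overlap sizes.
#' @export
#' @examples
#' overlap_length(data.frame(chrom = "chr1", start = 0, end = 10),
#'                data.frame(chrom = "chr1", start = 5, end = 15))
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  out <- pmax(0L, pmin(a$end[idx_a], b$end[idx_b]) -
                   pmax(a$start[idx_a], b$start[idx_b]))
  out[a$chrom[idx_a] != b$chrom[idx_b]] <- 0L
  as.integer(out)
}

fmt_coords <- function(x) paste(x, collapse = ",")

parse_coords <- function(x) {
  if (is.na(x) || x == "") return(integer())
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

annotation_extra_cols <- c("family", "base_mean", "true_fc")

#' Read and write gene annotations
#'
#' Three dialects are supported. `tsv` is the package's own flat dialect
#' (columns `gene_id`, `symbol`, `class_label`, `chrom`, `strand`, `start`,
#' `end`, `exon_starts`, `exon_ends`, `utr5_starts`, `utr5_ends`,
#' `utr3_starts`, `utr3_ends`, with comma-joined 0-based half-open
#' coordinates) and round-trips an annotation exactly, including the
#' generator's `family`, `base_mean` and `true_fc` columns when present.
#' `gtf` is a GTF-lite dialect (features `gene`, `exon`, `five_prime_utr`,
#' `three_prime_utr`; 1-based inclusive coordinates converted on the fly;
#' attributes `gene_id`, `gene_name`, `gene_class`) that round-trips the
#' gene structure but not generator metadata. `bed12` carries exon blocks
#' only: on reading, UTRs are empty, the symbol is the name field and the
#' class defaults to `other` (lossy, for interchange with browser tracks).
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"gtf"`, `"bed12"`.
#' @param annotation An [gene_annotation()] object.
#'
#' @return `read_annotation()` returns an `hq_annotation`;
#'   `write_annotation()` returns `path` invisibly.
#' @export
read_annotation <- function(path, format = c("tsv", "gtf", "bed12")) {
  format <- match.arg(format)
  switch(format,
    tsv = read_annotation_tsv(path),
    gtf = read_annotation_gtf(path),
    bed12 = read_annotation_bed12(path)
  )
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path, format = c("tsv", "gtf", "bed12")) {
  format <- match.arg(format)
  switch(format,
    tsv = write_annotation_tsv(annotation, path),
    gtf = write_annotation_gtf(annotation, path),
    bed12 = write_annotation_bed12(annotation, path)
  )
  invisible(path)
}

read_annotation_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  genes <- purrr::map_dfr(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    line_no <- i + 1L  # header is line 1
    starts <- parse_coords(r$exon_starts)
    ends <- parse_coords(r$exon_ends)
    if (length(starts) != length(ends) || length(starts) == 0 ||
        anyNA(starts) || anyNA(ends)) {
      abort(paste0("malformed exon coordinates at line ", line_no,
                   " of ", path))
    }
    tibble(
      gene_id = r$gene_id, symbol = r$symbol, class_label = r$class_label,
      chrom = r$chrom, strand = r$strand,
      start = as.integer(r$start), end = as.integer(r$end),
      exons = list(tibble(start = starts, end = ends)),
      utr5 = list(tibble(start = parse_coords(r$utr5_starts),
                         end = parse_coords(r$utr5_ends))),
      utr3 = list(tibble(start = parse_coords(r$utr3_starts),
                         end = parse_coords(r$utr3_ends)))
    )
  })
  for (col in annotation_extra_cols) {
    if (col %in% names(raw)) {
      genes[[col]] <- if (col == "family") {
        ifelse(raw[[col]] == "", NA_character_, raw[[col]])
      } else {
        as.numeric(raw[[col]])
      }
    }
  }
  gene_annotation(genes)
}

write_annotation_tsv <- function(annotation, path) {
  out <- tibble(
    gene_id = annotation$gene_id,
    symbol = annotation$symbol,
    class_label = annotation$class_label,
    chrom = annotation$chrom,
    strand = annotation$strand,
    start = annotation$start,
    end = annotation$end,
    exon_starts = purrr::map_chr(annotation$exons, ~ fmt_coords(.x$start)),
    exon_ends = purrr::map_chr(annotation$exons, ~ fmt_coords(.x$end)),
    utr5_starts = purrr::map_chr(annotation$utr5, ~ fmt_coords(.x$start)),
    utr5_ends = purrr::map_chr(annotation$utr5, ~ fmt_coords(.x$end)),
    utr3_starts = purrr::map_chr(annotation$utr3, ~ fmt_coords(.x$start)),
    utr3_ends = purrr::map_chr(annotation$utr3, ~ fmt_coords(.x$end))
  )
  for (col in annotation_extra_cols) {
    if (col %in% names(annotation)) out[[col]] <- annotation[[col]]
  }
  readr::write_tsv(out, path, progress = FALSE)
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

read_annotation_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  recs <- purrr::map_dfr(which(keep), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) abort(paste0("malformed GTF line ", i, " of ", path))
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || end1 < start1) {
      abort(paste0("malformed coordinates at GTF line ", i, " of ", path))
    }
    tibble(chrom = f[1], feature = f[3],
           start = start1 - 1L, end = end1,  # to 0-based half-open
           strand = f[7],
           gene_id = gtf_attr(f[9], "gene_id"),
           symbol = gtf_attr(f[9], "gene_name"),
           class_label = gtf_attr(f[9], "gene_class"))
  })
  gene_rows <- recs[recs$feature == "gene", ]
  genes <- purrr::map_dfr(seq_len(nrow(gene_rows)), function(i) {
    g <- gene_rows[i, ]
    sub <- recs[recs$gene_id == g$gene_id, ]
    pick <- function(feat) {
      s <- sub[sub$feature == feat, ]
      s <- s[order(s$start), ]
      tibble(start = s$start, end = s$end)
    }
    tibble(gene_id = g$gene_id, symbol = g$symbol,
           class_label = g$class_label %||% "other",
           chrom = g$chrom, strand = g$strand,
           start = g$start, end = g$end,
           exons = list(pick("exon")),
           utr5 = list(pick("five_prime_utr")),
           utr3 = list(pick("three_prime_utr")))
  })
  gene_annotation(genes)
}

write_annotation_gtf <- function(annotation, path) {
  lines <- character()
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_class "%s";',
                     g$gene_id, g$symbol, g$class_label)
    emit <- function(feature, start, end) {
      sprintf("%s\thistoquant\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, feature, start + 1L, end, g$strand, attrs)
    }
    lines <- c(lines, emit("gene", g$start, g$end))
    ex <- g$exons[[1]]
    lines <- c(lines, purrr::map2_chr(ex$start, ex$end, ~ emit("exon", .x, .y)))
    for (pair in list(c("utr5", "five_prime_utr"), c("utr3", "three_prime_utr"))) {
      u <- g[[pair[1]]][[1]]
      if (nrow(u) > 0) {
        lines <- c(lines,
                   purrr::map2_chr(u$start, u$end, ~ emit(pair[2], .x, .y)))
      }
    }
  }
  writeLines(lines, path)
}

read_annotation_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  genes <- purrr::map_dfr(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) abort(paste0("malformed BED12 line ", i, " of ", path))
    start <- as.integer(f[2]); end <- as.integer(f[3])
    if (is.na(start) || is.na(end) || end <= start) {
      abort(paste0("invalid interval at BED12 line ", i, " of ", path))
    }
    sizes <- parse_coords(sub(",$", "", f[11]))
    offsets <- parse_coords(sub(",$", "", f[12]))
    ex_starts <- start + offsets
    tibble(gene_id = f[4], symbol = f[4], class_label = "other",
           chrom = f[1], strand = f[6], start = start, end = end,
           exons = list(tibble(start = ex_starts,
                               end = ex_starts + sizes)),
           utr5 = list(tibble(start = integer(), end = integer())),
           utr3 = list(tibble(start = integer(), end = integer())))
  })
  gene_annotation(genes)
}

write_annotation_bed12 <- function(annotation, path) {
  lines <- purrr::map_chr(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    ex <- g$exons[[1]]
    paste(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
          g$start, g$end, "0", nrow(ex),
          fmt_coords(ex$end - ex$start), fmt_coords(ex$start - g$start),
          sep = "\t")
  })
  writeLines(lines, path)
}

#' Exon-union length per gene
#'
#' @param annotation An [gene_annotation()] object.
#' @return A tibble with `gene_id` and `exon_length` (bases).
#' @export
exon_union_length <- function(annotation) {
  tibble(
    gene_id = annotation$gene_id,
    exon_length = purrr::map_int(annotation$exons,
                                 ~ sum(as.integer(.x$end - .x$start)))
  )
}
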