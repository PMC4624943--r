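#' Read and write alignment tables
#'
#' The native format is a plain TSV with columns `read_id`, `chrom`,
#' `start`, `end` (0-based half-open) and `n_mappings`. A minimal SAM text
#' dialect is also supported: mandatory columns plus the `NH:i:` tag for
#' the mapping multiplicity (absent tag implies a unique read, reported
#' once per file), with the reference span derived from the CIGAR string.
#' The SAM writer emits unmapped-mate-free single-end records with an
#' `NH:i:` tag and a header built from the supplied annotation (or from
#' the maximal coordinates seen).
#'
#' @param path File path.
#' @param format `"tsv"` or `"sam"`.
#' @param alignments Tibble with `read_id`, `chrom`, `start`, `end`,
#'   `n_mappings`.
#' @param annotation Optional [gene_annotation()] supplying chromosome
#'   lengths for the SAM header.
#' @return `read_alignments()` returns an alignment tibble;
#'   `write_alignments()` returns `path` invisibly.
#' @export
read_alignments <- function(path, format = c("tsv", "sam")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- readr::read_tsv(
      path, comment = "#", progress = FALSE,
      col_types = readr::cols(
        read_id = "c", chrom = "c", start = "i", end = "i", n_mappings = "i"
      )
    )
    return(as_tibble(out))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^@", lines)]
  any_missing_nh <- FALSE
  out <- purrr::map_dfr(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) abort(paste0("malformed SAM line ", i, " of ", path))
    pos1 <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos1)) abort(paste0("invalid POS at SAM line ", i, " of ", path))
    width <- cigar_ref_width(f[6])
    nh_field <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    nh <- if (length(nh_field) >= 1) {
      as.integer(sub("^NH:i:", "", nh_field[1]))
    } else {
      any_missing_nh <<- TRUE
      1L
    }
    tibble(read_id = f[1], chrom = f[3], start = pos1 - 1L,
           end = pos1 - 1L + width, n_mappings = nh)
  })
  if (any_missing_nh) {
    inform("records without an NH tag were treated as uniquely mapping")
  }
  out
}

cigar_ref_width <- function(cigar) {
  if (cigar == "*") abort("CIGAR '*' (unmapped) records are not supported")
  m <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  if (length(m) == 0) abort(paste0("unparseable CIGAR: ", cigar))
  lens <- as.integer(sub("[MIDNSHP=X]$", "", m))
  ops <- sub("^\\d+", "", m)
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

#' @rdname read_alignments
#' @export
write_alignments <- function(alignments, path, format = c("tsv", "sam"),
                             annotation = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(alignments, path, progress = FALSE)
    return(invisible(path))
  }
  if (!is.null(annotation)) {
    sq <- dplyr::summarise(dplyr::group_by(as_tibble(annotation), .data$chrom),
                           len = max(.data$end) + 1000L, .groups = "drop")
  } else {
    sq <- dplyr::summarise(dplyr::group_by(alignments, .data$chrom),
                           len = max(.data$end) + 1000L, .groups = "drop")
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", sq$chrom, sq$len))
  body <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                  alignments$read_id, alignments$chrom,
                  alignments$start + 1L,
                  alignments$end - alignments$start,
                  alignments$n_mappings)
  writeLines(c(header, body), path)
  invisible(path)
}
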