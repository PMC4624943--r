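#' Simulation configuration
#'
#' Describes the synthetic study the generator emulates: two groups of
#' animals (an expressing "case" group and a "control" group, 4 each by
#' default), a set of canonical replication-dependent histone-like genes
#' organised in families of near-identical copies that drive multimapping,
#' distinct variant histone genes, a pool of non-differential genes usable
#' as normalization references, and additional differential genes in both
#' directions. Counts are negative-binomial; every draw is a pure function
#' of the configuration (same seed, same output).
#'
#' @param n_case,n_control Samples per group.
#' @param n_canonical Number of canonical histone-like genes.
#' @param canonical_copies Length-2 integer range of family sizes; every
#'   gene in a family is a near-identical copy, so each of its reads maps
#'   to all copies.
#' @param n_variant Number of variant histone genes (unique sequences).
#' @param n_unchanging Number of non-differential reference-candidate genes.
#' @param n_de Number of other differential genes, split half up, half down.
#' @param fc_canonical,fc_variant True case/control fold change of the
#'   canonical and variant sets.
#' @param fc_de_up,fc_de_down True fold changes of the other DE genes.
#' @param baseline_mean Expected unique-equivalent reads per gene per
#'   sample; per-gene baselines are drawn lognormal with this mean.
#' @param baseline_sdlog Lognormal sdlog of the per-gene baseline spread.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param library_size Optional expected total reads per sample; when set,
#'   per-gene means are scaled so the expected control total matches it.
#' @param read_length Simulated read length in bases.
#' @param clip_p_enriched,clip_p_background Default CLIP peak probabilities
#'   for enriched and background genes.
#' @param seed Master seed; per-stage and per-sample substreams are derived
#'   by fixed offsets.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case = 4, n_control = 4,
                       n_canonical = 34, canonical_copies = c(2L, 10L),
                       n_variant = 15, n_unchanging = 200, n_de = 100,
                       fc_canonical = 2.12, fc_variant = 0.841,
                       fc_de_up = 2, fc_de_down = 0.5,
                       baseline_mean = 100, baseline_sdlog = 0.8,
                       dispersion = 0.05, library_size = NULL,
                       read_length = 50,
                       clip_p_enriched = 0.8, clip_p_background = 0.2,
                       seed = 1L) {
  if (length(canonical_copies) == 1) {
    canonical_copies <- rep(canonical_copies, 2)
  }
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_canonical = as.integer(n_canonical),
    canonical_copies = as.integer(canonical_copies),
    n_variant = as.integer(n_variant),
    n_unchanging = as.integer(n_unchanging), n_de = as.integer(n_de),
    fc_canonical = fc_canonical, fc_variant = fc_variant,
    fc_de_up = fc_de_up, fc_de_down = fc_de_down,
    baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, library_size = library_size,
    read_length = as.integer(read_length),
    clip_p_enriched = clip_p_enriched,
    clip_p_background = clip_p_background,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_canonical < 1) abort("n_canonical must be >= 1")
  counts <- c(cfg$n_case, cfg$n_control, cfg$n_variant, cfg$n_unchanging,
              cfg$n_de)
  if (any(counts < 0)) abort("sample and gene counts must be >= 0")
  fcs <- c(cfg$fc_canonical, cfg$fc_variant, cfg$fc_de_up, cfg$fc_de_down)
  if (any(fcs <= 0)) abort("fold changes must be > 0")
  if (cfg$dispersion <= 0) abort("dispersion must be > 0")
  if (any(cfg$canonical_copies < 1) ||
      cfg$canonical_copies[2] < cfg$canonical_copies[1]) {
    abort("canonical_copies must be a positive, non-decreasing range")
  }
  invisible(cfg)
}

#' Packaged Scenario S1 preset
#'
#' The reference study design: 4 expressing vs 4 control samples, 34
#' canonical histone-like genes (true fold change 2.12) in multimapping
#' families, 15 variant histone genes (true fold change 0.841), 200
#' unchanging genes and 100 other DE genes. The preset ships as a YAML file
#' in `inst/extdata/scenario_s1.yaml`; arguments override its fields.
#'
#' @param seed Master seed (overrides the file's seed).
#' @param ... Further overrides passed to [sim_config()].
#'
#' @return A `sim_config`.
#' @export
scenario_s1 <- function(seed = NULL, ...) {
  path <- system.file("extdata", "scenario_s1.yaml", package = "histoquant")
  vals <- yaml::read_yaml(path)
  vals$canonical_copies <- as.integer(unlist(vals$canonical_copies))
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  if (!is.null(seed)) vals$seed <- as.integer(seed)
  do.call(sim_config, vals)
}

# Fixed-offset substream derivation: keeps every derived seed a valid
# 32-bit integer and decorrelates stages/samples of one master seed.
derive_seed <- function(master, stream) {
  v <- ((as.double(master) %% 2147483647) * 48271 +
          as.double(stream) * 7919) %% 2147483629
  as.integer(v)
}

seed_streams <- list(genome = 1L, case = 100L, control = 150L,
                     clip = 300L, ct = 400L, unchanging = 500L,
                     experiment_b = 700L)

make_gene <- function(gene_id, symbol, class_label, chrom, strand, cursor,
                      exon_lens, intron_lens, utr5_len, utr3_len,
                      family = NA_character_) {
  starts <- integer(length(exon_lens))
  pos <- cursor
  for (i in seq_along(exon_lens)) {
    starts[i] <- pos
    pos <- pos + exon_lens[i]
    if (i < length(exon_lens)) pos <- pos + intron_lens[i]
  }
  ends <- starts + exon_lens
  span_end <- ends[length(ends)]
  utr5 <- if (utr5_len > 0) {
    tibble(start = starts[1], end = starts[1] + utr5_len)
  } else tibble(start = integer(), end = integer())
  utr3 <- if (utr3_len > 0) {
    tibble(start = span_end - utr3_len, end = span_end)
  } else tibble(start = integer(), end = integer())
  tibble(
    gene_id = gene_id, symbol = symbol, class_label = class_label,
    chrom = chrom, strand = strand, start = cursor, end = span_end,
    exons = list(tibble(start = starts, end = ends)),
    utr5 = list(utr5), utr3 = list(utr3), family = family
  )
}

#' Build the toy genome annotation
#'
#' Lays out the configured genes on four toy chromosomes: canonical histone
#' families on `chrT1` (each family a run of structurally identical copies,
#' mirroring the highly repetitive histone clusters), variant histones on
#' `chrT2`, unchanging reference candidates on `chrT3` and the other DE
#' genes on `chrT4`. Every class contains at least one multi-exon gene with
#' annotated UTRs, and every exon is at least twice the read length. The
#' returned annotation carries generator metadata columns: `family`
#' (multimapping partners), `base_mean` (per-gene expected control count,
#' lognormal around `baseline_mean`) and `true_fc`.
#'
#' @param config A [sim_config()].
#'
#' @return An [gene_annotation()] with metadata columns.
#' @export
build_toy_genome <- function(config) {
  validate_config(config)
  withr::with_seed(derive_seed(config$seed, seed_streams$genome), {
    gap <- 500L
    rows <- list()

    # canonical families: near-identical copies, identical exon structure
    sizes <- integer()
    lo <- config$canonical_copies[1]; hi <- config$canonical_copies[2]
    while (sum(sizes) < config$n_canonical) {
      sizes <- c(sizes, if (lo == hi) lo else sample(lo:hi, 1))
    }
    excess <- sum(sizes) - config$n_canonical
    if (excess > 0) sizes[length(sizes)] <- sizes[length(sizes)] - excess
    sizes <- sizes[sizes > 0]
    cursor <- 0L
    gene_no <- 0L
    for (f in seq_along(sizes)) {
      if (f == 1) {
        exon_lens <- c(300L, 200L); intron_lens <- 150L
      } else {
        exon_lens <- sample(seq(400L, 600L, 20L), 1); intron_lens <- integer()
      }
      for (k in seq_len(sizes[f])) {
        gene_no <- gene_no + 1L
        id <- sprintf("canH%02d", gene_no)
        rows[[length(rows) + 1]] <- make_gene(
          id, id, "canonical_histone", "chrT1", "+", cursor,
          exon_lens, intron_lens, utr5_len = 50L, utr3_len = 60L,
          family = sprintf("fam%02d", f)
        )
        cursor <- cursor + sum(exon_lens) + sum(intron_lens) + gap
      }
    }

    layout_class <- function(n, prefix, class_label, chrom) {
      cursor <- 0L
      out <- vector("list", n)
      for (i in seq_len(n)) {
        if (i == 1) {
          exon_lens <- c(350L, 250L); intron_lens <- 200L
          u5 <- 40L; u3 <- 80L
        } else {
          n_ex <- sample(1:3, 1)
          exon_lens <- sample(seq(200L, 600L, 50L), n_ex, replace = TRUE)
          intron_lens <- if (n_ex > 1) {
            sample(seq(100L, 400L, 50L), n_ex - 1, replace = TRUE)
          } else integer()
          u5 <- 40L; u3 <- 60L
        }
        id <- sprintf("%s%03d", prefix, i)
        out[[i]] <- make_gene(id, id, class_label, chrom, "+", cursor,
                              exon_lens, intron_lens, u5, u3)
        cursor <- cursor + sum(exon_lens) + sum(intron_lens) + gap
      }
      out
    }

    rows <- c(rows,
              layout_class(config$n_variant, "varH", "variant_histone", "chrT2"),
              layout_class(config$n_unchanging, "stab", "unchanging_candidate",
                           "chrT3"),
              layout_class(config$n_de, "degn", "other", "chrT4"))
    genes <- dplyr::bind_rows(rows)

    meanlog <- log(config$baseline_mean) - config$baseline_sdlog^2 / 2
    genes$base_mean <- stats::rlnorm(nrow(genes), meanlog,
                                     config$baseline_sdlog)
    n_up <- ceiling(config$n_de / 2)
    genes$true_fc <- dplyr::case_when(
      genes$class_label == "canonical_histone" ~ config$fc_canonical,
      genes$class_label == "variant_histone" ~ config$fc_variant,
      genes$class_label == "other" &
        seq_len(nrow(genes)) %in%
          which(genes$class_label == "other")[seq_len(n_up)] ~ config$fc_de_up,
      genes$class_label == "other" ~ config$fc_de_down,
      TRUE ~ 1
    )
    gene_annotation(genes)
  })
}

#' Ground-truth table for a generated annotation
#'
#' @param annotation Output of [build_toy_genome()].
#' @param clip_truth Optional `truth` tibble from [simulate_clip_peaks()] to
#'   merge in as a `clip_label` column.
#' @return A tibble with `gene_id`, `class_label`, `family`, `base_mean`,
#'   `true_fc` (and `clip_label` when supplied).
#' @export
ground_truth <- function(annotation, clip_truth = NULL) {
  out <- tibble(
    gene_id = annotation$gene_id,
    class_label = annotation$class_label,
    family = annotation$family,
    base_mean = annotation$base_mean,
    true_fc = annotation$true_fc
  )
  if (!is.null(clip_truth)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(clip_truth, "gene_id", clip_label = "enriched"),
      by = "gene_id"
    )
  }
  out
}

#' Simulate an alignment table for one sample
#'
#' Per-gene read counts are negative-binomial with mean `base_mean *
#' true_fc` for case samples (`base_mean` for controls) and the configured
#' dispersion. Read positions are uniform over the gene's exon union
#' (always fully exonic). A read originating from a canonical family member
#' is emitted once at every copy of the family — identical copies are
#' indistinguishable to an aligner — with `n_mappings` equal to the family
#' size; reads from unique genes have `n_mappings = 1`. No cap is applied
#' at generation time.
#'
#' @param annotation Output of [build_toy_genome()].
#' @param config The [sim_config()] used to build it.
#' @param group `"case"` or `"control"`.
#' @param sample_index 1-based index within the group.
#' @param seed Master seed (defaults to `config$seed`); the per-sample
#'   substream is derived from it by a fixed offset.
#'
#' @return A tibble with columns `read_id`, `chrom`, `start`, `end`,
#'   `n_mappings`. Records sharing a `read_id` share `n_mappings`, and the
#'   weights `1/n_mappings` of one read sum to exactly 1.
#' @export
simulate_alignments <- function(annotation, config,
                                group = c("case", "control"),
                                sample_index, seed = config$seed) {
  group <- match.arg(group)
  stream <- seed_streams[[group]] + as.integer(sample_index)
  rl <- config$read_length
  withr::with_seed(derive_seed(seed, stream), {
    mu <- annotation$base_mean *
      (if (group == "case") annotation$true_fc else 1)
    if (!is.null(config$library_size)) {
      mu <- mu * config$library_size / sum(annotation$base_mean)
    }
    counts <- rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)

    fam <- annotation$family
    fam_key <- ifelse(is.na(fam), paste0(".solo.", annotation$gene_id), fam)
    fam_members <- split(seq_len(nrow(annotation)), fam_key)

    prefix <- paste0(group, sample_index)
    acc_id <- vector("list", nrow(annotation))
    acc_chrom <- vector("list", nrow(annotation))
    acc_start <- vector("list", nrow(annotation))
    acc_n <- vector("list", nrow(annotation))
    for (gi in seq_len(nrow(annotation))) {
      n <- counts[gi]
      if (n == 0) next
      ex <- annotation$exons[[gi]]
      lens <- ex$end - ex$start
      w <- pmax(lens - rl + 1L, 0L)
      eidx <- sample.int(nrow(ex), n, replace = TRUE, prob = w)
      within <- as.integer(floor(runif(n) * (w[eidx])))
      copies <- fam_members[[fam_key[gi]]]
      k <- length(copies)
      ids <- sprintf("%s_%s_%d", prefix, annotation$gene_id[gi], seq_len(n))
      starts <- integer(0)
      for (j in seq_len(k)) {
        cex <- annotation$exons[[copies[j]]]
        starts <- c(starts, cex$start[eidx] + within)
      }
      acc_id[[gi]] <- rep(ids, k)
      acc_chrom[[gi]] <- rep(annotation$chrom[copies], each = n)
      acc_start[[gi]] <- starts
      acc_n[[gi]] <- rep.int(k, n * k)
    }
    start <- as.integer(unlist(acc_start))
    tibble(read_id = as.character(unlist(acc_id)),
           chrom = as.character(unlist(acc_chrom)),
           start = start, end = start + rl,
           n_mappings = as.integer(unlist(acc_n)))
  })
}

#' Simulate CLIP binding clusters over a toy genome
#'
#' Each gene independently receives at least one peak with probability
#' `p_enriched` (genes in `enriched_set`) or `p_background` (all others).
#' Peaks are placed inside a randomly chosen feature (exon, intron or UTR
#' interval) of the gene. Ground-truth labels are returned alongside the
#' BED-style peak table.
#'
#' @param annotation An [gene_annotation()].
#' @param enriched_set Character vector of gene ids with elevated binding.
#' @param p_enriched,p_background Peak probabilities, with
#'   `0 <= p_background <= p_enriched <= 1`.
#' @param seed Integer seed.
#' @param peak_width Peak width in bases (clipped to the host feature).
#'
#' @return A list with `peaks` (tibble: `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`) and `truth` (tibble: `gene_id`, `enriched`,
#'   `bound`).
#' @export
simulate_clip_peaks <- function(annotation, enriched_set,
                                p_enriched = 0.8, p_background = 0.2,
                                seed = 1L, peak_width = 30L) {
  if (!(p_background >= 0 && p_background <= p_enriched && p_enriched <= 1)) {
    abort("need 0 <= p_background <= p_enriched <= 1")
  }
  unknown <- setdiff(enriched_set, annotation$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("enriched_set genes not in annotation: ",
                 paste(unknown, collapse = ", ")))
  }
  introns <- introns_of(annotation)
  withr::with_seed(as.integer(seed), {
    peak_rows <- list()
    truth <- tibble(gene_id = annotation$gene_id,
                    enriched = annotation$gene_id %in% enriched_set,
                    bound = FALSE)
    for (i in seq_len(nrow(annotation))) {
      p <- if (truth$enriched[i]) p_enriched else p_background
      if (runif(1) >= p) next
      truth$bound[i] <- TRUE
      g_introns <- introns[introns$gene_id == annotation$gene_id[i], ]
      feats <- dplyr::bind_rows(
        annotation$exons[[i]], annotation$utr5[[i]], annotation$utr3[[i]],
        tibble(start = g_introns$start, end = g_introns$end)
      )
      n_peaks <- 1L + rbinom(1, 1, 0.3)
      for (j in seq_len(n_peaks)) {
        fi <- sample.int(nrow(feats), 1)
        len <- feats$end[fi] - feats$start[fi]
        w <- min(peak_width, len)
        s <- feats$start[fi] + floor(runif(1) * (len - w + 1))
        peak_rows[[length(peak_rows) + 1]] <- tibble(
          chrom = annotation$chrom[i],
          start = as.integer(s), end = as.integer(s + w),
          name = sprintf("peak_%s_%d", annotation$gene_id[i], j),
          score = 0L, strand = "."
        )
      }
    }
    peaks <- if (length(peak_rows) > 0) dplyr::bind_rows(peak_rows) else {
      tibble(chrom = character(), start = integer(), end = integer(),
             name = character(), score = integer(), strand = character())
    }
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate a qPCR Ct table
#'
#' Target Ct values are generated as the housekeeping mean Ct minus
#' log2(true expression ratio), plus Gaussian noise, for every sample of
#' the configured groups. Ratios may be given per group and per priming
#' mode; when a `priming` column is present both priming labels are
#' emitted, emulating paired oligo-dT / random-hexamer assays.
#'
#' @param config A [sim_config()] (supplies group sizes and the seed).
#' @param ratios A tibble with columns `gene`, `ratio`, and optionally
#'   `group` (default: the ratio applies to the case group, controls get 1)
#'   and `priming` (default `"random_hexamer"`).
#' @param hk_ct Named numeric: baseline Ct of each housekeeping gene.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed Integer seed.
#'
#' @return A tibble with `sample_id`, `group`, `gene`, `priming`, `ct`.
#' @export
simulate_ct_table <- function(config, ratios,
                              hk_ct = c(Gapdh = 18, Actb = 21),
                              noise_sd = 0.2, seed = config$seed) {
  ratios <- as_tibble(ratios)
  if (any(ratios$ratio <= 0)) abort("ratios must be > 0")
  if (!"priming" %in% names(ratios)) ratios$priming <- "random_hexamer"
  if (!"group" %in% names(ratios)) {
    ratios <- dplyr::bind_rows(
      dplyr::mutate(ratios, group = "case"),
      dplyr::mutate(ratios, group = "control", ratio = 1)
    )
  }
  samples <- tibble(
    sample_id = c(paste0("case_", seq_len(config$n_case)),
                  paste0("control_", seq_len(config$n_control))),
    group = c(rep("case", config$n_case), rep("control", config$n_control))
  )
  hk_mean <- mean(hk_ct)
  withr::with_seed(derive_seed(seed, seed_streams$ct), {
    out <- list()
    for (pr in unique(ratios$priming)) {
      for (si in seq_len(nrow(samples))) {
        s <- samples[si, ]
        hk_rows <- tibble(
          sample_id = s$sample_id, group = s$group,
          gene = names(hk_ct), priming = pr,
          ct = unname(hk_ct) + rnorm(length(hk_ct), 0, noise_sd)
        )
        r <- ratios[ratios$priming == pr & ratios$group == s$group, ]
        tg_rows <- tibble(
          sample_id = s$sample_id, group = s$group,
          gene = r$gene, priming = pr,
          ct = hk_mean - log2(r$ratio) + rnorm(nrow(r), 0, noise_sd)
        )
        out[[length(out) + 1]] <- dplyr::bind_rows(hk_rows, tg_rows)
      }
    }
    dplyr::bind_rows(out)
  })
}
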