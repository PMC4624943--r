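prep_ct <- function(ct, priming) {
  ct <- as_tibble(ct)
  if (any(ct$ct <= 0)) abort("Ct values must be > 0")
  if (!is.null(priming)) {
    if (!priming %in% unique(ct$priming)) {
      abort(paste0("priming mode absent from table: ", priming))
    }
    ct <- ct[ct$priming == priming, ]
  }
  # technical replicates are averaged on the Ct scale before analysis
  dplyr::summarise(
    dplyr::group_by(ct, .data$sample_id, .data$group, .data$gene),
    ct = mean(.data$ct), .groups = "drop"
  )
}

#' Comparative-CT relative expression
#'
#' Implements the comparative CT method with multi-housekeeping
#' normalization: per sample, `dCt = Ct(target) - mean(Ct(housekeepers))`
#' (the arithmetic mean of housekeeping Ct values equals the geometric mean
#' of housekeeping expression on the `2^-Ct` scale), then `2^-dCt` scaled
#' so the reference group averages 1. Amplification efficiency is fixed at
#' a perfect doubling per cycle. Technical replicates (duplicate
#' `(sample, gene, priming)` rows) are averaged on the Ct scale first.
#'
#' @param ct Ct tibble with columns `sample_id`, `group`, `gene`,
#'   `priming`, `ct` (e.g. from [simulate_ct_table()]).
#' @param target_gene Gene to quantify.
#' @param housekeeping Character vector of housekeeping genes (default
#'   `Gapdh` and `Actb`).
#' @param reference_group Group whose mean relative expression anchors to 1.
#' @param priming Optional priming mode to restrict to (required when the
#'   table mixes modes).
#'
#' @return A tibble with `sample_id`, `group`, `relative_expression`.
#' @export
relative_expression <- function(ct, target_gene,
                                housekeeping = c("Gapdh", "Actb"),
                                reference_group = "control",
                                priming = NULL) {
  avg <- prep_ct(ct, priming)
  if (!reference_group %in% unique(avg$group)) {
    abort(paste0("reference_group absent from table: ", reference_group))
  }
  samples <- unique(avg$sample_id)
  rows <- purrr::map_dfr(samples, function(s) {
    sub <- avg[avg$sample_id == s, ]
    hk <- sub$ct[match(housekeeping, sub$gene)]
    if (anyNA(hk)) {
      miss <- housekeeping[is.na(hk)]
      abort(paste0("sample ", s, " is missing housekeeper(s): ",
                   paste(miss, collapse = ", ")))
    }
    tg <- sub$ct[sub$gene == target_gene]
    if (length(tg) != 1) {
      abort(paste0("sample ", s, " is missing target gene ", target_gene))
    }
    tibble(sample_id = s, group = sub$group[1],
           dct = tg - mean(hk))
  })
  rows$rel <- 2^(-rows$dct)
  anchor <- mean(rows$rel[rows$group == reference_group])
  tibble(sample_id = rows$sample_id, group = rows$group,
         relative_expression = rows$rel / anchor)
}

#' Oligo-dT to random-hexamer expression ratio
#'
#' Indexes a transcript's polyadenylation status: relative expression under
#' oligo-dT priming (polyadenylated RNA only) divided by relative
#' expression under random-hexamer priming (all RNA), each computed by
#' [relative_expression()] under its own priming with matched-priming
#' housekeepers.
#'
#' @inheritParams relative_expression
#' @param gene Gene to quantify.
#'
#' @return A tibble with `sample_id`, `group`, `ratio`.
#' @export
polyadenylation_ratio <- function(ct, gene,
                                  housekeeping = c("Gapdh", "Actb"),
                                  reference_group = "control") {
  modes <- unique(ct$priming)
  for (m in c("oligo_dT", "random_hexamer")) {
    if (!m %in% modes) abort(paste0("missing priming mode: ", m))
  }
  dt <- relative_expression(ct, gene, housekeeping, reference_group,
                            priming = "oligo_dT")
  hex <- relative_expression(ct, gene, housekeeping, reference_group,
                             priming = "random_hexamer")
  joined <- dplyr::inner_join(
    dplyr::rename(dt, rel_dt = "relative_expression"),
    dplyr::rename(hex, rel_hex = "relative_expression"),
    by = c("sample_id", "group")
  )
  tibble(sample_id = joined$sample_id, group = joined$group,
         ratio = joined$rel_dt / joined$rel_hex)
}
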