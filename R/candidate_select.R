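# The screen's transcript-selection filter on a quantification table.

require_columns <- function(table, cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    abort(paste0("missing column: ", paste(missing, collapse = ", ")))
  }
}

#' Select candidate transcripts from a quantification table
#'
#' Applies the three-part screen filter to per-transcript abundances, with
#' the published boundary semantics taken literally: expression strictly
#' above `fpkm_min` FPKM in Brn3a-WT RGCs ("more than"), a WT/KO fold
#' change of at least `fold_min` ("at least a two-fold differential"), and a
#' direction-free Brn3b WT/KO fold change strictly below `brn3b_fold_max`
#' ("less than two-fold", no Brn3b regulation). Fold ratios use a
#' pseudocount `epsilon` so transcripts absent in the knockout pass rather
#' than dividing by zero.
#'
#' @param table Tibble with columns `fpkm_brn3a_wt_rgc`,
#'   `fpkm_brn3a_ko_rgc`, `fpkm_brn3b_wt_rgc`, `fpkm_brn3b_ko_rgc`.
#' @param fpkm_min Strict lower bound on WT RGC FPKM.
#' @param fold_min Inclusive lower bound on the WT/KO fold change.
#' @param brn3b_fold_max Strict upper bound on the Brn3b |fold| change.
#' @param epsilon Pseudocount added to numerator and denominator of folds.
#' @return The input with audit columns `pass_expression`,
#'   `pass_brn3a_fold`, `pass_brn3b` and the combined `selected`.
#' @export
select_candidates <- function(table, fpkm_min = 2, fold_min = 2,
                              brn3b_fold_max = 2, epsilon = 0.1) {
  require_columns(table, c("fpkm_brn3a_wt_rgc", "fpkm_brn3a_ko_rgc",
                           "fpkm_brn3b_wt_rgc", "fpkm_brn3b_ko_rgc"))
  abun <- c("fpkm_brn3a_wt_rgc", "fpkm_brn3a_ko_rgc",
            "fpkm_brn3b_wt_rgc", "fpkm_brn3b_ko_rgc")
  if (any(vapply(table[abun], function(x) any(x < 0), logical(1)))) {
    abort("negative abundance")
  }
  table %>% mutate(
    pass_expression = .data$fpkm_brn3a_wt_rgc > fpkm_min,
    brn3a_fold = (.data$fpkm_brn3a_wt_rgc + epsilon) /
      (.data$fpkm_brn3a_ko_rgc + epsilon),
    pass_brn3a_fold = .data$brn3a_fold >= fold_min,
    brn3b_fold = pmax(
      (.data$fpkm_brn3b_wt_rgc + epsilon) / (.data$fpkm_brn3b_ko_rgc + epsilon),
      (.data$fpkm_brn3b_ko_rgc + epsilon) / (.data$fpkm_brn3b_wt_rgc + epsilon)
    ),
    pass_brn3b = .data$brn3b_fold < brn3b_fold_max,
    selected = .data$pass_expression & .data$pass_brn3a_fold & .data$pass_brn3b
  )
}

#' Gene-level enrichment and dependency flags from CPM columns
#'
#' Applies the same pseudocounted two-fold rules at gene level:
#' `rgc_enriched` when RGC CPM is at least two-fold over whole retina, and
#' `brn3a_dependent` when WT RGC CPM is at least two-fold over KO.
#'
#' @param table Tibble with columns `cpm_brn3a_wt_rgc`, `cpm_brn3a_ko_rgc`,
#'   `cpm_retina` (one row per gene, or per transcript with repeated gene
#'   values).
#' @param fold_min Inclusive fold bound.
#' @param epsilon Pseudocount.
#' @return Per-gene tibble with `rgc_enriched` and `brn3a_dependent`.
#' @export
gene_level_flags <- function(table, fold_min = 2, epsilon = 0.1) {
  require_columns(table, c("cpm_brn3a_wt_rgc", "cpm_brn3a_ko_rgc",
                           "cpm_retina"))
  cols <- c("cpm_brn3a_wt_rgc", "cpm_brn3a_ko_rgc", "cpm_retina")
  if (any(vapply(table[cols], function(x) any(x < 0), logical(1)))) {
    abort("negative abundance")
  }
  key <- if ("gene_id" %in% names(table)) "gene_id" else names(table)[1]
  table %>%
    distinct(dplyr::across(dplyr::all_of(c(key, cols)))) %>%
    mutate(
      rgc_enriched = (.data$cpm_brn3a_wt_rgc + epsilon) /
        (.data$cpm_retina + epsilon) >= fold_min,
      brn3a_dependent = (.data$cpm_brn3a_wt_rgc + epsilon) /
        (.data$cpm_brn3a_ko_rgc + epsilon) >= fold_min
    ) %>%
    select(dplyr::all_of(key), "rgc_enriched", "brn3a_dependent")
}
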