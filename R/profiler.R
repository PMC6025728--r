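# Aggregation of per-age call records into gene-level developmental
# summaries (enrichment/dependency flags, onset/peak/offset, sparseness)
# and the headline panel counts.

age_sort <- function(ages) ages[order(age_index(ages))]

#' Summarize one gene's five-age call records into a profile row
#'
#' Flags come from significant directional calls: `gcl_p3` and
#' `brn3a_target_p3` from the P3 enrichment/dependency calls,
#' `gcl_consistent` from the at-least-4-of-5-ages rule, `brn3a_target_any`
#' from any age. The developmental profile is read off the per-age GCL
#' expression series (stain-score means): onset is the earliest age with
#' signal above `3 * noise_mad`; peak is the age of maximal signal, with
#' contiguous ages within `peak_tol` of the maximum reported as a range
#' (earliest age first); offset is the earliest post-onset age where the
#' signal falls below threshold and stays below through P22.
#'
#' @param calls Call-record tibble for one gene (both comparisons, all five
#'   ages; enrichment calls taken from the WT genotype).
#' @param expression_series Tibble with columns `age` and `value` (per-age
#'   WT GCL stain score, e.g. the mean over ROIs).
#' @param noise_mad Robust scale of the measurement noise; the detection
#'   threshold is `3 * noise_mad`.
#' @param peak_tol Relative tolerance for calling a plateau around the peak.
#' @param sparse Logical sparse-expression flag (from [sparse_flag()]).
#' @return A one-row tibble (gene summary).
#' @export
summarize_gene <- function(calls, expression_series, noise_mad = 1,
                           peak_tol = 0.1, sparse = FALSE) {
  calls <- as_tibble(calls)
  series <- as_tibble(expression_series) %>%
    mutate(age = as.character(.data$age)) %>%
    arrange(age_index(.data$age))
  gene <- unique(calls$gene)
  if (length(gene) != 1) abort("calls must cover exactly one gene")

  enr <- calls %>% filter(.data$comparison == "enrichment")
  dep <- calls %>% filter(.data$comparison == "dependency")
  for (d in list(enr, dep)) {
    missing <- setdiff(AGES, d$age)
    if (length(missing)) {
      abort(paste0("missing age in call records: ",
                   paste(missing, collapse = ", ")))
    }
  }
  enr_by_age <- vapply(AGES, function(a) any(enr$call[enr$age == a]),
                       logical(1))
  dep_by_age <- vapply(AGES, function(a) any(dep$call[dep$age == a]),
                       logical(1))

  thr <- 3 * noise_mad
  vals <- setNames(series$value, series$age)
  above <- vals > thr
  onset <- if (any(above)) names(vals)[which(above)[1]] else NA_character_

  peak <- NA_character_
  if (any(above)) {
    mx <- max(vals)
    at_peak <- vals >= mx - peak_tol * abs(mx)
    peak_ages <- names(vals)[at_peak]
    # contiguous run containing the (earliest) maximum
    i_max <- which.max(vals)
    run <- i_max
    while (run[1] > 1 && at_peak[run[1] - 1]) run <- c(run[1] - 1, run)
    while (run[length(run)] < length(vals) && at_peak[run[length(run)] + 1]) {
      run <- c(run, run[length(run)] + 1)
    }
    peak <- if (length(run) > 1) {
      paste(names(vals)[run[1]], names(vals)[run[length(run)]], sep = "-")
    } else {
      names(vals)[run]
    }
  }

  offset <- NA_character_
  if (!is.na(onset)) {
    i_on <- which(names(vals) == onset)
    later <- seq_along(vals) > i_on
    below_and_stays <- vapply(seq_along(vals), function(i) {
      later[i] && all(!above[i:length(vals)])
    }, logical(1))
    if (any(below_and_stays)) {
      offset <- names(vals)[which(below_and_stays)[1]]
    }
  }

  tibble(
    gene = gene,
    gcl_p3 = unname(enr_by_age["P3"]),
    gcl_consistent = sum(enr_by_age) >= 4,
    brn3a_target_p3 = unname(dep_by_age["P3"]),
    brn3a_target_any = any(dep_by_age),
    onset = onset, peak = peak, offset = offset,
    sparse = sparse
  )
}

#' Developmentally consistent genotype dependency
#'
#' A gene counts as a consistent Brn3a target when it has a significant
#' dependency call at 4 or more of the 5 postnatal ages — the same
#' convention the gene-summary table states for consistent GCL enrichment.
#'
#' @param dependent Named (by age) or 5-long logical vector of per-age
#'   dependency calls, or a call-record tibble with `comparison ==
#'   "dependency"` rows.
#' @return Logical.
#' @export
#' @examples
#' consistent_dependency(c(P0 = TRUE, P3 = FALSE, P7 = TRUE,
#'                         P14 = TRUE, P22 = TRUE))
consistent_dependency <- function(dependent) {
  if (is.data.frame(dependent)) {
    dep <- dependent %>% filter(.data$comparison == "dependency")
    dependent <- setNames(dep$call, dep$age)
  }
  missing <- setdiff(AGES, names(dependent))
  if (is.null(names(dependent))) {
    if (length(dependent) != 5) abort("need calls for all 5 ages")
  } else if (length(missing)) {
    abort(paste0("missing age: ", paste(missing, collapse = ", ")))
  }
  sum(dependent) >= 4
}

#' Panel-level counts over a gene-summary table
#'
#' @param summary_table Gene-summary tibble (one row per gene) with logical
#'   columns `gcl_p3`, `brn3a_target_p3`, `brn3a_target_any` and optionally
#'   `gcl_consistent` and `consistent_dependency`.
#' @return One-row tibble of counts and integer-rounded percentages.
#' @export
panel_counts <- function(summary_table) {
  if (!nrow(summary_table)) abort("summary table is empty")
  n <- nrow(summary_table)
  cnt <- function(col) {
    if (col %in% names(summary_table)) sum(summary_table[[col]], na.rm = TRUE)
    else NA_integer_
  }
  tibble(
    n_genes = n,
    n_gcl_p3 = cnt("gcl_p3"),
    n_gcl_consistent = cnt("gcl_consistent"),
    n_brn3a_p3 = cnt("brn3a_target_p3"),
    n_brn3a_any = cnt("brn3a_target_any"),
    n_consistent_dependency = cnt("consistent_dependency"),
    pct_gcl_p3 = round(100 * .data$n_gcl_p3 / n),
    pct_brn3a_any = round(100 * .data$n_brn3a_any / n)
  )
}
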