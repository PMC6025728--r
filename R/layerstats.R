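# Two-sample Kolmogorov-Smirnov machinery and the two comparison types used
# throughout the screen: GCL-vs-inner-layer enrichment and WT-vs-KO GCL
# genotype dependency, with figure-legend star levels.

ks_statistic <- function(a, b) {
  x <- sort(unique(c(a, b)))
  fa <- vapply(x, function(v) mean(a <= v), numeric(1))
  fb <- vapply(x, function(v) mean(b <= v), numeric(1))
  max(abs(fa - fb))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup_x |F_a(x) - F_b(x)|` over the right-continuous
#' empirical CDFs (ties handled naturally by the right-continuous
#' convention). The two-sided p-value is exact — obtained by enumerating all
#' `choose(n1 + n2, n1)` assignments of the pooled values to the two labels —
#' whenever `n1 + n2 <= exact_limit`, which covers the 6-9-observation ROI
#' samples this test is used on. For larger samples the asymptotic series
#' `p = 2 * sum_k (-1)^(k-1) exp(-2 k^2 m D^2)` with
#' `m = n1 n2 / (n1 + n2)` is used, truncated when terms fall below 1e-12
#' and clamped to `(0, 1]`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_limit Maximal pooled size for exact enumeration.
#' @return An object of class `ks2_test` with elements `statistic`,
#'   `p.value`, `n1`, `n2`, `method` (`"exact"` or `"asymptotic"`).
#' @seealso [star_level()], [enrichment_call()], [dependency_call()]
#' @export
#' @examples
#' ks2(c(1, 2, 3), c(4, 5, 6))  # D = 1, exact p = 2 / choose(6, 3) = 0.1
ks2 <- function(a, b, exact_limit = 16) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) abort("samples must not contain NA")
  n1 <- length(a); n2 <- length(b)
  d <- ks_statistic(a, b)

  if (n1 + n2 <= exact_limit) {
    pooled <- c(a, b)
    idx <- combn(n1 + n2, n1)
    d_perm <- apply(idx, 2, function(i) {
      ks_statistic(pooled[i], pooled[-i])
    })
    p <- mean(d_perm >= d - 1e-12)
    method <- "exact"
  } else {
    m <- n1 * n2 / (n1 + n2)
    p <- 0; k <- 1
    if (d == 0) p <- 0.5  # degenerate: series diverges termwise; p clamps to 1
    else repeat {
      term <- (-1)^(k - 1) * exp(-2 * k^2 * m * d^2)
      p <- p + term
      if (abs(term) < 1e-12 || k > 1000) break
      k <- k + 1
    }
    p <- 2 * p
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "asymptotic"
  }
  structure(
    list(statistic = d, p.value = p, n1 = n1, n2 = n2, method = method),
    class = "ks2_test"
  )
}

#' @export
print.ks2_test <- function(x, ...) {
  cat(sprintf("Two-sample KS test (%s): D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p.value, x$n1, x$n2))
  invisible(x)
}

#' @method tidy ks2_test
#' @export
tidy.ks2_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         n1 = x$n1, n2 = x$n2, method = x$method,
         stars = star_level(x$p.value))
}

#' @method glance ks2_test
#' @export
glance.ks2_test <- function(x, ...) tidy(x)

#' Significance star level
#'
#' Strict figure-legend thresholds: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, otherwise `ns` (so p = 0.05 itself is `ns`).
#'
#' @param p p-value(s) in (0, 1].
#' @return Character vector over `{ns, *, **, ***}`.
#' @export
star_level <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p must lie in (0, 1]")
  }
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

call_record <- function(comparison, test, direction, call, gene, age,
                        genotype, reference) {
  stars <- star_level(test$p.value)
  tibble(
    comparison = comparison, gene = gene, age = age, genotype = genotype,
    reference = reference, n1 = test$n1, n2 = test$n2,
    statistic = test$statistic, p_value = test$p.value, method = test$method,
    direction = direction, stars = stars,
    call = call && stars != "ns"
  )
}

#' GCL-enrichment call for one condition
#'
#' Runs [ks2()] on the GCL sample against the inner reference layer sample
#' (NBL at P0/P3, INL from P7). The directional gate uses sample medians: the
#' comparison is only called an enrichment when it is significant *and* the
#' GCL median exceeds the inner median. Samples are stain-oriented values
#' (IPL-normalized from P3; background-minus-raw at P0), pooled ROI means
#' across the images of the condition.
#'
#' @param gcl_sample,inner_sample Numeric stain-score samples.
#' @param gene,age,genotype Condition labels carried into the record.
#' @param reference Inner reference layer label.
#' @param ... Passed to [ks2()].
#' @return A one-row call-record tibble; `call` is the enrichment verdict.
#' @export
enrichment_call <- function(gcl_sample, inner_sample, gene = NA, age = NA,
                            genotype = NA, reference = "INL", ...) {
  test <- ks2(gcl_sample, inner_sample, ...)
  mg <- median(gcl_sample); mi <- median(inner_sample)
  direction <- if (mg > mi) "higher_in_GCL" else if (mg < mi) "lower_in_GCL"
  else "none"
  call_record("enrichment", test, direction,
              direction == "higher_in_GCL", gene, age, genotype, reference)
}

#' Genotype-dependency call for one age
#'
#' Compares WT and KO GCL stain scores with [ks2()]; the gene is called
#' Brn3a-dependent at that age only when the difference is significant and
#' the WT median exceeds the KO median (expression lost in the knockout).
#'
#' @param wt_gcl_sample,ko_gcl_sample Numeric stain-score samples.
#' @inheritParams enrichment_call
#' @return A one-row call-record tibble; `call` is the dependency verdict.
#' @export
dependency_call <- function(wt_gcl_sample, ko_gcl_sample, gene = NA, age = NA,
                            ...) {
  test <- ks2(wt_gcl_sample, ko_gcl_sample, ...)
  mw <- median(wt_gcl_sample); mk <- median(ko_gcl_sample)
  direction <- if (mw > mk) "higher_in_WT" else if (mw < mk) "lower_in_WT"
  else "none"
  call_record("dependency", test, direction,
              direction == "higher_in_WT", gene, age, "WT_vs_KO", "GCL")
}
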