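# Shared helpers: primer design against synthetic panels and independent
# brute-force oracles used by the dual-route tests.

rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

exon_seq <- function(panel, label) {
  i <- match(label, panel$exons$label)
  substring(panel$genome, panel$exons$start[i] + 1, panel$exons$end[i])
}

# Forward primer at the 5' end of one exon, reverse primer at the 3' end of
# another (or the same) exon.
design_pair <- function(panel, name, f_exon, r_exon, len = 20) {
  fe <- exon_seq(panel, f_exon)
  re <- exon_seq(panel, r_exon)
  list(
    name = name,
    forward = substr(fe, 1, len),
    reverse = rc(substr(re, nchar(re) - len + 1, nchar(re)))
  )
}

# Independent oracle for product prediction: naive double scan over every
# start position, no shared code with predict_products().
oracle_products <- function(fwd, rev, seq) {
  rrc <- rc(rev)
  lens <- integer(0)
  n <- nchar(seq)
  for (i in seq_len(n - nchar(fwd) + 1)) {
    if (substring(seq, i, i + nchar(fwd) - 1) != fwd) next
    for (j in seq_len(n - nchar(rrc) + 1)) {
      if (substring(seq, j, j + nchar(rrc) - 1) != rrc) next
      end <- j + nchar(rrc) - 1
      if (j >= i && end - i + 1 >= max(nchar(fwd), nchar(rrc))) {
        lens <- c(lens, end - i + 1)
      }
    }
  }
  sort(lens)
}

# Independent oracle for band-pattern consistency: enumerate every subset
# directly from the definition.
oracle_minimal_subsets <- function(ids, predictions, observations, tol = 0.1) {
  match_size <- function(o, p) abs(o - p) <= tol * p
  consistent <- function(members) {
    for (i in seq_len(nrow(observations))) {
      pr <- predictions[predictions$pair == observations$pair[i] &
                          predictions$transcript_id %in% members, ]
      if (observations$outcome[i] == "negative") {
        if (nrow(pr) > 0) return(FALSE)
      } else {
        sizes <- observations$sizes[[i]]
        if (nrow(pr) == 0 || length(sizes) == 0) return(FALSE)
        for (s in sizes) if (!any(match_size(s, pr$product_bp))) return(FALSE)
        for (p in pr$product_bp) if (!any(match_size(sizes, p))) return(FALSE)
      }
    }
    TRUE
  }
  all_subsets <- unlist(lapply(0:length(ids), function(k) {
    if (k == 0) list(character(0)) else
      apply(combn(ids, k), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  cons <- Filter(consistent, all_subsets)
  minimal <- Filter(function(s) {
    !any(vapply(cons, function(t) {
      length(t) < length(s) && all(t %in% s)
    }, logical(1)))
  }, cons)
  lapply(minimal, sort)
}

canon_subsets <- function(subsets) {
  unname(lapply(subsets, sort))[order(vapply(subsets, function(s) {
    paste(sort(s), collapse = "|")
  }, character(1)))]
}
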