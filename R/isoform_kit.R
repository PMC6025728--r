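# Transcript-model arithmetic: splicing, in-silico PCR, band-pattern based
# transcript support inference, and riboprobe QC.

check_acgt <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    abort(paste0(what, " must be a non-empty string"))
  }
  if (grepl("[^ACGT]", seq)) {
    abort(paste0(what, " contains non-ACGT characters"))
  }
  invisible(seq)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Construct a transcript isoform model
#'
#' @param id Transcript identifier.
#' @param exons Data frame with columns `label`, `start`, `end` (0-based
#'   half-open genomic intervals); must be sorted and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @return A `transcript_model`.
#' @export
transcript_model <- function(id, exons, strand = "+") {
  exons <- as_tibble(exons)
  stopifnot(all(c("label", "start", "end") %in% names(exons)))
  exons <- exons %>% arrange(.data$start)
  if (any(exons$end <= exons$start)) abort("empty exon interval")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    abort("overlapping exons")
  }
  structure(list(id = id, strand = strand, exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s strand): %s\n", x$id, x$strand,
              paste(x$exons$label, collapse = "-")))
  invisible(x)
}

#' Spliced sequence of a transcript model
#'
#' Concatenates the exon substrings of the genome (0-based half-open
#' coordinates); minus-strand models are reverse-complemented.
#'
#' @param model A [transcript_model()].
#' @param genome Genome sequence (character scalar).
#' @return The spliced transcript sequence.
#' @export
splice <- function(model, genome) {
  stopifnot(inherits(model, "transcript_model"))
  if (any(model$exons$start < 0) || any(model$exons$end > nchar(genome))) {
    abort("exon out of genome bounds")
  }
  parts <- substring(genome, model$exons$start + 1, model$exons$end)
  out <- paste(parts, collapse = "")
  if (model$strand == "-") out <- revcomp(out)
  out
}

# Spliced-coordinate position (1-based) of the last base of each exon.
exon_boundaries <- function(model) {
  cumsum(model$exons$end - model$exons$start)
}

find_all <- function(haystack, needle) {
  hits <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Predict in-silico PCR products of a primer pair on isoform models
#'
#' Matches the forward primer and the reverse complement of the reverse
#' primer exactly (no mismatches) on each spliced sequence, and reports one
#' product per orientation-ordered site pair. The product length runs from
#' the first base of the forward site through the last base of the reverse
#' site inclusive; a primer pair may yield several products on one
#' transcript. Exon-exon junctions spanned by each product are reported
#' using the models' exon labels.
#'
#' @param pair List or one-row data frame with `name`, `forward`, `reverse`,
#'   and optionally `t3_appended` (adds 26 nt to the reported extended
#'   length, the T3 promoter used for riboprobe transcription).
#' @param models List of [transcript_model()]s.
#' @param sequences Named character of spliced sequences; computed from
#'   `genome` when omitted.
#' @param genome Genome string (used when `sequences` is missing).
#' @return Tibble with `pair`, `transcript_id`, `product_bp`,
#'   `extended_bp`, `junctions`, `f_start`, `r_end` (one row per product;
#'   transcripts with no product contribute no rows).
#' @export
predict_products <- function(pair, models, sequences = NULL, genome = NULL) {
  fwd <- toupper(pair$forward[[1]]); rev <- toupper(pair$reverse[[1]])
  check_acgt(fwd, "forward primer"); check_acgt(rev, "reverse primer")
  t3 <- isTRUE(pair$t3_appended[[1]])
  if (is.null(sequences)) {
    if (is.null(genome)) abort("provide sequences or genome")
    sequences <- purrr::map_chr(models, splice, genome = genome)
    names(sequences) <- purrr::map_chr(models, "id")
  }
  rev_rc <- revcomp(rev)

  purrr::map_dfr(models, function(model) {
    seq <- sequences[[model$id]]
    f_sites <- find_all(seq, fwd)
    r_sites <- find_all(seq, rev_rc)
    if (!length(f_sites) || !length(r_sites)) return(empty_predictions())
    bounds <- exon_boundaries(model)
    labs <- model$exons$label
    combos <- tidyr::expand_grid(f = f_sites, r = r_sites) %>%
      mutate(r_end = .data$r + nchar(rev_rc) - 1L) %>%
      filter(.data$r >= .data$f,
             .data$r_end - .data$f + 1L >= max(nchar(fwd), nchar(rev_rc)))
    if (!nrow(combos)) return(empty_predictions())
    purrr::pmap_dfr(combos, function(f, r, r_end) {
      spanned <- which(bounds >= f & bounds < r_end)
      junctions <- if (length(spanned)) {
        paste(paste(labs[spanned], labs[spanned + 1], sep = "_"),
              collapse = ",")
      } else ""
      tibble(
        pair = pair$name[[1]], transcript_id = model$id,
        product_bp = r_end - f + 1L,
        extended_bp = if (t3) r_end - f + 1L + 26L else NA_integer_,
        junctions = junctions, f_start = f, r_end = r_end
      )
    })
  })
}

#' Append the T3 promoter consensus to a reverse primer
#'
#' Prepends the 26-nt T3 promoter consensus used to transcribe the
#' antisense riboprobe from a PCR template, extending the product by
#' exactly 26 nt.
#'
#' @param primer Reverse primer sequence (ACGT).
#' @return Extended sequence `T3 consensus + primer`.
#' @export
#' @examples
#' nchar(append_t3("GCTAGCCCCACGGCTTTC")) - nchar("GCTAGCCCCACGGCTTTC")  # 26
append_t3 <- function(primer) {
  check_acgt(toupper(primer), "primer")
  paste0(t3_promoter(), toupper(primer))
}

#' The T3 promoter consensus sequence
#' @return 26-nt character scalar.
#' @export
t3_promoter <- function() "GGAGCAAATTAACCCTCACTAAAGGG"

empty_predictions <- function() {
  tibble(pair = character(0), transcript_id = character(0),
         product_bp = integer(0), extended_bp = integer(0),
         junctions = character(0), f_start = integer(0), r_end = integer(0))
}

sizes_match <- function(observed, predicted, tol) {
  abs(observed - predicted) <= tol * predicted
}

# A candidate subset S of transcripts is consistent with the band
# observations when (sensitivity assumed perfect):
#   * every negative pair has no predicted product on any member of S;
#   * for every positive pair, each observed band size matches a predicted
#     product of some member of S (within tolerance), and every product
#     predicted on members of S matches some observed band.
consistent_subsets <- function(ids, predictions, observations, tol) {
  n <- length(ids)
  # precompute, per observation, the predicted sizes of each candidate
  per_obs <- lapply(seq_len(nrow(observations)), function(i) {
    pr <- predictions[predictions$pair == observations$pair[i], ]
    list(
      negative = identical(observations$outcome[i], "negative"),
      sizes = observations$sizes[[i]],
      by_id = lapply(ids, function(id) {
        pr$product_bp[pr$transcript_id == id]
      })
    )
  })
  subsets <- list()
  for (mask in 0:(2^n - 1)) {
    in_s <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    ok <- TRUE
    for (ob in per_obs) {
      pred_sizes <- unlist(ob$by_id[in_s])
      if (ob$negative) {
        if (length(pred_sizes)) { ok <- FALSE; break }
      } else {
        if (!length(pred_sizes) || !length(ob$sizes)) { ok <- FALSE; break }
        obs_ok <- all(vapply(ob$sizes, function(s) {
          any(sizes_match(s, pred_sizes, tol))
        }, logical(1)))
        pred_ok <- all(vapply(pred_sizes, function(p) {
          any(sizes_match(ob$sizes, p, tol))
        }, logical(1)))
        if (!obs_ok || !pred_ok) { ok <- FALSE; break }
      }
    }
    if (ok) subsets[[length(subsets) + 1]] <- ids[in_s]
  }
  subsets
}

minimal_subsets <- function(subsets) {
  keep <- vapply(seq_along(subsets), function(i) {
    !any(vapply(seq_along(subsets), function(j) {
      j != i && length(subsets[[j]]) < length(subsets[[i]]) &&
        all(subsets[[j]] %in% subsets[[i]])
    }, logical(1)))
  }, logical(1))
  subsets[keep]
}

# Candidate novel single-junction models: exon a spliced directly onto the
# downstream chain b..n of the exon universe.
novel_junction_models <- function(exon_universe, genome) {
  ex <- as_tibble(exon_universe) %>% arrange(.data$start)
  n <- nrow(ex)
  out <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      id <- paste0("novel_", ex$label[a], "_", ex$label[b])
      out[[id]] <- transcript_model(id, ex[c(a, b:n), ])
    }
  }
  out
}

#' Infer transcript support from RT-PCR band patterns
#'
#' Performs an exhaustive search over subsets of the candidate transcripts
#' for those consistent with every band observation, treating reaction
#' sensitivity as perfect: a negative reaction excludes every transcript the
#' pair is predicted to amplify, and a present transcript must account for
#' (and only for) observed band sizes within the gel tolerance. A
#' transcript is `supported` when it belongs to every minimal consistent
#' subset, `excluded` when it belongs to no consistent subset, and
#' `undetermined` otherwise. When no annotated subset explains the
#' observations and an exon universe plus genome are supplied, candidate
#' novel single-junction isoforms (an upstream exon joined directly onto
#' the downstream exon chain) are added and the search repeated; hypotheses
#' appearing in minimal subsets are reported.
#'
#' @param predictions Prediction tibble from [predict_products()] covering
#'   every observed pair (rows for all candidate transcripts).
#' @param observations Tibble with columns `pair`, `outcome`
#'   (`"positive"`/`"negative"`) and `sizes` (list-column of numeric band
#'   sizes; ignored for negatives).
#' @param pairs Named list of primer pairs (needed to predict products of
#'   novel candidates); each element as in [predict_products()].
#' @param exon_universe,genome Optional exon table and genome string
#'   enabling the novel-junction search.
#' @param tol Relative band-size tolerance (gel resolution), default 10%.
#' @return An `isoform_support` object: list with `status` (tibble:
#'   transcript_id, status), `minimal_subsets` (list of character vectors)
#'   and `novel` (tibble of novel-junction hypotheses).
#' @export
infer_transcript_support <- function(predictions, observations, pairs = NULL,
                                     exon_universe = NULL, genome = NULL,
                                     tol = 0.1) {
  observations <- as_tibble(observations)
  known_pairs <- if (!is.null(pairs)) {
    vapply(pairs, function(p) p$name[[1]], character(1))
  } else {
    unique(predictions$pair)
  }
  unknown <- setdiff(observations$pair, known_pairs)
  if (length(unknown)) {
    abort(paste0("observation references unknown pair: ",
                 paste(unknown, collapse = ", ")))
  }
  ids <- sort(unique(predictions$transcript_id))
  subsets <- consistent_subsets(ids, predictions, observations, tol)
  novel <- tibble(id = character(0), junction = character(0))

  if (!length(subsets) && !is.null(exon_universe) && !is.null(genome) &&
      !is.null(pairs)) {
    nov_models <- novel_junction_models(exon_universe, genome)
    nov_preds <- purrr::map_dfr(pairs, function(p) {
      predict_products(p, nov_models, genome = genome)
    })
    # keep only hypotheses whose predictions match an observed positive
    # band (keeps the exhaustive search small)
    pos <- observations %>% filter(.data$outcome == "positive")
    helpful <- unique(nov_preds$transcript_id[
      purrr::map_lgl(seq_len(nrow(nov_preds)), function(i) {
        j <- which(pos$pair == nov_preds$pair[i])
        length(j) > 0 &&
          any(sizes_match(unlist(pos$sizes[j]), nov_preds$product_bp[i], tol))
      })
    ])
    nov_models <- nov_models[helpful]
    nov_preds <- nov_preds %>% filter(.data$transcript_id %in% helpful)
    predictions2 <- bind_rows(predictions, nov_preds)
    ids2 <- c(ids, names(nov_models))
    subsets <- consistent_subsets(ids2, predictions2, observations, tol)
    used <- unique(unlist(minimal_subsets(subsets)))
    nov_used <- intersect(names(nov_models), used)
    novel <- tibble(
      id = nov_used,
      junction = sub("^novel_", "", nov_used)
    )
    ids <- ids2
  }

  mins <- minimal_subsets(subsets)
  in_all_min <- if (length(mins)) Reduce(intersect, mins) else character(0)
  in_any <- unique(unlist(subsets))
  status <- tibble(transcript_id = ids) %>%
    mutate(status = dplyr::case_when(
      .data$transcript_id %in% in_all_min ~ "supported",
      !.data$transcript_id %in% in_any ~ "excluded",
      TRUE ~ "undetermined"
    ))
  structure(list(status = status, minimal_subsets = mins, novel = novel),
            class = "isoform_support")
}

#' @export
print.isoform_support <- function(x, ...) {
  cat("<isoform_support>\n")
  print(x$status)
  if (nrow(x$novel)) {
    cat("novel junction hypotheses:",
        paste(x$novel$junction, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy isoform_support
#' @export
tidy.isoform_support <- function(x, ...) x$status

#' Riboprobe template quality control
#'
#' Checks a probe template against the screen's design constraints: length
#' between 160 and 900 bp, melting temperature between 77 and 94 degrees C,
#' and absence of low-complexity or repetitive stretches. Tm uses the
#' long-duplex approximation
#' `Tm = 81.5 + 16.6 log10([Na+]) + 0.41 %GC - 675 / N`
#' at the hybridization salt default (0.195 M). Low complexity is a
#' windowed overlapping-triplet entropy screen; the repeat flag fires when
#' any 15-mer recurs within the template.
#'
#' @param sequence Probe template (ACGT).
#' @param na_molar Monovalent salt concentration for the Tm formula.
#' @param min_len,max_len Length bounds (bp).
#' @param tm_range Acceptable Tm range (degrees C).
#' @param entropy_window,entropy_min Window size (nt) and minimal triplet
#'   entropy (bits) for the low-complexity screen.
#' @param repeat_k k-mer size for the repeat screen.
#' @return One-row tibble: `length`, `gc`, `tm`, `low_complexity`,
#'   `repeat_flag`, `pass`, `reason`.
#' @export
probe_qc <- function(sequence, na_molar = 0.195, min_len = 160,
                     max_len = 900, tm_range = c(77, 94),
                     entropy_window = 48, entropy_min = 2,
                     repeat_k = 15) {
  sequence <- toupper(sequence)
  check_acgt(sequence, "probe sequence")
  n <- nchar(sequence)
  bases <- strsplit(sequence, "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  tm <- 81.5 + 16.6 * log10(na_molar) + 0.41 * (100 * gc) - 675 / n

  triplet_entropy <- function(chars) {
    tri <- paste0(chars[-c(length(chars) - 1, length(chars))],
                  chars[-c(1, length(chars))],
                  chars[-c(1, 2)])
    p <- table(tri) / length(tri)
    -sum(p * log2(p))
  }
  win <- min(entropy_window, n)
  starts <- seq(1, max(1, n - win + 1), by = max(1, win %/% 4))
  ent <- vapply(starts, function(s) {
    triplet_entropy(bases[s:(s + win - 1)])
  }, numeric(1))
  low_complexity <- any(ent < entropy_min)

  repeat_flag <- FALSE
  if (n >= 2 * repeat_k) {
    kmers <- substring(sequence, 1:(n - repeat_k + 1), repeat_k:n)
    repeat_flag <- anyDuplicated(kmers) > 0
  }

  reasons <- c(
    if (n < min_len || n > max_len) "length",
    if (tm < tm_range[1] || tm > tm_range[2]) "tm",
    if (low_complexity) "low_complexity",
    if (repeat_flag) "repeat"
  )
  tibble(
    length = n, gc = gc, tm = tm,
    low_complexity = low_complexity, repeat_flag = repeat_flag,
    pass = length(reasons) == 0,
    reason = if (length(reasons)) paste(reasons, collapse = ",") else ""
  )
}
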