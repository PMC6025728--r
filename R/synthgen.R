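# Synthetic-data generators: laminated bright-field section images,
# transcript quantification tables and multi-isoform transcript panels,
# all with ground truth attached so downstream stages can be tested
# without any external data.

#' Layer composition of a retinal section at a given postnatal age
#'
#' Early sections have fewer resolvable layers: at P0 only the neuroblast
#' layer (NBL) and ganglion cell layer (GCL) are distinguishable, at P3 the
#' inner plexiform layer (IPL) appears between them, and from P7 onwards the
#' outer nuclear (ONL), inner nuclear (INL), IPL and GCL are all scored.
#' The IPL, being free of cell bodies, serves as the within-section
#' normalization reference wherever it exists.
#'
#' @param age One of `"P0"`, `"P3"`, `"P7"`, `"P14"`, `"P22"`.
#' @return A list with `age`, `layers` (ordered outer-to-inner as they appear
#'   in a radial section), and `has_ipl_reference`.
#' @export
#' @examples
#' age_layer_profile("P3")
age_layer_profile <- function(age) {
  if (!is.character(age) || length(age) != 1 || !age %in% AGES) {
    abort(paste0("unsupported age: ", paste(age, collapse = ", ")))
  }
  layers <- switch(age,
    P0 = c("NBL", "GCL"),
    P3 = c("NBL", "IPL", "GCL"),
    c("ONL", "INL", "IPL", "GCL")
  )
  list(age = age, layers = layers, has_ipl_reference = "IPL" %in% layers)
}

# Relative band thicknesses (top to bottom of the section image).
layer_fractions <- function(age) {
  switch(age,
    P0 = c(NBL = 0.75, GCL = 0.25),
    P3 = c(NBL = 0.60, IPL = 0.16, GCL = 0.24),
    c(ONL = 0.32, INL = 0.28, IPL = 0.22, GCL = 0.18)
  )
}

#' Define an expression scenario for the image generator
#'
#' A scenario is the ground truth behind a set of synthetic sections: the
#' stain amplitude of each layer at each age (in gray levels below the
#' unstained background), an optional population of intensely stained sparse
#' somata, pixel noise, and a multiplicative knockout effect on the GCL
#' amplitude.
#'
#' @param gene Gene label carried into image metadata.
#' @param amplitudes Data frame with columns `age`, `layer`, `amplitude`
#'   (gray levels, >= 0) giving the wild-type stain per layer. Layers or ages
#'   not listed get amplitude 0.
#' @param genotype_effect Multiplier applied to the GCL amplitude (and GCL
#'   sparse-soma density) in the knockout; 1 means no genotype effect, 0 a
#'   complete loss.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise (gray
#'   levels).
#' @param background Gray value of unstained tissue (8-bit scale).
#' @param sparse_fraction Named numeric: per-layer fraction (0-1) of pixels
#'   covered by intensely stained somata.
#' @param sparse_amplitude Stain amplitude of sparse somata (gray levels).
#' @param height,width Image dimensions in pixels.
#' @return An object of class `expression_scenario`.
#' @export
expression_scenario <- function(gene,
                                amplitudes,
                                genotype_effect = 1,
                                noise_sd = 8,
                                background = 200,
                                sparse_fraction = numeric(0),
                                sparse_amplitude = 0,
                                height = 128,
                                width = 96) {
  amplitudes <- as_tibble(amplitudes)
  stopifnot(all(c("age", "layer", "amplitude") %in% names(amplitudes)))
  if (any(amplitudes$amplitude < 0)) abort("amplitudes must be >= 0")
  if (length(sparse_fraction) &&
      (any(sparse_fraction < 0) || any(sparse_fraction > 1))) {
    abort("sparse_fraction must lie in [0, 1]")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(
      gene = gene, amplitudes = amplitudes,
      genotype_effect = genotype_effect, noise_sd = noise_sd,
      background = background, sparse_fraction = sparse_fraction,
      sparse_amplitude = sparse_amplitude, height = height, width = width
    ),
    class = "expression_scenario"
  )
}

#' Convenience scenario with age-constant amplitudes
#'
#' @param gene Gene label.
#' @param gcl Stain amplitude in the GCL (gray levels).
#' @param inner Amplitude in the inner reference layer (INL or NBL).
#' @param ipl,onl Amplitudes in the IPL and ONL.
#' @param ages Ages to cover.
#' @inheritParams expression_scenario
#' @param ... Passed on to [expression_scenario()].
#' @return An `expression_scenario`.
#' @export
scenario_flat <- function(gene, gcl = 0, inner = 0, ipl = 0, onl = 0,
                          ages = AGES, ...) {
  amp <- purrr::map_dfr(ages, function(a) {
    prof <- age_layer_profile(a)
    tibble(age = a, layer = prof$layers) %>%
      mutate(amplitude = dplyr::case_when(
        .data$layer == "GCL" ~ gcl,
        .data$layer == "IPL" ~ ipl,
        .data$layer == "ONL" ~ onl,
        TRUE ~ inner
      ))
  })
  expression_scenario(gene, amp, ...)
}

scenario_amplitude <- function(scenario, age, layer, genotype) {
  row <- scenario$amplitudes %>%
    filter(.data$age == !!age, .data$layer == !!layer)
  amp <- if (nrow(row)) row$amplitude[[1]] else 0
  if (layer == "GCL" && genotype == "KO") amp <- amp * scenario$genotype_effect
  amp
}

# One deterministic RNG stream per (seed, age, genotype, replicate).
stream_seed <- function(seed, age, genotype, replicate) {
  if (length(seed) != 1 || is.na(seed) || seed < 0) {
    abort("seed must be a single non-negative integer")
  }
  g <- if (genotype == "KO") 1L else 0L
  as.integer((seed * 131 + age_index(age) * 17 + g * 7 + replicate * 257) %%
               2147483629)
}

#' Generate one laminated bright-field section image
#'
#' Layers are horizontal bands in the outer-to-inner order of the age's
#' [age_layer_profile()], with fixed per-age thickness ratios and a small
#' unassigned ("outside") margin at the top and bottom. Each layer's expected
#' gray value is `background - amplitude` (bright-field polarity: darker
#' means more stain). Sparse somata are disks of radius 3 px whose count is
#' Poisson-distributed to cover the requested pixel fraction. Gaussian noise
#' is added, then pixels are rounded and clipped to `[0, 255]`. The output is
#' a pure function of `(scenario, age, genotype, replicate, seed)`.
#'
#' @param scenario An [expression_scenario()].
#' @param age,genotype,replicate Condition of the section (`genotype` is
#'   `"WT"` or `"KO"`).
#' @param seed Non-negative integer controlling the image's RNG stream.
#' @return A `section_image`: a list with `pixels` (integer matrix),
#'   `layer_map` (tibble of 1-based inclusive row bands per layer) and
#'   `meta`.
#' @export
#' @examples
#' sc <- scenario_flat("demo", gcl = 80, noise_sd = 5)
#' img <- generate_section_image(sc, "P14", "WT", replicate = 1, seed = 7)
#' img
generate_section_image <- function(scenario, age, genotype = c("WT", "KO"),
                                   replicate = 1, seed = 0) {
  stopifnot(inherits(scenario, "expression_scenario"))
  genotype <- match.arg(genotype)
  prof <- age_layer_profile(age)
  h <- scenario$height; w <- scenario$width
  margin <- 4L
  usable <- h - 2L * margin
  fr <- layer_fractions(age)
  heights <- floor(usable * fr)
  heights[length(heights)] <- usable - sum(heights[-length(heights)])
  starts <- margin + c(0L, cumsum(heights[-length(heights)])) + 1L
  ends <- starts + heights - 1L
  layer_map <- tibble(layer = prof$layers, row_start = as.integer(starts),
                      row_end = as.integer(ends))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(stream_seed(seed, age, genotype, replicate))

  px <- matrix(scenario$background, nrow = h, ncol = w)
  for (i in seq_len(nrow(layer_map))) {
    ly <- layer_map$layer[[i]]
    amp <- scenario_amplitude(scenario, age, ly, genotype)
    if (amp > scenario$background) {
      warn(paste0("amplitude ", amp, " exceeds background in ", ly,
                  "; values clipped"))
    }
    rows <- layer_map$row_start[[i]]:layer_map$row_end[[i]]
    px[rows, ] <- scenario$background - amp

    frac <- scenario$sparse_fraction[ly]
    if (!is.na(frac) && length(frac) && frac > 0) {
      if (ly == "GCL" && genotype == "KO") frac <- frac * scenario$genotype_effect
      r <- 3
      area <- length(rows) * w
      n_somata <- rpois(1, frac * area / (pi * r^2))
      if (n_somata > 0) {
        cy <- sample(rows, n_somata, replace = TRUE)
        cx <- sample(seq_len(w), n_somata, replace = TRUE)
        for (k in seq_len(n_somata)) {
          rr <- max(1, cy[k] - r):min(h, cy[k] + r)
          cc <- max(1, cx[k] - r):min(w, cx[k] + r)
          d2 <- outer((rr - cy[k])^2, (cc - cx[k])^2, "+")
          sub <- px[rr, cc, drop = FALSE]
          sub[d2 <= r^2] <- scenario$background - scenario$sparse_amplitude
          px[rr, cc] <- sub
        }
      }
    }
  }
  if (scenario$noise_sd > 0) {
    px <- px + matrix(rnorm(h * w, sd = scenario$noise_sd), nrow = h)
  }
  px <- matrix(as.integer(pmin(255, pmax(0, round(px)))), nrow = h)

  structure(
    list(
      pixels = px, layer_map = layer_map,
      meta = list(gene = scenario$gene, age = age, genotype = genotype,
                  replicate = replicate, seed = seed,
                  background = scenario$background,
                  noise_sd = scenario$noise_sd)
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<section_image> %s %s %s rep %s  [%d x %d px]\n",
              m$gene, m$age, m$genotype, m$replicate,
              nrow(x$pixels), ncol(x$pixels)))
  cat("layers:", paste(x$layer_map$layer, collapse = " > "), "\n")
  invisible(x)
}

#' Generate a transcript quantification table with planted candidates
#'
#' Emulates the upstream RNA-seq screen input: per-transcript FPKM in
#' Brn3a-WT/KO RGCs, whole retina, and Brn3b-WT/KO RGCs, plus gene-level CPM
#' columns. A `planted` fraction of transcripts is constructed to satisfy all
#' three selection criteria with margin (expression above 2 FPKM, at least
#' two-fold WT/KO differential, less than two-fold Brn3b differential); the
#' rest violate at least one criterion with margin. The ground-truth flag is
#' emitted so recovery tests never re-derive truth from outputs.
#'
#' @param n_genes Number of genes.
#' @param n_transcripts_per_gene Transcripts per gene.
#' @param planted_fraction Fraction of transcripts planted as candidates.
#' @param fold Minimum planted WT/KO fold margin base (must be > 1).
#' @param seed RNG seed.
#' @return A tibble with FPKM/CPM columns and the logical `planted` column.
#' @export
generate_quant_table <- function(n_genes = 100, n_transcripts_per_gene = 2,
                                 planted_fraction = 0.2, fold = 2, seed = 1) {
  if (fold <= 1) abort("fold must be > 1")
  if (planted_fraction < 0 || planted_fraction > 1) {
    abort("planted_fraction must lie in [0, 1]")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% 2147483629))

  n <- n_genes * n_transcripts_per_gene
  tab <- tibble(
    gene_id = rep(sprintf("gene%04d", seq_len(n_genes)),
                  each = n_transcripts_per_gene),
    transcript_id = sprintf("tx%05d", seq_len(n)),
    planted = runif(n) < planted_fraction
  )
  wt <- ko <- retina <- b_wt <- b_ko <- numeric(n)
  for (i in seq_len(n)) {
    if (tab$planted[i]) {
      wt[i] <- runif(1, 4, 50)
      ko[i] <- wt[i] / (fold * runif(1, 1.25, 2.5))
      retina[i] <- wt[i] / runif(1, 2.5, 5)
      b_wt[i] <- runif(1, 1, 20)
      b_ko[i] <- b_wt[i] * runif(1, 0.8, 1.25)
    } else {
      mode <- sample(c("low", "flat", "brn3b"), 1)
      if (mode == "low") {
        wt[i] <- runif(1, 0, 1.5)
        ko[i] <- wt[i] * runif(1, 0.3, 1.2)
      } else if (mode == "flat") {
        wt[i] <- runif(1, 3, 40)
        ko[i] <- wt[i] * runif(1, 0.85, 1.2)
      } else {
        wt[i] <- runif(1, 4, 40)
        ko[i] <- wt[i] / (fold * runif(1, 1.25, 2))
      }
      retina[i] <- wt[i] * runif(1, 0.4, 1.5)
      b_wt[i] <- runif(1, 2, 20)
      b_ko[i] <- if (mode == "brn3b") b_wt[i] / runif(1, 2.5, 4) else
        b_wt[i] * runif(1, 0.8, 1.25)
    }
  }
  tab <- tab %>% mutate(
    fpkm_brn3a_wt_rgc = round(wt, 3),
    fpkm_brn3a_ko_rgc = round(ko, 3),
    fpkm_retina = round(retina, 3),
    fpkm_brn3b_wt_rgc = round(b_wt, 3),
    fpkm_brn3b_ko_rgc = round(b_ko, 3)
  )
  gene_cpm <- tab %>%
    group_by(.data$gene_id) %>%
    summarise(
      cpm_brn3a_wt_rgc = sum(.data$fpkm_brn3a_wt_rgc),
      cpm_brn3a_ko_rgc = sum(.data$fpkm_brn3a_ko_rgc),
      cpm_retina = sum(.data$fpkm_retina),
      .groups = "drop"
    )
  tab %>%
    left_join(gene_cpm, by = "gene_id") %>%
    select("gene_id", "transcript_id", dplyr::starts_with("fpkm_"),
           dplyr::starts_with("cpm_"), "planted")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic multi-isoform transcript panel
#'
#' Builds a small synthetic "genome" string, an exon universe on it, and a
#' set of isoform models emulating the two transcript-diagnosis situations in
#' the study: `alt_first_exon` panels share all exons downstream of a common
#' exon but start from distinct first-exon variants (one isoform additionally
#' carrying a unique internal exon), and `cassette` panels differ by skipped
#' internal exons / alternative starts.
#'
#' @param kind `"alt_first_exon"` or `"cassette"`.
#' @param seed RNG seed.
#' @return A list with `genome` (character scalar), `exons` (tibble: label,
#'   start, end; 0-based half-open), `models` (list of [transcript_model()])
#'   and `sequences` (named character of spliced sequences).
#' @export
generate_isoform_panel <- function(kind = c("alt_first_exon", "cassette"),
                                   seed = 1) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% 2147483629))

  if (kind == "alt_first_exon") {
    labels <- c("e1a", "e1b", "e1c", "e2", "e3", "e4", "e5")
    structure_sets <- list(
      isoA = c("e1a", "e3", "e4", "e5"),
      isoB = c("e1b", "e3", "e4", "e5"),
      isoC = c("e1c", "e2", "e3", "e4", "e5")
    )
  } else {
    labels <- c("e1", "e2", "e3", "e4", "e5", "e6")
    structure_sets <- list(
      iso_long = c("e2", "e3", "e6"),
      iso_medium = c("e5", "e6"),
      iso_short = c("e2", "e3", "e4")
    )
  }
  lens <- sample(80:200, length(labels), replace = TRUE)
  gaps <- sample(30:80, length(labels) + 1, replace = TRUE)
  starts <- cumsum(gaps[seq_along(labels)] + c(0, lens[-length(lens)]))
  exons <- tibble(label = labels, start = starts, end = starts + lens)
  genome <- random_dna(max(exons$end) + gaps[length(gaps)])

  models <- purrr::imap(structure_sets, function(labs, id) {
    transcript_model(id, exons %>% filter(.data$label %in% labs))
  })
  sequences <- purrr::map_chr(models, splice, genome = genome)
  list(genome = genome, exons = exons, models = models, sequences = sequences)
}
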