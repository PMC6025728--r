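# Readers and writers: section images (8-bit grayscale PNG + JSON sidecar),
# transcript models (BED12 via rtracklayer), sequences (FASTA via
# Biostrings) and provenance-stamped TSV outputs.

#' Write a section image as PNG plus a JSON sidecar
#'
#' The PNG holds the 8-bit grayscale pixels; the sidecar carries metadata
#' and the per-layer row bands as 0-based half-open ranges.
#'
#' @param image A `section_image`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to `gene_age_genotype_repN`.
#' @return Invisibly, the PNG path.
#' @export
write_section_image <- function(image, dir, stem = NULL) {
  stopifnot(inherits(image, "section_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- image$meta
  if (is.null(stem)) {
    stem <- sprintf("%s_%s_%s_rep%d", m$gene, m$age, m$genotype, m$replicate)
  }
  png_path <- file.path(dir, paste0(stem, ".png"))
  png::writePNG(image$pixels / 255, png_path)
  sidecar <- list(
    meta = m,
    layers = purrr::pmap(image$layer_map, function(layer, row_start, row_end) {
      list(layer = layer, row_start = row_start - 1L, row_end = row_end)
    })
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE)
  invisible(png_path)
}

#' Read a section image written by [write_section_image()]
#'
#' @param png_path Path to the PNG (the sidecar is found by extension swap).
#' @return A `section_image`.
#' @export
read_section_image <- function(png_path) {
  px <- png::readPNG(png_path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px <- matrix(as.integer(round(px * 255)), nrow = nrow(px))
  sidecar <- jsonlite::read_json(sub("\\.png$", ".json", png_path),
                                 simplifyVector = FALSE)
  layer_map <- purrr::map_dfr(sidecar$layers, function(l) {
    tibble(layer = l$layer, row_start = l$row_start + 1L,
           row_end = as.integer(l$row_end))
  })
  structure(list(pixels = px, layer_map = layer_map, meta = sidecar$meta),
            class = "section_image")
}

#' Write transcript models as BED12
#'
#' @param models List of [transcript_model()]s (plus-strand coordinates on
#'   one synthetic chromosome).
#' @param path Output file.
#' @param chrom Chromosome name.
#' @return Invisibly, `path`.
#' @export
write_transcript_bed <- function(models, path, chrom = "synth") {
  grl <- methods::as(purrr::map(models, function(m) {
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = m$exons$start + 1, end = m$exons$end),
      strand = m$strand
    )
  }), "GRangesList")
  names(grl) <- purrr::map_chr(models, "id")
  rtracklayer::export(rtracklayer::asBED(grl), path, format = "BED")
  invisible(path)
}

#' Read transcript models from BED12
#'
#' Exon labels are regenerated positionally (`e1`, `e2`, ...) per
#' transcript; genomic exon coordinates round-trip exactly.
#'
#' @param path BED12 file.
#' @return Named list of [transcript_model()]s.
#' @export
read_transcript_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- purrr::map(seq_along(gr), function(i) {
    blocks <- gr$blocks[[i]]
    starts <- GenomicRanges::start(gr)[i] - 1 + IRanges::start(blocks) - 1
    ends <- starts + IRanges::width(blocks)
    transcript_model(
      gr$name[i],
      tibble(label = paste0("e", seq_along(starts)),
             start = starts, end = ends),
      strand = as.character(GenomicRanges::strand(gr))[i]
    )
  })
  setNames(out, purrr::map_chr(out, "id"))
}

#' Write named sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write a tibble as TSV with a provenance header
#'
#' Prepends `#`-prefixed lines recording the package version, seed and a
#' configuration hash, so every output records how it was produced.
#'
#' @param x Tibble.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param config Optional list hashed into the header.
#' @return Invisibly, `path`.
#' @export
write_tsv_provenance <- function(x, path, seed = NA, config = list()) {
  header <- c(
    paste0("# laminaquant ",
           as.character(utils::packageVersion("laminaquant"))),
    paste0("# seed=", seed, " config_hash=", rlang::hash(config))
  )
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_provenance()]
#' @param path Input path.
#' @return A tibble (provenance lines skipped).
#' @export
read_tsv_provenance <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
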