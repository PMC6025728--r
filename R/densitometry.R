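# ROI placement, mean-gray densitometry and IPL-referenced normalization.

#' Place registered layer ROIs on a section image
#'
#' Places `n_rois` rectangular ROIs per layer. ROIs are organised in
#' registration groups: all layers of one group share the same column span
#' ("registered along the section plane"), and all ROIs of one layer have
#' identical area. Column positions are drawn deterministically from `seed`,
#' one group per equal-width segment of the section.
#'
#' @param image A `section_image`.
#' @param n_rois Number of ROIs (registration groups) per layer; default 3.
#' @param roi_width ROI width in pixels.
#' @param seed Integer seed controlling within-segment jitter.
#' @return A tibble with columns `layer`, `group`, `row_start`, `row_end`,
#'   `col_start`, `col_end` (1-based inclusive) and `area`.
#' @export
place_layer_rois <- function(image, n_rois = 3, roi_width = 16, seed = 0) {
  stopifnot(inherits(image, "section_image"))
  w <- ncol(image$pixels)
  seg <- floor(w / n_rois)
  if (seg < roi_width) {
    abort(sprintf("image too narrow for %d ROIs of width %d", n_rois, roi_width))
  }
  too_small <- image$layer_map %>%
    filter(.data$row_end - .data$row_start + 1 < 3)
  if (nrow(too_small)) {
    abort(paste0("layer too small for ROI placement: ",
                 paste(too_small$layer, collapse = ", ")))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% 2147483629))

  col_starts <- vapply(seq_len(n_rois), function(g) {
    lo <- (g - 1L) * seg + 1L
    hi <- g * seg - roi_width + 1L
    if (hi <= lo) lo else sample(lo:hi, 1)
  }, integer(1))

  purrr::map_dfr(seq_len(n_rois), function(g) {
    image$layer_map %>%
      mutate(
        group = g,
        row_start = .data$row_start + 1L,
        row_end = .data$row_end - 1L,
        col_start = col_starts[g],
        col_end = col_starts[g] + as.integer(roi_width) - 1L
      )
  }) %>%
    mutate(area = (.data$row_end - .data$row_start + 1L) *
             (.data$col_end - .data$col_start + 1L)) %>%
    select("layer", "group", "row_start", "row_end", "col_start",
           "col_end", "area")
}

#' Mean gray value of a rectangular ROI
#'
#' @param image A `section_image`.
#' @param roi A one-row data frame (or list) with `row_start`, `row_end`,
#'   `col_start`, `col_end`, 1-based inclusive.
#' @return The arithmetic mean of the pixel gray values in the rectangle.
#' @export
mean_gray <- function(image, roi) {
  stopifnot(inherits(image, "section_image"))
  rs <- roi$row_start[[1]]; re <- roi$row_end[[1]]
  cs <- roi$col_start[[1]]; ce <- roi$col_end[[1]]
  if (rs < 1 || cs < 1 || re > nrow(image$pixels) || ce > ncol(image$pixels) ||
      rs > re || cs > ce) {
    abort("ROI out of image bounds")
  }
  mean(image$pixels[rs:re, cs:ce])
}

#' Apply the age-specific IPL-referenced normalization
#'
#' For ages with a visible IPL (P3 and later), each cellular layer's
#' normalized value is `raw(IPL) - raw(layer)`: because stain darkens the
#' bright-field image, layers darker (more stained) than the cell-body-free
#' IPL score positive. The IPL itself carries only its raw value. At P0
#' there is no IPL, so raw values are carried forward unchanged and
#' `normalization_applied` is `FALSE`.
#'
#' @param raw Named numeric vector of per-layer raw mean gray values; must
#'   contain every layer of the age's [age_layer_profile()].
#' @param age Postnatal age.
#' @return A tibble with columns `layer`, `raw`, `normalized` (`NA` for the
#'   IPL and for all layers at P0) and `normalization_applied`.
#' @export
#' @examples
#' normalize_record(c(GCL = 100, INL = 170, ONL = 175, IPL = 180), "P14")
normalize_record <- function(raw, age) {
  prof <- age_layer_profile(age)
  missing <- setdiff(prof$layers, names(raw))
  if (length(missing)) {
    abort(paste0("missing layer value: ", paste(missing, collapse = ", ")))
  }
  out <- tibble(layer = prof$layers, raw = unname(raw[prof$layers]))
  if (prof$has_ipl_reference) {
    ipl <- raw[["IPL"]]
    out <- out %>% mutate(
      normalized = ifelse(.data$layer == "IPL", NA_real_, ipl - .data$raw),
      normalization_applied = TRUE
    )
  } else {
    out <- out %>% mutate(normalized = NA_real_, normalization_applied = FALSE)
  }
  out
}

#' Quantify one section image into per-ROI layer records
#'
#' Places registered ROIs, measures each layer's mean gray per registration
#' group, and applies the IPL normalization within each group (each cellular
#' layer is referenced to the IPL ROI of its own group).
#'
#' @inheritParams place_layer_rois
#' @return A tibble with image metadata, `group`, `layer`, `raw`,
#'   `normalized` and `normalization_applied`.
#' @export
quantify_image <- function(image, n_rois = 3, roi_width = 16, seed = 0) {
  rois <- place_layer_rois(image, n_rois = n_rois, roi_width = roi_width,
                           seed = seed)
  rois$raw <- vapply(seq_len(nrow(rois)), function(i) {
    mean_gray(image, rois[i, ])
  }, numeric(1))
  m <- image$meta
  purrr::map_dfr(unique(rois$group), function(g) {
    sub <- rois %>% filter(.data$group == g)
    normalize_record(setNames(sub$raw, sub$layer), m$age) %>%
      mutate(group = g)
  }) %>%
    mutate(gene = m$gene, age = m$age, genotype = m$genotype,
           replicate = m$replicate) %>%
    select("gene", "age", "genotype", "replicate", "group", "layer",
           "raw", "normalized", "normalization_applied")
}

#' Quantify a list of section images
#'
#' @param images List of `section_image` objects.
#' @inheritParams place_layer_rois
#' @return Row-bound per-ROI records from [quantify_image()].
#' @export
quantify_images <- function(images, n_rois = 3, roi_width = 16, seed = 0) {
  purrr::imap_dfr(images, function(img, i) {
    quantify_image(img, n_rois = n_rois, roi_width = roi_width,
                   seed = seed + as.integer(i))
  })
}

#' Stain-oriented comparison sample for one layer
#'
#' Extracts the per-ROI values used by the statistical calls: normalized
#' values where the IPL reference exists, and `background - raw` at P0 so
#' that larger always means more stain regardless of age.
#'
#' @param quant Per-ROI records from [quantify_image()].
#' @param layer Layer to extract.
#' @param background Background gray used for the P0 polarity flip.
#' @return Numeric vector of stain scores.
#' @export
stain_scores <- function(quant, layer, background = 200) {
  sub <- quant %>% filter(.data$layer == !!layer)
  ifelse(sub$normalization_applied, sub$normalized, background - sub$raw)
}

#' Flag sparse intensely stained somata in a layer
#'
#' A layer is flagged sparse when its overall mean stays near the unstained
#' background while more than `min_fraction` of its pixels are markedly
#' darker than the layer median (beyond `k` robust standard deviations).
#' This mirrors the situation where rare intensely stained cell bodies are
#' averaged away by the unstained majority.
#'
#' @param image A `section_image`.
#' @param layer Layer to inspect (default GCL).
#' @param k Robust z-score cut for "intensely stained" pixels.
#' @param min_fraction Minimal fraction of such pixels.
#' @param background_margin Maximal distance of the layer median from the
#'   image background for the layer to count as "near background".
#' @return Logical flag.
#' @export
sparse_flag <- function(image, layer = "GCL", k = 3, min_fraction = 0.01,
                        background_margin = 25) {
  band <- image$layer_map %>% filter(.data$layer == !!layer)
  if (!nrow(band)) abort(paste0("no such layer: ", layer))
  px <- as.numeric(image$pixels[band$row_start:band$row_end, ])
  med <- median(px)
  s <- mad(px)
  if (s == 0) s <- max(1, stats::sd(px))
  frac_dark <- mean(px < med - k * s)
  near_bg <- abs(med - image$meta$background) <= background_margin
  isTRUE(near_bg && frac_dark > min_fraction)
}
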