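# ggplot2 views of the main result types.

#' @importFrom ggplot2 aes autoplot ggplot geom_raster geom_boxplot
#'   geom_line geom_point geom_hline facet_grid facet_wrap labs
#'   scale_fill_gradient theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a synthetic section image
#'
#' @param object A `section_image`.
#' @param ... Unused.
#' @return A ggplot (grayscale raster, image row 1 on top).
#' @method autoplot section_image
#' @export
autoplot.section_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$gray <- as.vector(object$pixels)
  m <- object$meta
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$gray)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    labs(title = sprintf("%s %s %s rep %d", m$gene, m$age, m$genotype,
                         m$replicate),
         x = NULL, y = NULL, fill = "gray") +
    theme_minimal()
}

#' Box-whisker view of per-ROI stain scores by layer
#'
#' Mirrors the quantitation panels of the screen: one box per layer and
#' genotype, faceted by age, on IPL-normalized values (background-minus-raw
#' at P0).
#'
#' @param quant Per-ROI records from [quantify_images()].
#' @param background Background gray for the P0 polarity flip.
#' @return A ggplot.
#' @export
plot_layer_scores <- function(quant, background = 200) {
  df <- quant %>%
    filter(.data$layer != "IPL") %>%
    mutate(
      score = ifelse(.data$normalization_applied, .data$normalized,
                     background - .data$raw),
      age = factor(.data$age, levels = AGES)
    )
  ggplot(df, aes(x = .data$layer, y = .data$score, fill = .data$genotype)) +
    geom_boxplot(position = "dodge") +
    facet_grid(gene ~ age, scales = "free_y") +
    labs(x = "retinal layer", y = "stain score (gray levels vs IPL)",
         fill = NULL) +
    theme_minimal()
}

#' Developmental GCL expression profile
#'
#' @param series Tibble with columns `age`, `value` and optionally `gene`.
#' @param threshold Optional detection threshold drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_expression_profile <- function(series, threshold = NULL) {
  df <- series %>% mutate(age = factor(.data$age, levels = AGES))
  p <- ggplot(df, aes(x = .data$age, y = .data$value, group = 1)) +
    geom_line() + geom_point() +
    labs(x = "postnatal age", y = "GCL stain score") +
    theme_minimal()
  if ("gene" %in% names(df)) p <- p + facet_wrap(~gene, scales = "free_y")
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
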