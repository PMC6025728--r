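test_that("age layer profiles follow the study's layer sets", {
  expect_equal(age_layer_profile("P0")$layers, c("NBL", "GCL"))
  expect_false(age_layer_profile("P0")$has_ipl_reference)
  expect_equal(age_layer_profile("P3")$layers, c("NBL", "IPL", "GCL"))
  for (a in c("P7", "P14", "P22")) {
    expect_equal(age_layer_profile(a)$layers, c("ONL", "INL", "IPL", "GCL"))
    expect_true(age_layer_profile(a)$has_ipl_reference)
  }
  expect_error(age_layer_profile("P5"), "unsupported age")
})

test_that("noise-free zero-amplitude image is constant background", {
  sc <- scenario_flat("g", gcl = 0, noise_sd = 0)
  img <- generate_section_image(sc, "P14", "WT", 1, seed = 1)
  expect_true(all(img$pixels == 200))
})

test_that("section images are bit-identical for identical parameters", {
  sc <- scenario_flat("g", gcl = 40, inner = 10, noise_sd = 6,
                      sparse_fraction = c(GCL = 0.03), sparse_amplitude = 120)
  a <- generate_section_image(sc, "P7", "KO", 2, seed = 7)
  b <- generate_section_image(sc, "P7", "KO", 2, seed = 7)
  expect_identical(a$pixels, b$pixels)
  c <- generate_section_image(sc, "P7", "KO", 2, seed = 8)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("empirical layer mean tracks background minus amplitude", {
  # GCL amplitude 80 on background 200 with sd-5 noise: the band mean must
  # sit within 3*sd/sqrt(n) of 120
  sc <- scenario_flat("g", gcl = 80, noise_sd = 5)
  img <- generate_section_image(sc, "P14", "WT", 1, seed = 42)
  band <- img$layer_map[img$layer_map$layer == "GCL", ]
  px <- img$pixels[band$row_start:band$row_end, ]
  expect_lt(abs(mean(px) - 120), 3 * 5 / sqrt(length(px)) + 0.5)
})

test_that("stain polarity: more amplitude gives darker layer until clipping", {
  means <- vapply(c(0, 50, 100, 150), function(a) {
    sc <- scenario_flat("g", gcl = a, noise_sd = 0)
    img <- generate_section_image(sc, "P14", "WT", 1, seed = 1)
    band <- img$layer_map[img$layer_map$layer == "GCL", ]
    mean(img$pixels[band$row_start:band$row_end, ])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("amplitude above background clips with a warning", {
  sc <- scenario_flat("g", gcl = 250, noise_sd = 0)
  expect_warning(img <- generate_section_image(sc, "P14", "WT", 1, seed = 1),
                 "clipped")
  expect_true(all(img$pixels >= 0))
})

test_that("every pixel belongs to exactly one layer band or the margin", {
  sc <- scenario_flat("g", gcl = 10, noise_sd = 0)
  for (a in c("P0", "P3", "P14")) {
    img <- generate_section_image(sc, a, "WT", 1, seed = 1)
    lm <- img$layer_map
    rows <- unlist(Map(seq, lm$row_start, lm$row_end))
    expect_equal(anyDuplicated(rows), 0)
    expect_true(all(rows >= 1 & rows <= nrow(img$pixels)))
    expect_equal(lm$layer, age_layer_profile(a)$layers)
  }
})

test_that("quant tables plant candidates that pass the filter by margin", {
  tab <- generate_quant_table(n_genes = 250, n_transcripts_per_gene = 2,
                              planted_fraction = 0.2, seed = 1)
  sel <- select_candidates(tab)
  expect_identical(sel$selected, tab$planted)

  none <- generate_quant_table(n_genes = 50, planted_fraction = 0, seed = 2)
  expect_equal(sum(select_candidates(none)$selected), 0)
})

test_that("fold-boundary semantics: exactly two-fold passes, 2 FPKM fails", {
  row <- tibble::tibble(
    fpkm_brn3a_wt_rgc = 4, fpkm_brn3a_ko_rgc = 2,
    fpkm_brn3b_wt_rgc = 5, fpkm_brn3b_ko_rgc = 5
  )
  expect_true(select_candidates(row, epsilon = 0)$selected)
  row$fpkm_brn3a_wt_rgc <- 2
  expect_false(select_candidates(row, epsilon = 0)$selected)
})

test_that("isoform panels reconstruct spliced sequences from coordinates", {
  for (kind in c("alt_first_exon", "cassette")) {
    p <- generate_isoform_panel(kind, seed = 5)
    for (m in p$models) {
      expect_equal(nchar(splice(m, p$genome)),
                   sum(m$exons$end - m$exons$start))
    }
  }
})

test_that("alt-first-exon isoforms share sequence downstream of the common exon", {
  p <- generate_isoform_panel("alt_first_exon", seed = 9)
  # all isoforms share e3..e5; their spliced tails must be identical
  tail_len <- sum(with(p$exons, end - start)[p$exons$label %in%
                                               c("e3", "e4", "e5")])
  tails <- vapply(p$sequences, function(s) {
    substring(s, nchar(s) - tail_len + 1, nchar(s))
  }, character(1))
  expect_equal(length(unique(tails)), 1)
})

test_that("cassette skipping isoform length equals total minus skipped exons", {
  p <- generate_isoform_panel("cassette", seed = 4)
  len <- function(lab) with(p$exons, end - start)[match(lab, p$exons$label)]
  expect_equal(nchar(p$sequences[["iso_long"]]),
               sum(len(c("e2", "e3", "e6"))))
})
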