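---
title: "Layer-resolved ISH densitometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-resolved ISH densitometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminaquant)
```

# The measurement problem

Colorimetric in situ hybridization (ISH) on sections of developing mouse
retina produces bright-field images in which darker pixels mean more
transcript. The biological questions asked of such images in a candidate-gene
screen are layer-resolved: is a gene's signal enriched in the ganglion cell
layer (GCL) relative to the inner retina, and does that GCL signal depend on
the genotype (here, loss of the transcription factor Brn3a/Pou4f1 in retinal
ganglion cells)? `laminaquant` implements the full quantitation and calling
chain for this design, together with the up- and downstream steps that
surround it: the RNA-seq filter that nominates candidate genes, the
developmental profiling of per-age calls into a gene summary table, and the
transcript-isoform diagnostics (in-silico PCR, band-pattern support
inference, riboprobe QC) used when a gene's isoforms must be told apart.

Because the raw images and sequencing data behind the original screen are
not deposited, the package ships a first-class synthetic-data module. Its
generators emit laminated section images, quantification tables and isoform
panels with ground truth attached, so that every stage of the pipeline is
testable end to end.

# Layer model and densitometry

A section is modelled as horizontal bands in the outer-to-inner order a
radial section shows. The resolvable layer set depends on age:
at P0 only the neuroblast layer (NBL) and GCL can be scored, at P3 the inner
plexiform layer (IPL) appears between them, and from P7 the outer nuclear
(ONL), inner nuclear (INL), IPL and GCL are all available. The IPL, being
free of cell bodies, serves as a within-section reference.

`place_layer_rois()` places `n_rois` (default 3) rectangular ROIs per layer.
ROIs are organised in *registration groups*: all layers of one group share
the same column span — each group is registered along the section plane, so
every layer is sampled at the same position — and all ROIs of one layer
have identical area (the original manual procedure kept areas approximately
equal; here they are made exact). `mean_gray()` is a plain
arithmetic mean over the half-open rectangle.

Normalization follows the age-specific rule: for P3 and later,
`normalized(layer) = raw(IPL) − raw(layer)`, so a stained (darker) layer
scores positive; at P0 no IPL exists and raw values are carried forward with
`normalization_applied = FALSE`. Two consequences are worth noting:

* The IPL-referenced difference is invariant to adding a constant to all
  layer means, so slide-to-slide illumination offsets cancel.
* At P0 the raw gray scale runs *opposite* to stain. So that the directional
  gates keep one meaning across ages, the pipeline feeds `background − raw`
  ("stain score") into the P0 comparisons. The KS statistic and p-value are
  unchanged by this strictly increasing transform applied to both samples;
  only the direction label is affected.

A documented limitation is inherited from the measurement itself: when a
gene is expressed intensely in few cells, area-averaged densitometry dilutes
the signal toward the unstained majority. The package does not compensate
for this; it flags it. `sparse_flag()` marks a layer whose median stays near
background while more than 1% of pixels fall 3 robust SDs below the median.

# The statistical calls

Comparisons use a two-sample Kolmogorov–Smirnov test written for the small
samples this design produces (2–3 images per condition with 3 ROIs each,
hence 6–9 observations per layer). `ks2()` computes
`D = sup |F_a − F_b|` with right-continuous empirical CDFs (ties need no
special handling under this convention) and a two-sided p-value by:

* **exact enumeration** of all `choose(n1 + n2, n1)` label assignments when
  `n1 + n2 ≤ 16` — chosen because the asymptotic series is unreliable
  exactly where the design's samples live;
* otherwise the **asymptotic series**
  `p = 2 Σ_k (−1)^(k−1) exp(−2 k² m D²)`, `m = n1 n2/(n1+n2)`, truncated at
  terms below 1e−12 and clamped to `(0, 1]`.

Star levels use the strict thresholds `* p < 0.05`, `** p < 0.01`,
`*** p < 0.001` (0.05 itself is `ns`). Two comparison types are built on
this machinery. `enrichment_call()` tests GCL against the inner reference
layer (NBL at P0/P3, INL from P7); `dependency_call()` tests WT against KO
GCL. Both gate the verdict on the sample medians (GCL above inner; WT above
KO): a significant difference in the wrong direction is reported but not
called. Medians were chosen over means because sparse high-expressors skew
the pooled ROI distribution. No multiple-testing correction is applied,
matching the per-comparison star convention of the original design; users
comparing many genes should treat the stars accordingly.

# Developmental profiling

`summarize_gene()` reduces a gene's ten calls (two comparisons × five ages)
and its per-age GCL expression series to one row: enrichment at P3,
consistent enrichment (≥ 4 of 5 ages — the summary-table convention),
dependency at P3 and at any age, and an onset/peak/offset profile.
Thresholding uses `3 ×` a robust noise scale (MAD of pooled ROI values):
the stain intensity scale is arbitrary, so only a scale-free criterion
makes sense, and no numeric threshold is part of the original design. Peaks within 10% of the maximum that form a contiguous
run are reported as a range (e.g. `P7-P14`), matching the two-age peaks of
the published summary; the offset is the earliest post-onset age where the
signal drops below threshold *and stays there* — a transient dip does not
count. The same ≥ 4-of-5 rule is applied to dependency calls by
`consistent_dependency()`; the published table defines the rule only for
enrichment, and mirroring it for dependency reproduces the stated
three-gene set of developmentally consistent targets.

# The candidate filter

`select_candidates()` applies the screen's three rules with the published
boundary semantics taken literally: WT RGC expression strictly *more than*
2 FPKM; *at least* two-fold WT/KO differential; *less than* two-fold Brn3b
differential in either direction (the Brn3b criterion is direction-free
because "no regulation" is symmetric). Fold changes use a pseudocount
`ε = 0.1` in numerator and denominator so that a transcript absent in the
knockout passes rather than dividing by zero; for abundances ≥ 1 the
selection is identical with and without the pseudocount, so ε matters only
where it should. Note that with the pseudocount an exactly-two-fold ratio
falls marginally below 2; boundary examples are therefore evaluated at
`ε = 0`.

# Isoform diagnostics

`predict_products()` performs in-silico PCR on spliced isoform sequences:
exact matching of the forward primer and the reverse complement of the
reverse primer (primers are designed against their templates, so mismatch
tolerance is out of scope), product length from the forward-site start
through the reverse-site end inclusive — the convention under which the
published product sizes equal their combined-exon spans — and one product
per orientation-ordered site pair, so a pair may yield two bands on two
splice variants. The 26-nt T3 promoter appended to every reverse primer
(`append_t3()`) adds exactly 26 nt to a template, the `+ (26)` convention
of the primer tables.

`infer_transcript_support()` turns a band pattern into transcript-level
conclusions by exhaustive search over candidate subsets. A subset is
consistent when every negative reaction has no predicted product among its
members and every positive reaction's band sizes match predicted products
two-way within a ±10% gel tolerance. Sensitivity is treated as perfect — a
negative excludes every transcript its pair should amplify — which is the
strongest reading of negative evidence and is flagged here as such.
Transcripts in every minimal consistent subset are `supported`, those in no
consistent subset `excluded`, the rest `undetermined`. When no annotated
subset explains the pattern, single-junction novel isoforms (an upstream
exon joined directly onto the downstream exon chain) are hypothesised,
restricted to those matching an observed band; the engine reports the
junction, not a transcription start site, because a band pattern cannot fix
the latter.

`probe_qc()` checks riboprobe templates against the design constraints:
length 160–900 bp, melting temperature 77–94 °C, no low-complexity or
repetitive stretches. The stated Tm range does not by itself pin down a
formula or salt condition; the long-duplex approximation
`Tm = 81.5 + 16.6 log10([Na+]) + 0.41 %GC − 675/N` at 0.195 M monovalent
salt is used, a standard choice for hybridization probes of this length,
and the salt default is an explicit argument. Low complexity is a windowed
(48 nt) overlapping-triplet entropy screen with a 2-bit floor — a
homopolymer scores 0 bits, random sequence about 5.5 — and the repeat flag
fires when any 15-mer recurs within the template.

# The synthetic-data generators

`generate_section_image()` is a pure function of
`(scenario, age, genotype, replicate, seed)`. A scenario fixes per-layer
stain amplitudes (gray levels below background), Gaussian pixel noise,
optional sparse somata (radius-3 disks, Poisson-placed to cover a requested
pixel fraction), and a multiplicative knockout effect on the GCL. Defaults
the study design does not constrain were chosen once: background gray 200 (leaves
headroom for amplitudes up to 200 without clipping), 128 × 96 px sections
with fixed per-age layer thickness ratios, noise SD 8 gray levels. The
generator emulates laminated bright-field appearance and polarity, not
histological texture: passing tests demonstrate that the quantitation and
calling machinery recovers planted effects under Gaussian noise and
idealised layer geometry, not that it is robust to real-world artefacts
(uneven illumination, section folds, chromogen granularity), which remain
out of scope.

`generate_quant_table()` plants a chosen fraction of transcripts that
satisfy all three selection rules with margin and makes the rest violate at
least one rule with margin, emitting the ground-truth flag so recovery is
never inferred from outputs. `generate_isoform_panel()` builds the two
diagnostic situations on a synthetic genome: alternative first exons over a
shared downstream chain (one isoform carrying a unique internal exon) and
cassette/alternative-start structures.

# Numerical choices and problem sizes

Deterministic streams are derived per condition from small integer
arithmetic on the master seed, so reruns are bit-identical and parallel
conditions do not share streams. The test-suite and acceptance-script
problem sizes — 2,000 null replicates for calibration, 500 image replicates
for enrichment recovery at a planted amplitude of 4 × noise SD, 1,000 draws
for exact-vs-asymptotic agreement at n = 30, 100 random panels for the
isoform-inference oracle parity — were chosen to give stable Monte-Carlo
estimates (binomial SE below ~0.01) while keeping a full run in the
one-to-two-minute range on one CPU.

Known limitations, beyond those noted above: layer geometry is axis-aligned
(no curvature, no segmentation from unannotated images); illumination-field
correction and color deconvolution are not implemented; the KS exact path
enumerates label assignments and is therefore limited to pooled sizes ≤ 16,
beyond which the asymptotic series (verified against an independent exact
implementation to within 0.02 at n = 30) takes over.
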