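# Packaged fixture tables

These TSVs transcribe the published primer, splice-variant and gene-summary
tables so that the package's profiling and isoform machinery can be exercised
without the original PDF.

- `table1.tsv` — ISH probe / RT-PCR primer list. The `section` column splits
  the 24 3'-UTR probes (23 candidates plus the Pou4f1 positive control) from
  the transcript-specific primer combinations for Clcc1 and Pnkd.
  `product_bp` is the PCR template length excluding the 26-nt T3 promoter
  extension (`t3_ext`); `product_bp_alt` carries the second band where a
  primer combination yields two splice-variant products. The published table
  prints forward and reverse primers run together without a delimiter; the
  split adopted here assumes typical 18-25-nt primers and is therefore a
  best-effort reconstruction — downstream code uses only product lengths,
  flags and incubation times, never these primer strings.
- `table2.tsv` — predicted and confirmed splicing variants. `sizes_bp` lists
  the band sizes (comma-separated for two-band combinations),
  `predicted_transcripts` the isoforms each primer pair should amplify,
  `detected_transcripts` those marked as detected by RT-PCR, and
  `confirmed_junctions` the exon joins each positive reaction demonstrates.
  `rtpcr_negative = yes` marks reactions that gave no (or only nonspecific)
  product.
- `table3.tsv` — the 28-gene summary: per-gene GCL enrichment at P3,
  consistent enrichment (at least 4 of the 5 ages), genotype (Brn3a)
  dependency at P3 and at any age, onset/peak/offset of GCL expression,
  sparse high-expressor flag, presence of genotype-independent transcripts
  and gene-level regulation. `none` marks empty cells; `na` the one
  not-assessed cell (Pak6 gene-level regulation).
- `dependency_matrix.tsv` — per-age significant genotype-dependency calls,
  encoded from the per-gene results narrative (each gene's listed significant
  WT-vs-KO ages). Fixture convention: Tusc5, whose GCL signal is described as
  nearly completely lost in the knockout with strong dependency throughout,
  is encoded as dependent at all five ages.

Checksums for all four files live in `checksums.tsv` and are verified by
`laminaquant_fixture()` at load time.
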