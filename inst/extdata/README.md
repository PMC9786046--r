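# Packaged fixture data

- `table2_known_variants.tsv` — 37 database-described ("known mutation")
  variants with their curated phenotype strings, in the package's annotation
  table layout.
- `table3_predicted_variants.tsv` — 43 not-previously-described ("potential
  mutation") variants with per-tool in-silico prediction labels and scores
  (`PP` = predicted pathogenic, `NPP` = not predicted pathogenic, `-` =
  tool output unavailable). Splice-tool columns carry score-delta percents
  (`24.24`, or a lower bound `>20`) and CADD-Splice scaled scores.
- `panel_genes.txt` — the default 40-gene cholesterol-metabolism panel.

Conventions:

- Coordinates are 1-based GRCh37 `chrom:pos`. `ref`/`alt` alleles are
  transcribed from the coding-HGVS nucleotide change (strand unresolved), so
  they identify each record consistently within this package but are not
  guaranteed to match genomic-strand alleles. The frameshift deletion uses a
  synthetic anchor base.
- Population allele-frequency cells are empty: all rows already passed the
  rare-variant filter, and an absent frequency is treated as rare.
- One variant (LPA c.5311C>T) appears in both tables by design; the
  classifier resolves it to the known-mutation category by database
  precedence, while gene/row tallies over the union count both rows.
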