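---
title: "Rare-variant filtering and classification for cholesterol-pathway panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant filtering and classification for cholesterol-pathway panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholvar)
```

## The problem

Targeted resequencing of a gene panel in a disease cohort yields, per patient,
hundreds of variant calls of which only a handful are plausibly
disease-relevant. `cholvar` implements the prioritization pipeline used in
panel studies of cholesterol-metabolism genes in myocardial-infarction
cohorts: a two-stage filter that removes common and likely-inert variants,
a four-category classification that separates *known* from *potential*
mutations, and cohort-level aggregation up to the headline statistic of such
studies — the fraction of patients carrying at least one known or potential
mutation.

The pipeline consumes standard inputs: per-patient VCFs (GRCh37), a
tab-separated annotation table emulating the population-frequency
(gnomAD/dbSNP-style), curated-database (HGMD-style) and in-silico tool
lookups, and a panel gene list. It never recomputes annotations from
sequence; predictions and consequences arrive as annotation fields, which is
how such lookups reach an analyst in practice.

## The filter cascade

Two filters run in fixed order over unique variants (patient multiplicity is
handled later, at the cohort level):

1. **Frequency filter.** A variant is *common*, and removed, when its allele
   frequency in *either* reference database strictly exceeds
   `maf_threshold` (default 0.01, the classical common-variant boundary).
   An absent frequency is treated as zero: a variant recorded nowhere is
   rare by definition. The boundary is exclusive — a frequency of exactly
   0.01 is retained.
2. **Consequence filter.** Synonymous and intronic variants farther than
   `splice_keep_window` bases (default 5) from the nearest acceptor/donor
   splice site are removed. Everything else — all protein-altering
   consequences, canonical splice-site variants, and synonymous/intronic
   variants inside the window — is retained. Splice distance follows the
   HGVS +1/−1 convention (distance 1 is the first base past the exon/intron
   boundary). The `annotation_window` (default ±10 bases) bounds what is
   ingested at all; the keep window bounds what survives.

`filter_report()` tallies the telescoping stage counts (input = common +
rare; rare = consequence-filtered + retained; retained = category I +
category II) and asserts those identities on every construction, so a
violation is an error, not a silent miscount.

## The category decision tree

Retained variants are classified by `classify_variant()` in a fixed order;
the rationale trail records each rule fired, making every assignment
auditable.

1. **Known-database branch.** A variant described in the curated mutation
   database is category **I**; when its recorded phenotype string contains
   any of the configured lipid/cardiac keywords (case-insensitive substring
   match) it is category **Ip**, a *known mutation*. This branch is
   terminal: a described variant never enters the prediction branch, which
   by definition holds only variants "not previously pathology-associated".
   A described variant with no retrievable phenotype string stays plain
   category I and carries a `phenotype_unavailable` rationale entry.
2. **Truncating rule.** Among not-described variants, stop-gained and
   frameshift consequences are category **IIp** outright. (The published
   table this rule anchors on contains a frameshift classified IIp with four
   tools blank, so the rule covers both truncating consequences, not only
   stop gains.)
3. **Missense consensus.** Missense — and other protein-altering coding
   variants, which face the same evidence situation — are IIp when at least
   `consensus_min_pathogenic` (default 3) of the five missense tools
   (Mutation Taster, SNAP2, SIFT, PolyPhen2, PhD-SNP) call them pathogenic.
   A tool without an available call never counts either way, and the
   threshold stays absolute over available tools: 3-of-4-available meets it,
   and a variant with no predictions at all cannot.
4. **Splice consensus.** Splice-proximal variants (canonical splice sites,
   plus synonymous/intronic within the keep window) are assessed by the
   five splice tools (Mutation Taster, BDGP neural network, NetGene2, ASSP,
   CADD-Splice) under the same counting contract. Score-based tools are
   converted to labels by the **splice-delta rule**: a call is pathogenic
   when the score changes by at least `splice_delta_min` (default 20%,
   boundary inclusive) between reference and variant sequence, or when the
   site is lost entirely; a site undetected in the *reference* makes the
   tool uninformative (missing). CADD-Splice scaled scores are labelled
   pathogenic at `cadd_splice_min` (default 20).
5. Anything not meeting its branch's rule stays plain category **II**.

Three choices here were genuinely open and deserve their reasoning:

- **Consensus threshold ≥ 3.** The source material states the rule once as
  "more than three" and once as "at least three"; the published
  potential-mutation table contains several rows with exactly three
  pathogenic calls, which only the inclusive reading reproduces. The
  threshold is configurable for users who want the stricter reading.
- **Phenotype keywords.** No explicit keyword list exists for "lipid
  metabolism disorders or cardiopathies", so the default list was built to
  cover the vocabulary of familial lipid disorders and cardiac/ischemic
  disease. Two non-obvious entries: the stem `"triglycerid"` (the compound
  "hypertriglyceridaemia" does not contain the full word "triglyceride"),
  and `"cd36"` (CD36 deficiency is a lipid scavenger-receptor disorder
  whose phenotype string carries no other lipid token). The list is a
  configuration field, not a constant.
- **Lower-bound score deltas.** Published tables sometimes print a delta
  only as ">20%". Such a cell is pathogenic when the bound already
  guarantees the threshold; under a stricter threshold it would be
  indeterminate and is treated as missing rather than guessed.

One variant can legitimately appear in both anchor tables (a described
variant that also has a damaging prediction profile); classification
resolves it to Ip by database precedence, while table-level tallies keep
both rows, matching how such studies count their totals.

## Cohort aggregation

`read_cohort_vcf()` ingests single- or multi-sample VCFs with presence
semantics: one observation per (patient, variant) pair regardless of
zygosity, because the quantities of interest are carrier counts, not allele
dosages. Multi-allelic records are decomposed into per-allele keys;
`"chr2"` and `"2"` normalize to the same key. Per-call depth (≥ 30) and
site quality (≥ 30) thresholds mirror sequencing-QC practice for clinical
panels and are configurable; they apply at ingestion, the only place this
pipeline can apply them.

`summarize_cohort()` reports per-gene Ip/IIp counts, occurrence and carrier
tallies per class, multi-variant carriers, and `prevalence_any` — the
fraction of patients with at least one Ip/IIp variant.
`gene_carrier_frequency()` gives the per-gene carrier fraction.
Carrier-versus-non-carrier group comparisons use Pearson's chi-squared
without continuity correction for dichotomous covariates (a flag enables
the Yates correction; the default follows the uncorrected Pearson form
that the two-group ANOVA identity F = t² pairs with) and one-way ANOVA
for age. Both are delegated to the standard R implementations behind a
stable interface, and the test suite checks them against independently
hand-computed closed forms.

## The synthetic-cohort generator

No patient-level data ships with studies of this kind, so the generator is
the package's instrument for end-to-end validation. Its defaults *are* the
cohort structure the pipeline targets: 105 patients; 474 unique panel
variants of which 259 are common; 86 of the 215 rare variants synonymous or
deep-intronic; 43 described variants (37 with lipid/cardiac phenotypes) and
43 planted novel damaging variants among the 129 retained; and a
per-patient burden averaging about 83 observed variants, dominated by
common variants (the common-variant carry probability is derived from the
target burden). Planted carrier probabilities default to 0.013 (known) and
0.010 (novel) per patient and variant, placing expected planted occurrence
counts near 50 and 44.

Every variant receives an annotation row consistent with its intended
classification, and ground-truth labels travel with the cohort. Two
planting modes exist: independent per-patient Bernoulli draws (for
estimator-bias checks against the binomial expectation) and a deterministic
mode that plants an exact carrier set (for exact-recovery tests, e.g.
recovering a planted 63/105 = 60% prevalence precisely).
`recovery_experiment()` loops generate → classify → summarize over
replicates and reports classification agreement with truth (exactly 100%
when `score_noise = 0`, by construction of the annotation rows), per-class
sensitivity/specificity, and the prevalence estimate with its standard
error.

What the generator deliberately does **not** emulate: linkage and haplotype
structure, mutation-rate heterogeneity along genes, uneven clustering of
pathogenic variants in a few genes (generated variants spread uniformly
over the panel, so the per-gene distribution is flatter than real cohorts),
read-level errors, and genuinely ambiguous annotation (every generated row
is classifiable without conflict). Green recovery tests therefore show the
*pipeline logic* is faithful, not that real cohorts will reproduce any
particular prevalence.

## Numerical and degenerate-input choices

- Threshold boundaries: frequency is dropped strictly *above* 0.01; the
  splice delta is pathogenic *at* 20%; the consensus needs *at least* 3.
- Empty inputs yield all-zero reports rather than errors; duplicate unique
  variant keys are an error instructing deduplication (silent collapsing
  would corrupt the stage counts).
- Validation is front-loaded: frequencies outside [0, 1], a missing splice
  distance where one is required, out-of-panel genes, and observations for
  unknown patients all fail fast with specific messages.
- Reports are byte-stable for identical inputs; rationale entries are
  recorded in fixed tree order so diffs of two runs are meaningful.
- Test problem sizes: property tests run the generator at 40–60 variants
  and about a dozen patients over a few seeds, with one 200-replicate
  recovery experiment; the packaged full-size configuration (474 × 105)
  runs in the examples and remains fast.

## Known limitations

- The phenotype keyword list is a pragmatic instrument, not an ontology;
  phenotype strings outside its vocabulary demote a known mutation to plain
  category I. Users matching against a different curated database should
  review it.
- Fixture `ref`/`alt` alleles are transcribed from coding-HGVS changes with
  strand unresolved; they are self-consistent identifiers, not
  genomic-strand truth.
- The pipeline trusts its annotation table. Wrong consequences or splice
  distances propagate; no re-annotation from sequence is attempted.
- Group-comparison helpers cover the dichotomous-covariate and two-group
  age designs of a descriptive cohort paper; they are not a general
  association-testing framework, and no multiple-testing correction is
  applied.
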