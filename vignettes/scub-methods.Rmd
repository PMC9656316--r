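---
title: "Synonymous codon usage bias with exon and intron stratification: methods"
author: "scubr developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synonymous codon usage bias with exon and intron stratification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scubr)
```

## The problem

Synonymous codons encode the same amino acid but are not used at equal
frequency: this synonymous codon usage bias (SCUB) shifts during evolution
and domestication, and in plant genomes it is structured along at least three
axes — the baseline preference for C/G-ending third bases, a drift toward
A/T-ending codons in genes with more introns, and a convex ("∩") enrichment
of A/T-ending codons in the internal exons of multi-exon genes. A fourth
signature ties SCUB to DNA methylation: 5-methylcytosine deaminates to
thymine, so CpG dinucleotides decay into TpG (read on the strand carrying
the C) and CpA (read on the opposite strand). At the codon level this
predicts an excess of `NCA` relative to `NCG` (second-base context) and of
`NT|G` relative to `NC|G` (next-codon first-base context).

`scubr` implements the complete analysis path: CDS extraction from genome
FASTA + GFF3, phase-aware codon-to-exon assignment, SCUB frequency
statistics stratified by chromosome, intron number and exon position,
methylation-context codon-combination ratios, the classic indices (RSCU,
CAI, CBI, Wright's Nc), and the downstream comparisons (chi-square
cross-table tests, Welch t-tests, coefficients of variation, average-linkage
correlation-distance clustering, PCA). Because real genome releases drift, a
seed-deterministic synthetic genome generator provides ground truth for
every stage.

## Statistics

All synonymous-codon statistics run over the **59-SC set**: the 61 sense
codons minus ATG (Met) and TGG (Trp), which have no synonym. Serine is
treated as a single six-codon family (TCT/TCC/TCA/TCG/AGT/AGC).

* **Total SCUB frequencies** `f_NNA`, `f_NNT`, `f_NNC`, `f_NNG`: fractions
  of 59-SC occurrences by third base (they sum to 1); `f_NNAT`/`f_NNCG`
  pool the pyrimidine/purine-... strictly, the A/T- versus C/G-ending
  classes, and their ratio summarises the wobble-position bias.
* **Per-amino-acid SCUB frequency**: for each of the 18 degenerate amino
  acids, the pooled count of its C/G-ending SCs divided by the count of its
  A/T-ending SCs.
* **RSCU**: `count * family_size / family_total`; values in a non-empty
  family average to exactly 1.
* **CAI**: geometric mean of relative adaptiveness `w = RSCU / max(RSCU)`
  over SC occurrences. The classic implementations require an external
  reference set which the source workflow does not pin down, so the default
  reference is the scope's own usage (self-referential weights, CAI = 1 iff
  only the most frequent codon of each family is used); an external weight
  table can be supplied. Zero/missing weights are floored at 0.01.
* **CBI** (Bennetzen–Hall): `(N_pref - N_rand) / (N_tot - N_rand)` with one
  preferred codon per family (most frequent, ties alphabetical) and
  `N_rand = sum(n_fam / k_fam)`.
* **Nc** (Wright): `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with `Fk` the mean codon
  homozygosity over k-fold families with at least two counted codons;
  non-positive family homozygosities are treated as missing (the usual
  practical convention), a missing 3-fold class is replaced by
  `(F2 + F4)/2`, and the result is clamped to `[20, 61]`.
* **Undefined ratios** (zero denominators) propagate as `NA`, never as
  `Inf` or 0.

### Conventions with a choice behind them

* **Transcript selection**: one transcript per gene, the first mRNA child in
  GFF3 document order (the most literal reading of "first transcript"; a
  lexicographic-ID mode is available).
* **Coordinates**: GFF3 is 1-based inclusive; everything internal is 0-based
  half-open.
* **CDS filters**, applied in a fixed order so reports are deterministic:
  length not a multiple of three, contains N, start codon not ATG, final
  codon not TAA/TAG/TGA. The CDS is expected to include its stop codon
  (EnsemblPlants convention) — a CDS without one is rejected as `bad_stop`.
* **Codon-to-exon assignment**: a codon split after its first nucleotide
  belongs to the downstream exon, after its second to the upstream exon —
  equivalently, the exon owning the codon's middle nucleotide. This makes
  per-exon codon counts exactly partition the CDS.
* **Exon/intron counts** are over *coding* exons only; all codon statistics
  are CDS-based, so UTR-only exons never enter.
* **Neighbor context is CDS-contiguous**: `next_first_base` walks the
  spliced CDS, so an intron between two adjacent codons does not break the
  CpG context. The final sense codon takes its context from the stop codon
  (part of the CDS string); `drop_final_codon_context` disables that donor.
* **Terminal vs internal exons**: terminal = first, second and last;
  internal = third through last-but-one (empty for genes with three or
  fewer exons). Per-ordinal statistics are pooled-count ratios across all
  genes of an exon-count class, not per-gene averages.
* **Intron classes** run 0–9; genes with ten or more introns stay in
  genome-wide totals but are excluded from the class tables (configurable).
* **Methylation-context denominators**: `NT|X / NC|X` uses *all* C-ending
  SCs, purely positionally; the family-restricted variant lives in the
  per-amino-acid pair ratios (the 11 amino acids owning an NNA/NNG sibling
  pair with identical first two bases; for Leu and Arg both sibling pairs
  are pooled).
* **Statistics**: Pearson chi-square without continuity correction (counts
  are genome-scale); Welch t by default (pooled optional); no
  multiple-testing correction — raw p-values are reported, as in the
  workflows this package mirrors. Clustering uses average linkage on
  `1 - Pearson correlation`, with heights also reported on the similarity
  scale `100 * (1 - d/2)` used by classic clustering GUIs. PCA is on
  centered (optionally standardized) features with a deterministic sign
  convention: each component is flipped so its largest-magnitude loading is
  positive.

## The synthetic generator: what it emulates, and what it does not

`generator_spec()` describes a genome as a stated world: 1–10 coding exons
per gene (default distribution decaying from single-exon genes, every
intron class 0–9 populated), exon lengths of `2 + Poisson(18)` codons,
uniform composition over the 18 degenerate amino acids plus a 5% Met/Trp
background, and third bases drawn with C/G log-odds

```
eta = beta0 + beta_first * [first exon] - beta1 * introns - beta2 * w(ordinal, m)
```

followed by the CpG-context re-weighting `gamma` (A endings after a C in
the second position; T endings before a next codon starting with G). The
two-pass scheme — amino acids and first-two-base prefixes first, third
bases second — makes the next codon's first base well-defined at draw time.
The class probability is exactly `plogis(eta)` for every draw (endings are
uniform within the available A/T and C/G endings of a prefix group), which
is what makes the generator's expectations analytically checkable.

Default parameters are chosen once to portray the rice-like world the
package is aimed at: `beta0 = 1.1` puts the genome-wide NNA/T : NNC/G ratio
in the 0.6–0.7 band reported for rice genomes *after* the other effects;
`beta1 = 0.1` brings nine-intron genes near A/T-C/G parity, mirroring the
observed weakening of C/G preference with intron number; `beta2 = 0.3`
produces the convex internal-exon A/T excess; `gamma = 1.5` inflates
NCA/NCG and NT|G/NC|G above their within-second-base peers. `beta_first`
(default 0.15) is this package's own addition: with the centrality weight
pinned to zero at ordinals 1, 2 and m, the three terminal exons would be
exchangeable in expectation, whereas real first exons are distinctly more
C/G-biased; a small extra first-exon C/G log-odds reproduces that strict
first-exon minimum in `f_NNAT`.

`paired_species()` shares *all* structural randomness — exon architecture,
intron sequences, amino-acid and prefix draws — between the two genomes and
redraws only third bases under each parameter set. That is a deliberate
strengthening of "identical exon architecture, independent codon draws":
it isolates the wild/cultivated contrast in exactly the parameters that
differ, which is what the recovery tests need.

What the generator does **not** emulate: real base composition outside
coding regions (introns are arbitrary `GT...AG` filler, spacers a single
base), UTRs, alternative transcripts, overlapping genes, selenocysteine or
non-standard codes, and any actual methylation data — the CpG effect is a
sequence-context proxy only. A green recovery test therefore establishes
that the pipeline measures what the generator planted, not that any real
genome behaves this way.

## Numerical and degenerate-input choices

* Empty scopes (no sense codons / no SCs) are hard errors rather than NaN
  tables; strata with no codons yield `NA` rows.
* Tie-breaks are deterministic everywhere (preferred-codon ties go
  alphabetical; PCA signs are fixed by the largest-loading rule), so reruns
  are byte-identical.
* Feature columns containing `NA` are dropped (with a message) before
  clustering or PCA; constant rows are an error naming the row, since a
  correlation distance is undefined for them.
* Two zero-variance samples with equal means give `t = 0, p = 1` by
  convention; CV errors on a zero mean.
* `Nc` is clamped to `[20, 61]`; under the generator's "uniform" world the
  3-fold family (Ile) is uniform over its A/T endings but its single
  C-ending codon takes half the mass, so the expected Nc is ≈ 60.7, inside
  the documented 0.5 band of the 61 limit — the band is not slack, it
  covers this structural effect.

## Known limitations

* The first-mRNA selection rule depends on GFF3 document order; annotations
  that interleave features unusually may need the ID-sorted mode.
* CAI without an external reference is self-referential and therefore not
  comparable across scopes with very different usage; supply a weight table
  for cross-species comparisons.
* The chromosome tables keep every sequence region present in the input;
  restricting to named chromosomes is the caller's choice.
* With only two species the PCA stage is skipped (a plane needs three
  rows); the clustering and contrast tables still run.
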