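---
title: "Genome-wide nsLTP surveys with nsltpkit: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide nsLTP surveys with nsltpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsltpkit)
```

## The problem

Plant non-specific lipid transfer proteins (nsLTPs) are small, mostly basic
secreted proteins that shuttle lipids between membranes and respond to
abiotic stress. The family is defined by an eight-cysteine motif (8CM),

```
C - Xn - C - Xn - CC - Xn - CXC - Xn - C - Xn - C
```

whose backbone of disulfide-forming cysteines is rigidly conserved while
the inter-cysteine spacings vary by subfamily. A genome-wide survey of the
family proceeds from a pile of candidate proteins (harvested elsewhere by
BLAST/HMM/keyword searches) through a screening funnel, physicochemical
profiling, type classification, phylogeny, gene-structure and duplication
analysis, promoter scanning and expression summaries. `nsltpkit`
implements that entire downstream pipeline as composable, tibble-first
functions, together with a seeded synthetic-cohort generator so every
stage is testable offline.

## Screening funnel

`run_screen()` applies the classical stages in order:

1. **8CM presence** — `find_8cm()` enumerates every cysteine 8-tuple
   satisfying the CC adjacency, the single-residue CXC core, configurable
   gap bounds and a maximal span. When several motifs exist, the canonical
   one is the leftmost start with the smallest span.
2. **N-terminal signal sequence (NSS)** — `detect_nss()` is a transparent
   hydrophobicity heuristic: a run of at least 8 consecutive residues
   (within the first 45, beginning within the first 12) with mean
   Kyte–Doolittle hydropathy ≥ 1.5, cleaved at the first A/G/S/C after the
   run. Neural predictors (SignalP-class tools) are deliberately not
   re-implemented; their calls can be injected through the `annotations`
   table and then win verbatim. Note that cysteine is a legal cleavage
   residue, so a cleavage site falling on the first motif cysteine is a
   valid (if conservative) call; the candidate is still typed from its
   precursor motif.
3. **GPI anchor** — `detect_gpi()` flags (and *retains*) candidates whose
   C-terminal 25 residues average ≥ 1.0 hydropathy with an ω-site
   candidate (S/G/A/N/D/C) 20–30 residues from the C-terminus. When
   several candidates sit in that window the most C-terminal one is
   chosen, which keeps the longest possible mature chain. The mature
   sequence of GPI-positive proteins is truncated at ω − 1.
4. **Proline-rich exclusion** — hybrid proline-rich proteins are excluded
   when the segment between the cleavage site and the first motif cysteine
   is ≥ 15 residues with a P+H+G fraction ≥ 0.35.
5. **Storage-protein exclusion** — global-alignment identity ≥ 30% to any
   sequence in an exemplar list (2S-albumin/inhibitor-like). The package
   ships only a clearly-labelled *synthetic* exemplar for testing; real
   surveys should supply their own FASTA.
6. **Maturity length** — an optional cut on mature length. It is **off by
   default**: published catalogs list mature nsLTPs up to 200 aa, so a
   blanket 120-aa rule would contradict the very tables it produced.
   Setting `max_mature_length` restores it.

The funnel report satisfies exact conservation: input = accepted + the sum
of the per-stage exclusions.

The default gap bounds (g1..g5 ∈ [2,40], [2,50], [2,60], [2,50], [2,40];
span ≤ 160) are deliberately generous — every catalogued architecture
passes — and fully configurable; they are plumbing, not biology.

## Physicochemical profiling

`physchem_profile()` computes mature/precursor length, molecular weight
(average isotopic masses, one water for the termini), theoretical pI
(bisection of the Henderson–Hasselbalch net charge with the Bjellqvist pKa
set used by the ExPASy Compute pI/Mw tool, to |charge| < 1e-4 on [0, 14]),
the Guruprasad instability index (10/L times the sum of dipeptide weight
values), the Ikai aliphatic index and the Kyte–Doolittle GRAVY. Unknown
residues (`X`) take neutral fallbacks: the mean residue mass, hydropathy
0, dipeptide weight 1. `summarize_cohort()` reports per-group means with
the catalog's printed precision (masses to 1 Da, pI to 2 decimals,
lengths to integers), and `load_table1()` ships the 75-entry barley/Qingke
reference catalog used by the package's regression tests.

Because published catalogs are ambiguous about precursor vs mature input,
`physchem_profile()` takes the sequence column as an argument; profile
both and compare.

## Classification

`assign_type()` types each accepted protein by a deterministic cascade:
GPI-positive ⇒ type G; otherwise the profiles whose five gap ranges all
contain the protein's spacing vector (and whose intron expectation matches
the gene model, when one is linked) are candidates; ties break by highest
mean identity to per-type exemplars, then the lexicographically smallest
label; with no candidate and no exemplar above 30% identity the protein is
typed X. Confidence is the mean exemplar identity (0 for rule-only calls).

The shipped spacing ranges (`type_profiles()`) are *editable
configuration*: surveys in this family never print their discriminating
thresholds, so the defaults are ranges in the style of the
Edstam classification with disjoint CC–CXC gaps for the four major types
(1, 2, D, G), which makes rule-based typing unambiguous on clean data.
Identity is computed on mature sequences with a global alignment scoring
match +1, mismatch 0, linear gap −1, identity = identical pairs /
alignment columns.

`build_anchored_alignment()` aligns motifs by construction — each gap
block right-padded to its maximum width — so cysteine columns are 100%
conserved and the width is exactly 8 + Σ max block widths + 1.
`cxc_polarity()` classifies the CXC centre residue by the sign of its
hydropathy.

## Phylogeny

`p_distance()` computes mismatch proportions with pairwise deletion of
gapped columns (complete deletion available). `nj_tree()` is a
Saitou–Nei neighbour-joining implementation with the standard Q-criterion,
deterministic tie-breaking (smallest Q, then lexicographically smallest
label pair) and negative branch lengths clamped to zero; it recovers
additive matrices exactly and is cross-checked against an independent
implementation in the test suite. `bootstrap_support()` resamples
alignment columns, rebuilds the tree per replicate, and reports bipartition
percentages on the reference tree; a single seed makes runs reproducible.

## Gene structure, chromosomes, duplications

`intron_stats()` reports intron counts and offsets in bp from the first
base of the codon encoding the eighth motif cysteine. Offsets are measured
**along the spliced coding sequence** in transcript orientation (negative =
upstream): that is the only measure under which several introns can all
lie within a few dozen bp of the codon, and it is invariant under
reflection of the locus because the exon walk is strand-aware.

`find_duplications()` follows the common tandem-array convention: a pair
of family genes is *tandem* when their proteins share ≥ 50% identity on
the same chromosome within 100 kb and at most 5 intervening family genes;
high-identity pairs failing the geometry are labelled
`segmental_candidate` — candidates, not calls, because true segmental
assignment needs synteny blocks, which are out of scope. Clusters are the
transitive closure of tandem pairs. `chromosome_map()` orders genes per
chromosome and sidelines unplaced genes (`chrUn`) from the counts.

## Promoters

`extract_upstream()` takes the 1.5 kb immediately upstream of the
**translation start** (the first CDS base) — not the transcription start —
because that is how the field's promoter scans are anchored in practice;
windows are truncated with a warning at contig edges. `scan_promoter()`
is a from-scratch IUPAC-degenerate consensus scanner on both strands:
overlapping hits are all reported, `N` in the genome matches nothing, and
palindromic double-hits at one footprint collapse to strand `±`. The
packaged catalog (`cis_element_catalog()`) carries PlantCARE-style
consensus strings as editable YAML — catalog releases differ, so the
strings are configuration, not asserted fact. `compare_organization()`
defines *identical organization* as equality of (element, start, strand)
multisets.

## Expression

`relative_quantity()` implements 2^−ΔΔCt: technical replicates are
averaged per biological sample, ΔCt = Ct_target − Ct_reference, ΔΔCt is
taken against the mean calibrator ΔCt, and the per-condition relative
quantity is `2^−(mean ΔΔCt)` — the geometric-mean form, under which the
calibrator is *exactly* 1 (an arithmetic mean of per-replicate 2^−ΔΔCt
would exceed 1 by Jensen's inequality). The standard error is taken over
the per-replicate 2^−ΔΔCt values. Significance versus the calibrator is a
two-sided Welch t-test on ΔCt values — the field's figures show stars but
never name a test, so this is a documented assumption; in the noise-free
degenerate case (zero variance in both groups) the p-value is defined as
1 for equal means and 0 otherwise. Stars follow `**` p < 0.01, `*`
p < 0.05, `ns` otherwise.

`heatmap_matrix()` applies log2(x+1) and an optional per-row z-score
(zero-variance rows map to 0, never NaN); display order comes from
average-linkage clustering of correlation distance. Primer-efficiency
correction is not modelled; the reference gene enters only through the
Ct_reference column.

## The synthetic cohort generator

`generate_cohort()` emits a complete, internally consistent survey: a
candidate proteome, a genome with gene models and promoters, an FPKM
tissue matrix and a long-format qPCR table, plus a ground-truth manifest.
Its defaults *are* the study conditions of a barley-scale survey:

* 16/5/11/8 true genes of types 1/2/D/G and 107 cysteine-deficient + 11
  signal-less + 2 proline-rich decoys, so the funnel reads
  160 → 107/11/2 → 40;
* a Table-1-style chromosome layout (11 genes on chr2, one on chr6, one
  unplaced), two 3-gene tandem clusters (six tandem pairs) and one
  cross-chromosome segmental pair built as 5%-mutated copies of their
  founders;
* an intron plan of 1/0/(3 of 11)/2 introns for types 1/2/D/G at spliced
  offsets +30/—/−9/(+12, +60) bp from the eighth-cysteine codon. Offsets
  near the +104 end of the plausible interval are geometrically impossible
  for proteins with short C-terminal tails (there is simply not enough
  coding sequence downstream of the codon), so the defaults exercise both
  signs within what the synthetic proteins allow; impossible configurations
  error before emission;
* 1.5 kb promoters with two core elements (TATA at −80, CAAT at −200) and
  three randomly placed, non-overlapping catalog elements per gene, planted
  on either strand as concrete instantiations of their degenerate
  consensus;
* qPCR fold changes drawn from {0.25, 0.5, 2, 4} with biological Ct noise
  σ = 0.1 cycles and technical noise 0.05, 3 × 3 replicates; an FPKM matrix
  over 16 tissue labels with one tissue planted silent and tissue-specific
  spikes for types 1 and 2.

All randomness flows from one master seed through fixed per-stage
substreams (proteins, genome, promoters, expression), so a fixed seed
reproduces the bundle byte-for-byte and skipping one stage never perturbs
another. Back-translation uses a fixed most-frequent-codon table and the
genomic background is i.i.d. uniform ACGT — adequate for coordinate
arithmetic and scanner tests, *not* for codon usage, GC structure or
read-level realism. Passing tests on this cohort therefore demonstrates
algorithmic correctness (coordinates, invariants, recovery under
controlled noise), not performance on real genomes, where signal-peptide
and GPI heuristics in particular are cruder than the neural predictors
they stand in for.

`mutate_cohort()` degrades protein sequences at a chosen rate while
preserving cysteines (never creating one), for classifier-robustness
curves.

## Numerical choices and degenerate inputs

* pI bisection: bracket [0, 14], |charge| < 1e-4, ≤ 100 iterations; the
  termini guarantee a crossing.
* NJ tie-breaks are deterministic (Q, then labels); Newick branch lengths
  serialize at 12 significant digits so additive metrics round-trip to
  < 1e-8.
* p-distance errors loudly on a pair with zero comparable columns, naming
  the pair.
* Empty screens return all-zero reports; empty catalogs return empty hit
  tables; all-zero expression rows transform to zeros, never NaN.
* Coordinates are 0-based half-open internally, 1-based inclusive in all
  I/O (GFF3, hit tables, reports).

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full 160-protein
funnel, a 500-sequence motif-scanner/oracle comparison (≤ 200 aa,
controlled cysteine counts), 200 random additive trees (≤ 12 taxa), 1000
random peptides for the pI invariant, 1000 random mini-cohorts for funnel
conservation, 200 seeded qPCR trials, and the 75-entry reference catalog
— sizes chosen to exercise every code path at survey scale while keeping
a full run in the order of a minute or two.

## Known limitations

* NSS/GPI detection is a hydrophobicity heuristic with override hooks, not
  a trained predictor; on real proteomes, inject SignalP/big-PI calls via
  `annotations`.
* Segmental duplications are labelled candidates only (no synteny).
* Promoter consensus strings vary between catalog releases; conclusions
  about element counts are only as good as the supplied catalog.
* Type C/E/F profiles are best-effort configuration; the barley/Qingke
  family lacks those types, so they are untested against real members.
* No database harvesting, no motif discovery, no 3D structure or
  subcellular localization, no collinearity analysis, no read-level
  RNA-seq processing.
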