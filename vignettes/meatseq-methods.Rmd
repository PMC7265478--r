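---
title: "meatseq: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meatseq: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science and the engineering decisions behind
`meatseq`: what the pipeline assumes, why its defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
numerical corners are.

## The identification model

The unit of identification is the *meat category*: a user-configurable group
of taxa (typically genera) that the market treats as one meat. The shipped
13-category scheme (pork, beef, mutton, chicken, rabbit, rat, venison, horse,
camel, bear, dog, cat, fox) assigns representative genera to each category;
`mutton`, for instance, spans *Capra*, *Ovis* and *Pseudois*. Category
matching is case-insensitive whole-token matching against species-name words
and explicit taxon labels — deliberately no fuzzy matching, because a silent
mis-assignment of a reference genome corrupts every downstream call
(predictability over recall). A taxon may belong to only one category; a
violation is a load-time error rather than a warning for the same reason.

Reads are assumed to come from a mitochondrial marker amplicon (the
CB1-5/CB3A *CYTB* product of roughly 385 bp, sequenced as ~300 bp merged
reads) or from whole-mtDNA shotgun data. Mitochondrial DNA is the right
compartment for food forensics: high copy number survives processing, and
the *CYTB* region carries genus-level phylogenetic signal.

**Mapping.** The internal aligner is a k-mer seed (k = 21) plus ungapped
extension along the seed diagonal, both strands, best hit per genome. It is
*ungapped by design*: amplicon reads are near-full-length matches to their
templates and indel divergence between congeneric mitogenomes at this scale
is rare, so gapped alignment would add cost and a tie-breaking surface
without changing category decisions. Hits need identity ≥ `min_identity`
(0.90) over ≥ `min_cov` (0.80) of the read. One best hit per genome is kept
(most matches, then highest identity, then leftmost, then forward strand) so
that repeated hits *within* one genome can never masquerade as multi-genome
evidence.

**The unique-read rule.** A read is credited to a category only when *all*
of its hit genomes belong to that category; reads whose hits span two or
more categories are discarded, and reads with no hits are unmapped. The
accounting identity `sum(counts) + discarded + unmapped == total_reads`
holds on every run and is asserted in the container constructor. Discarding
is the pipeline's central robustness device: conserved mitochondrial
stretches (the classic case being the near-identical *CYTB* regions of sheep
and deer relatives) produce reads that genuinely cannot distinguish
categories, and counting them anywhere would manufacture false positives.

**Reporting.** Proportions are per-category unique reads over total unique
reads; discarded/unmapped reads are excluded from the denominator. The
method is qualitative — primer-binding efficiency differs across taxa, so
read proportions are biased estimates of mass fractions. Presence is called
at ≥ 0.5% of mapped unique reads: comfortably above the residual
conserved-region false-positive level (~0.1–0.2% in the six-component
reference mixture) and comfortably below real ~1% components (a 1% chicken
component measures ~0.7% of reads). Concordance against a reference method
(fluorescence qPCR) is computed per (sample, category) pair over an
*explicit* user-supplied universe; the counts TP/FP/FN/TN and rates follow
the usual definitions, with rates reported as `NA` when their denominator is
zero. The universe is explicit because published comparisons of this kind
rarely pin down their denominator; the function errors on mismatched
universes instead of guessing.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 21 | bp | specific in a ~16.5 kb mitogenome (4^21 >> genome size); with ≤ 4 mismatches in a 100 bp read a seed provably survives |
| `min_identity` | 0.90 | fraction | separates congeneric templates (≥ ~0.97 observed identity) from cross-category ones (~0.85 at typical between-genus divergence) |
| `min_cov` | 0.80 | fraction of read | tolerates reads overhanging amplicon/reference edges without admitting local spurious matches |
| `max_mismatch` (primers) | 3 | bases | universal primers tolerate a few internal mismatches across vertebrate templates |
| `exact_3prime` | 2 | bases | polymerase extension requires a matched 3' terminus; mismatches there abolish amplification |
| product length | 250–500 (CYTB preset) | bp | brackets the ~385 bp CB1-5/CB3A product |
| presence threshold | 0.5 | % of mapped unique reads | above conserved-region false positives, below real 1% components |
| `min_length` (reads) | 50 | bp | shorter reads carry too little marker information; counted unmapped with a warning |
| subsampling mode | exact-count | — | `floor(N·ratio)` without replacement makes published subsample sizes exactly reproducible (0.5% of 1,764,067 reads = 8,820); Bernoulli mode is available |
| Std. Dev. | sample (n−1) | — | standard "Std. Dev." usage for replicate summaries |

Primer presets carry the exact published sequences: CB1-5
`CCATCCAACATCTCAGCATGATGAAA` / CB3A `CCCTCAGAATGATATTTGTCCTCA` (*CYTB*),
COIF/COIR (*COI*), CE CVZV 1/2 (D-loop).

IUPAC handling is asymmetric on purpose: ambiguity codes in a *primer*
match their expansion sets (that is what a degenerate primer means), while
ambiguity codes in a *template or reference* are literal and match nothing —
they count as mismatches and never seed the mapper. Expanding reference
ambiguities would cost combinatorial index growth to handle characters that
are vanishingly rare in curated mitogenomes.

Reference templates are treated as circular (mitogenomes) for in-silico PCR,
so products spanning the origin are found; a product can never exceed the
template length. The read mapper treats genomes linearly: simulated and real
amplicon reads live inside the marker locus, and a wrap-around read would at
worst be unmapped, never mis-assigned.

## The synthetic world

`make_world()` generates the world the tests and the detection-limit checks
run in: one random ancestral sequence; per-category roots mutated at half the
*between*-category divergence; species genomes mutated from their root at
half the *within*-category divergence (divergence parameters are therefore
approximate *pairwise* substitution fractions); a universal-primer cassette
(forward primer + the genome's own divergent interior + reverse-complemented
reverse primer) implanted at one fixed locus, giving a 385 bp amplicon; and
optional conserved blocks copied verbatim into all genomes of selected
category sets, *inside* the amplicon, to emulate the near-identical *CYTB*
stretches that make related meats confusable and to exercise the discard
rule. Defaults: 13 categories x 2 species, 16 kb genomes, between-divergence
0.15 and within-divergence 0.02 — the order of between-genus and
within-genus mitochondrial divergence at this marker.

`simulate_reads()` draws a category per read from the mixture, a species
uniformly within the category, a fragment position uniform in the amplicon
(or genome-wide in shotgun mode), a random strand, and i.i.d. substitution
errors (0.5% per base by default, a reasonable post-merge Illumina figure).
`simulate_h1_like()` fixes the mixture at the six-component reference
composition 40.38/22.70/22.40/10.83/2.54/1.08% with 30,000 reads — the
throughput at which the method is recommended to operate — so the ~1%
detection-limit property is probed where it matters.

What the generator does **not** emulate — and hence what a green test does
not establish: per-taxon amplification-efficiency bias (the dominant cause
of quantitative error on real data; a per-category efficiency multiplier is
a documented extension point, not implemented), indels and structural
variation, chimeric PCR products, quality-score structure, and real
phylogenetic tree shape (categories are equidistant by construction).
Green detection-limit tests say the *pipeline logic* resolves a 1% component
at 30,000 reads; they do not certify a wet-lab limit of detection.

## Numerical choices

- **Rounding** is half-up to 2 decimals, applied only at presentation
  (printed tables round half-up; base R's `round()` is round-half-even).
  Internal arithmetic is unrounded, and the unrounded proportions sum to
  exactly 100 whenever any read mapped. Difference columns are computed from
  the presentation-rounded proportions, matching how such tables are
  actually derived.
- **Known source discrepancy:** in the published six-component table the
  beef and pork *target* percentages (22.70, 2.54) are not the ratios of the
  printed concentrations (which give 22.76, 2.55). The arithmetic definition
  is implemented; the discrepancy is asserted as such in the tests, not
  emulated.
- **NJ determinism:** ties on the Q-criterion are broken by the
  lexicographically smallest label pair, where an internal node is keyed by
  the smallest leaf label in its clade; degenerate all-equal matrices
  therefore give a stable, documented topology. Negative branch-length
  estimates (possible on non-additive input) are clamped to zero and the
  total clamped amount is recorded in the tree's `clamped` attribute.
- **Alignment:** amplicons from a common primer-delimited locus are aligned
  by center-star end-gapping only (longest sequence as center, best ungapped
  offset per sequence, ties to the smallest shift). Internal indels are not
  modeled — consistent with the substitution-only world and the ungapped
  mapper. Columns with > 50% gaps are dropped before distances; sites with
  non-ACGT characters are excluded pairwise. Distances are p-distances with
  an optional Jukes–Cantor transform; the published tree used a composite
  likelihood distance (and mentions UPGMA), but category-level separation is
  robust to the distance model, so the simpler metric with NJ (as the figure
  caption states) is implemented and the substitution is documented.
- **Replicate seeds** for the subsampling study are derived from
  (base seed, ratio index, replicate) through an LCG-style integer hash.
  A naive linear combination produced arithmetic-progression seeds, which
  correlate R's Mersenne-Twister initialisation enough to inflate
  between-replicate variance by ~50% — detected because the RSD invariant is
  tested against binomial/hypergeometric theory. Hash-derived seeds restore
  agreement with theory.
- **Degenerate inputs** are first-class: empty FASTQ files yield all-zero
  counts; empty count vectors yield header-only CSVs; all-negative
  concordance reports `NA` rates; a zero target makes the relative
  difference undefined (`NA`), never `Inf`.

## Oracle-test design

Every non-trivial operation is tested against an independent path: naive
substring search for the k-mer index, a character-level IUPAC Hamming scan
for primer sites, exhaustive-offset alignment for the mapper, per-read rule
application for the classifier, enumeration of all unrooted topologies
(4–5 leaves) plus `ape::nj` for neighbor joining, and edge-removal flooding
for monophyly. One subtlety is worth recording: a seed-free oracle can
accept an alignment at exactly the identity threshold whose mismatches are
spread so evenly that no exact 21-mer survives, which the seeded mapper then
legitimately misses. The oracle worlds therefore use between-category
divergence 0.30, far from the 0.90 threshold, so that every cross-category
decision is unambiguous and oracle equality is exact; identity near the
threshold occurs only inside conserved blocks, where long exact runs
guarantee seeds.

## Limitations

- Qualitative only: no amplification-bias correction, so proportions are not
  mass fractions (correction factors are future work).
- Ungapped alignment throughout; divergent taxa with marker indels would
  need the SAM-ingestion path with an external gapped aligner.
- Mate pairs are classified independently; read merging is upstream.
- No bootstrap support or full progressive MSA in the marker phylogeny;
  the tree is a resolution check, not a publishable phylogeny.
- Reference curation is the caller's: the package gates mitogenome length
  (12–20.5 kb, warning) but does not resolve taxonomy IDs or download data.
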