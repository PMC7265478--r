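# meatseq

Identification of animal-derived components in meat products from
high-throughput sequencing reads.

## The problem

Adulteration and mislabeling of meat products are routinely policed with
species-specific PCR assays, which scale poorly as products mix more and more
species. An alternative is DNA metabarcoding: amplify a short mitochondrial
marker (a ~385 bp stretch of the *CYTB* gene bounded by the universal primers
CB1-5/CB3A), sequence the amplicons, and map every read against a curated
database of complete mitochondrial genomes grouped into *meat categories*
(e.g. "mutton" spans *Capra*, *Ovis* and *Pseudois*). `meatseq` implements
that workflow end to end for analysts who need qualitative multi-species
calls from amplicon (or whole-mtDNA shotgun) reads.

## The method

Each read *r* is aligned to every reference genome sharing an exact k-mer
seed (k = 21 by default) by ungapped extension; hits with identity ≥ 0.90
over ≥ 0.80 of the read are kept, at most one per genome. With
C(r) = { category(g) : g a hit genome of r }, the **unique-read rule** is

- |C(r)| = 0 → unmapped,
- |C(r)| = 1 → the read counts for that single category,
- |C(r)| ≥ 2 → the read is discarded (it cannot distinguish the categories).

The per-category proportion is p̂_c = n_c / Σ_c n_c (discarded and unmapped
reads excluded), and a category is called present when p̂_c ≥ 0.5%. The
method is qualitative: amplification bias makes the proportions unreliable as
mass fractions, which is why reporting includes absolute/relative differences
against a known target composition. Sequencing throughput is tuned by seeded
subsampling: at extraction ratio ρ the relative standard deviation of a
category with proportion p scales like √((1−p)/(n·p)) across replicates.

## Worked example

```r
library(meatseq)

w   <- make_world(seed = 7)            # 13 categories x 2 synthetic mitogenomes
db  <- world_db(w)                     # k-mer indexed reference database
sim <- simulate_h1_like(w, seed = 7)   # 30,000 amplicon reads, six components
cc  <- classify_reads(sim$reads$seq, db)
compute_proportions(cc)
```

```
  category reads_mapped proportion_pct
1   mutton        11849          39.73
2     beef         6913          23.18
3   rabbit         6674          22.38
4      rat         3262          10.94
5     pork          809           2.71
6  chicken          315           1.06
```

The simulated mixture contained 40.38 / 22.70 / 22.40 / 10.83 / 2.54 / 1.08 %
of mutton, beef, rabbit, rat, pork and chicken: all six components, including
the ~1% chicken minority, are recovered above the 0.5% presence threshold
(`call_presence(compute_proportions(cc), 0.5)`), and 178 of 30,000 reads were
discarded as cross-category evidence. Real data enter through
`classify_fastq("reads.fastq.gz", db)` or, for external alignments,
`ingest_sam("aln.sam", db)`.

Marker sanity checks: `slice_marker_panel(db)` performs in-silico PCR on
every genome (CB1-5/CB3A preset), and

```r
panel <- slice_marker_panel(db)
tr <- nj_tree(amplicon_dist(align_amplicons(panel$amplicons)))
category_coherence(tr)$fraction   # 1 on this synthetic panel
```

builds the neighbor-joining tree of the amplicons and checks that meat
categories form clean clades.

## Command line

Every step is scriptable through `meatseq::run_cli()` (wrapper in
`inst/scripts/meatseq`):

```sh
meatseq build-db   --fasta ref.fa --categories categories.cfg --k 21 --out db/
meatseq insilico-pcr --db db/ --preset cytb --max-mismatch 3 --out amplicons.fa --skips skips.txt
meatseq classify   --db db/ --fastq reads.fastq --out result.csv
meatseq report     --counts counts.csv --target target.csv --out report.csv
meatseq subsample  --fastq in.fastq --ratio 0.005 --seed 7 --out sub.fastq
meatseq rsd-study  --fastq in.fastq --db db/ --ratios 0.001,0.005,0.025,0.125,0.625 --reps 4 --seed 7 --out rsd.csv
meatseq tree       --amplicons amplicons.fa --model p --out tree.nwk --coherence coherence.csv
meatseq simulate   --preset h1 --seed 7 --out reads.fastq --truth truth.csv
meatseq concordance --test ngs_calls.csv --ref qpcr_calls.csv --out conc.csv
```

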