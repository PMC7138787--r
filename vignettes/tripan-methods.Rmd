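---
title: "Methods: tri-genome pan-genome comparison on simulated genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tri-genome pan-genome comparison on simulated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tripan` re-implements the comparative layer of an assembly-based rice
pan-genome analysis: three closely related genomes (a cultivar, here
labelled SAT, and two wild relatives, RUF and NIV) are compared pairwise
by whole-genome alignment, every base is classified as core (shared by
all three), dispensable (shared by exactly two) or genome-specific, and
the same one-to-one alignments drive SNP/indel extraction with
functional-effect annotation, a six-category classifier for large
(>= 10 bp) variants, presence-absence variation (PAV) calling with the
published length and identity filters, and read-depth copy-number (CNV)
calling. Fisher exact-test enrichment with Benjamini-Hochberg correction
covers the gene-set statistics.

Because the real assemblies are far beyond desk scale, the package ships a
three-genome evolution simulator as first-class, tested code. It emits a
machine-readable truth set for every planted event, so each stage of the
pipeline is validated by truth recovery rather than by eyeballing. The
packaged study conditions are: a 1 Mb single-chromosome ancestor with 200
planted protein-coding genes; three descendants drawn independently from
the ancestor (a star phylogeny); substitution rate 0.005 per bp; small
indels at 5e-4 per bp with geometrically distributed lengths capped at
10 bp; 20 segmental presence-absence events of 1-5 kb per genome; tandem
copy-number events (copy 0, 2 or 3) in dedicated branches. The
substitution and event scales are free choices standing in for roughly
megayear-scale divergence among close relatives — they are not estimates
of rice biology; what matters for the tests is that every event is known.

## What the simulator does and does not emulate

The generator produces: point substitutions; small insertions/deletions
(optionally restricted to multiples of three inside coding sequence, the
"purifying" mode that reproduces the period-3 coding indel spectrum);
novel-sequence insertions and segmental deletions at PAV scale; tandem
duplications; copy-scaled Poisson (optionally negative-binomial) depth
tracks; and intact ORFs (ATG start, no internal stop, stop codon end,
both strands, multi-exon) whose annotations can be lifted onto each
descendant. Events are placed by rejection sampling with a 50 bp spacing
margin so each is individually resolvable, and placement fails loudly
after 1,000 rejections rather than allowing silent overlap that would
corrupt the replay oracle (`replay_truth()` must rebuild each descendant
byte for byte).

Real genomes add what the simulator deliberately leaves out: repeat
families and segmental duplications much larger than the planted events,
inversions and translocations, heterozygosity, sequencing and assembly
error, and GC heterogeneity. Passing truth-recovery tests therefore shows
the *rules* are implemented correctly and recover cleanly separable
events; it does not certify performance on repeat-rich real assemblies,
where the external-aligner escape hatch (show-coords ingestion) is the
intended route.

# The built-in aligner

Anchors are exact k-mer matches (default k = 21, odd so no k-mer is its
own reverse complement) whose k-mer occurs exactly once in each genome,
counting a k-mer and its reverse complement together; both strands are
searched. Runs of anchors on one diagonal are collapsed into maximal
segments, then chained per (reference chromosome, query chromosome,
strand) by a gap-bounded weighted dynamic programme (gap bound 10 kb,
per-bp gap penalty 0.01, and a k-sized overlap slack because breakpoint
ambiguity at indel junctions shifts neighbouring anchors by a few bases;
overlaps are trimmed off the incoming anchor during block building).

Interstices between consecutive anchors are closed three ways: pure gaps
(one side empty) become gap records; equal-length interstices are
compared base by base (and realigned globally only when they are at least
30 bp and over 30% mismatched, the signature of twin indels rather than
clustered substitutions); small mixed interstices (minor side <= 50 bp)
are aligned globally with `Biostrings::pairwiseAlignment`. Interstices
whose two sides both exceed 50 bp are deliberately *not* bridged: they
split the chain, leaving the between-block gap geometry to the
structural-variant classifier. Finally every block end is extended by
exact matching. This extension is what creates the tandem-duplication
signature: across a tandem gain the two flanking blocks each extend
through one copy of the unit, so consecutive blocks overlap on one genome
(negative gap), which is precisely the configuration the six-category
classifier reads as tandem expansion/contraction. Unique-k-mer anchoring
alone can never enter the duplicated copies, so without the extension the
tandem categories would be unobservable.

One-to-one filtering is greedy by alignment weight (identity x aligned
columns). A candidate block is kept while, on both genomes, its overlap
with already retained blocks is at most half its span *or* it contributes
at least 100 bp of new coverage. Redundant alignments of one region are
dropped (the higher-identity one wins), while blocks reaching across a
tandem duplication keep their bounded overlap instead of being trimmed —
trimming would destroy exactly the negative-gap evidence the classifier
needs. Strict non-overlapping behaviour remains available
(`max_overlap_frac = 0, min_new_bp = Inf`) and is what the
exhaustive-subset comparison in the tests exercises.

Coverage, everywhere downstream, means *aligned columns*: gap-skipped
bases inside a bridged block are not covered, so a bridged 5 kb insertion
still counts as query-specific sequence.

# The tri-genome partition

The pan-genome is reference-centric with SAT as pivot, following the
order of the pairwise comparisons (SAT-RUF, SAT-NIV, then RUF-NIV): SAT
bases aligned to both others are core, to exactly one dispensable, to
none SAT-specific; RUF bases unaligned to SAT are dispensable when the
RUF-NIV alignment covers them and RUF-specific otherwise; NIV bases
aligned to neither are NIV-specific. Shared RUF/NIV sequence absent from
SAT is counted once, owned by RUF — the source analysis does not state
its deduplication rule, and this choice makes the additivity identity
`pan = core + dispensable + sum(specific)` exact by construction (it is
asserted on every run). Gene membership uses CDS coverage: a gene is
present in another genome when at least 80% (configurable; the published
analysis uses both 80% and 50% in different places) of its CDS bases lie
in sequence aligned to that genome; presence in 3/2/1 genomes gives
core/dispensable/specific.

# Variants

Small variants (<= 10 bp) are read directly off the one-to-one blocks:
one SNP per mismatched aligned column, one indel per gap run, alleles on
the reference strand, indels left-normalized to their leftmost equivalent
position (the usual VCF convention). Truth matching in the tests
canonicalizes planted indels through the same left-shift, because a
homopolymer indel's planted position is not identifiable from the
sequence itself; SNP matching is exact. Effects against gene models are
strand-aware codon comparisons: synonymous / nonsynonymous / stop_gain /
stop_loss for coding SNPs, frameshift / inframe by length modulo three
for coding indels, with partial CDS overlaps flagged (`boundary`) rather
than dropped, and everything else intergenic. The unit oracle is
whole-protein translation of the mutated gene.

Large variants (>= 10 bp) come from two sources. Within a block, any gap
whose sides differ by >= 10 bp is a plain insertion or deletion. Between
consecutive blocks of one chromosome/strand pairing, with `dr` the
reference gap and `dq` the strand-adjusted query gap: both non-negative
and the smaller <= 50 bp gives a plain indel; both above 50 bp a repeat
expansion/contraction (by the sign of `dq - dr`); `dr < 0` a tandem
expansion; `dq < 0` a tandem contraction; both negative is reported as
unclassified and excluded from the six-category total. Negative gaps no
larger than 50 bp are clamped to zero first: chance matching extends
block ends a few bases across a clean junction, and that noise is not
overlap evidence. These decision rules are this package's committed
reconstruction — the published analysis names only the external
classifier and its category names and counts — and all thresholds sit in
`threshold_config()`.

# PAV and CNV

Presence-side PAV: query intervals with no aligned coverage and longer
than 100 bp are re-searched against the reference with the same anchor
aligner (all candidates in one pass); a candidate survives with no hit or
best-block identity <= 0.95. Absence-side PAV: reference stretches with
zero query coverage are merged when closer than 500 bp (strict
inequality) and reported when longer than 100 bp. Uncovered slivers at
small-indel scale (<= 10 bp) are removed before merging: they are
deletion footprints already reported by the small-variant caller, and
chaining them into absence blocks would drag record boundaries away from
the real segment. Gene assignment uses > 50% of CDS for presence-side
specific genes and >= 50% of gene span for absence-side, both
configurable. When planted deletions lie closer than the merge distance,
the caller reports one merged block spanning them — that is the published
rule's intended behaviour, so truth scoring merges the planted spans
under the same rule before comparing breakpoints (tolerance +-50 bp, the
anchor-granularity bound).

CNV calling normalizes window depths by the genome median (a ratio, so
calls are invariant under uniform rescaling of the track) and merges runs
of adjacent windows outside the thresholds in one direction, keeping runs
of >= 500 bp. The published bounds "depth < 1.2 or > 1.8 of the mean"
cannot both apply to a ratio whose neutral value is 1.0 — every normal
window would satisfy the loss bound — so the working defaults are 0.5
(loss) and 1.5 (gain), with the printed pair available via
`use_printed_cnv_thresholds = TRUE`. The depth window defaults to 200 bp:
with Poisson(40) noise, a single outlier window is then never long enough
to pass the 500 bp minimum on its own (three consecutive outliers are
needed), which is the regime in which per-window false positives are
negligible while 1 kb events still span five or more windows. Gene-level
calls need > 80% of exon bases inside CNV regions; "both" requires gain
and loss regions each touching the gene's exons.

# Statistics

One-sided over-representation is the hypergeometric upper tail
(`phyper`), which is the one-sided Fisher exact test; sidedness is not
stated in the source analysis, and over-representation is the universal
convention for GO-style enrichment. Benjamini-Hochberg correction uses
`p.adjust`. The tests compare against an explicit enumeration oracle
(log-binomial sums) over every 2x2 table with N <= 60 at 12 significant
digits, and against a direct step-up implementation on random p-vectors.
The permutation-null check draws 1,000 random gene sets of 100 from a
2,000-gene universe with a 500-gene term: at these margins the discrete
null is close enough to uniform that the empirical false-positive rate at
p < 0.05 sits inside a 4-sigma binomial band of 0.05 (exact value ~0.041;
with much smaller tables the discreteness of the exact test would push it
below any such band, which is a property of the test, not a defect).

Printed percentages of the source analysis (core and two-genome pan
fractions, gene-class fractions, conserved-core-gene recovery, the
positively-selected-gene fraction) are recomputed from their printed
numerators and denominators with half-up rounding at the printed
precision — the way manuscripts round — via `printed_fraction_report()`;
the operand table ships as `inst/extdata/reported_counts.csv`.

# Problem sizes and determinism

The shipped analyses and acceptance checks use: the 3 x 1 Mb trio for the
pan-genome partition (recovery within 2% of truth; a hand-worked 75 kb
interval-arithmetic toy must match exactly); 100 kb structural-variant-
free pairs for SNP/indel precision and recall (>= 0.99); 20 planted
structural variants (10 plain indels of 50-500 bp, 5 tandem gains seen
from the query side, 5 from the reference side) for the six-category
classifier (>= 18/20); a 200 kb branch with 20 segmental events for PAV
(+-50 bp); and a 1 Mb branch with 30 copy-number events (>= 1 kb, copy 0
or 3) at 40x Poisson depth for CNV (recall and precision >= 0.9). These
sizes keep the full suite in the minutes range on one CPU while leaving
every rate at its study value. All randomness flows from a single integer
seed (per-stage seeds are small fixed offsets from it), so identical
seeds give byte-identical outputs end to end.

# Known limitations

* Coverage symmetry and block structure are only as good as unique-k-mer
  anchoring: heavily repetitive sequence yields no anchors and falls out
  as unaligned (hence "specific") sequence; real-data use should import
  external aligner coordinates instead.
* Equal-length diverged interstices are compared positionally; a
  same-length insertion/deletion pair closer than an anchor length apart
  can be mis-read as a run of substitutions (guarded above 30 bp, rare
  below).
* The coords dialect cannot carry per-gap detail, so blocks read from
  external files support coverage-level analyses but not within-block
  small-variant extraction.
* Heterozygosity, read-level simulation and the read-mapping variant
  path of the source analysis are out of scope; the WGA path is the one
  implemented.
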