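---
title: "Methods: consolidating, classifying and validating oil palm genome annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consolidating, classifying and validating oil palm genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package computes

`palmannot` implements the post-processing stages that turn two raw
gene-prediction sets for a plant genome into a single evidence-graded
annotation, and the comparative stages that validate interspecific
structural variants (SVs) with diagnostic PCR schemes. The pipeline was
designed around the two oil palm reference genomes (*Elaeis guineensis*
and *E. oleifera*), but every stage operates on standard formats (FASTA,
GFF3, BED, TSV) and is exercised end-to-end on synthetic data with planted
ground truth.

The stages, in execution order (mirrored by the `analysis/` scripts):

1. **Merge** two prediction sets by coordinate rules.
2. **Remove candidate lncRNAs** by a coding-potential/homology consensus.
3. **Review near-neighbour gene pairs** and drop transcripts whose exon
   boundaries lack RNA-seq junction support.
4. **Integrate evidence** (CAGE, RNA-Seq, homology) per transcript.
5. **Classify genes** into six classes and pick representative isoforms.
6. **Profile methylation** around translation start/end per class, and
   correlate gene/repeat densities in genomic windows.
7. **Filter SV calls** and design junction-diagnostic primers validated by
   electronic PCR.

## The merge model

Internally every annotation is a tidy table of exon/CDS intervals in
0-based half-open coordinates (GFF3 and BED are converted at the I/O
boundary; a single internal convention prevents off-by-one drift).

Set B is the kept-on-identity set. Rule 1: transcripts from the two sets
that agree on the genomic span endpoints *and* on the full CDS coordinate
list collapse to the set-B copy; when several set-B transcripts are
coordinate-identical to one set-A transcript the lexicographically
smallest id is recorded, for determinism. We compare the full CDS
coordinate list exon-by-exon, the stricter of the two possible readings of
"same CDS coordinates". Rule 2: identical span but different exon
boundaries keeps both transcripts as isoforms of one gene. Gene grouping
is then recomputed from geometry alone — transcripts sharing an identical
span on the same strand, or overlapping on the same strand with at least
1 bp of shared CDS, are one gene — because the two pipelines share no
identifiers.

A transcript is removed as a candidate lncRNA iff at least one of the two
coding-potential callers deems it non-coding *and* it has no homology hit
at e-value ≤ 1e-5 ("both or either one" consensus). Proximity review flags
gene pairs on the same strand less than 150 nt apart, and pairs on
opposite strands less than 300 nt apart whose 3'-terminal exons overlap by
at least 1 bp. Distances are measured between nearest span endpoints and
thresholds are exclusive — "within 150 nt" is read as `< 150`, fixed here
for testability. Review only removes unsupported transcripts; it never
fuses two genes into one, since the published procedure describes removal
only.

## Evidence integration and the six classes

* **CAGE**: the association window of a transcript is
  `[CDS start − 3000, CDS start + 10]` in transcription orientation, both
  bounds inclusive (the published window bounds do not state
  inclusivity; we take both inclusive). The cluster summit — a recorded
  single position — is tested against the window, since a tag is a point
  datum. One cluster may support several isoforms of one gene but never
  two genes; a summit falling in windows of two or more genes is assigned
  to the gene with the nearest CDS start (deterministic and logged), and
  an exact distance tie leaves it unassigned.
* **RNA-Seq**: a transcript is supported at ≥ 1 TPM in at least one
  tissue. The 1 TPM default is the conventional presence threshold; the
  source procedure names no numeric cutoff, so it is configurable.
* **Homology**: supported at query coverage ≥ 50% and e-value ≤ 1e-5,
  both inclusive.

With gene-level booleans (C, R, B) OR-ed over isoforms, the classes are
N1 = C∧R∧B, N2 = C plus exactly one of R/B, N3 = R∧B without C,
N4 = exactly one of C/R without B, N5 = B only, N6 = nothing. The
"either"/"only" wordings are read exclusively: that is the only reading
under which the eight combinations form a partition, which the tests
prove by enumeration.

The representative isoform is chosen by a strict lexicographic cascade:
(1) best per-isoform class, (2) smallest homology e-value (absent ranks
worst), (3) most tissues expressed, (4) highest TPM (max across tissues —
the aggregation is unspecified; max is monotone with the breadth
criterion), (5) longest CDS, (6) first predicted model. The gene label
uses OR-over-isoforms while ranking uses per-isoform axes; the source
text is not fully explicit, and this combination is the one that keeps
the label and the ranking mutually consistent.

## Methylation metaprofiles

Profiles anchor at the **translation** start (first base of the start
codon) and end (last base of the stop codon) of each gene's
representative isoform. The describing text mentions transcription-site
anchors in one place and translation-site anchors in the figure that
reports the result; the figure is the operative description, so
translation anchors are the default and the anchor is configurable.
Offsets run in transcription orientation over ±500 nt in 5 nt bins
(200 bins). Each bin averages per-cytosine levels
(`methylated/total` per position) *unweighted* — averaging values, not
pooling counts — and a bin with no cytosines is `NA`, never 0. Only the
representative isoform anchors a gene, avoiding double-counting.

Windowed density tracks count features by start position (each feature
once) in 1 Mb tiles; Spearman correlation with average ranks for ties is
computed over paired windows genome-wide.

## SV filtering and primer schemes

Calls overlapping an assembly gap (N run) in either genome are dropped;
then inversions ≥ 5 Mb and duplications/translocations ≥ 50 kb are kept
(inclusive thresholds). Deletions carry no size threshold — they feed the
small-SV validation track.

Genome A is the reference carrying the sequence the other genome lacks.
For a deletion, D1F sits in the shared 5' flank and D1R inside the A-only
sequence, D2F inside and D2R in the shared 3' flank; both pairs amplify
genome A only. The spanning assay re-uses D1F with D2R: in genome B the
flanks are joined and the product is small, while in genome A the deleted
sequence stretches it past the product ceiling, so it amplifies genome B
only. For a tandem duplication, U1F points out of the 3' end of the
duplicated region and U1R out of its 5' end; they converge only across
the junction between tandem copies (genome B only). For a translocation,
T1 and T2 straddle the two origin-locus junctions (genome A only).

Primer placement: 20 nt primers, flanks searched within 1 kb of the
junction, products capped at 3 kb — all configurable. There is no
melting-temperature model: validation is exact-match electronic PCR, so
thermodynamics would add parameters without changing any verdict.
Uniqueness is enforced as exact-match count 1 in genome A. Primers may
not cover any interspecific SNP; the invariant mask is therefore defined
per genome as the sequence free of known small variants. Genome-specific
segments (deleted or duplicated sequence) stay in their own genome's
mask — the deletion-internal primers D1R/D2F must sit there by design —
and for a SNP-only genome pair the mask coincides exactly with the
per-base identity mask of the alignment, which is what the oracle test
checks.

A spanning assay is geometrically impossible when the deletion is smaller
than `max_product − 2×search_radius` (no placement can push the genome-A
product past the ceiling while keeping the genome-B product amplifiable);
the design then fails with an explicit reason rather than emitting a pair
with an off-scheme pattern. Electronic PCR reports every convergent,
non-overlapping placement of the two primers on either strand with
product length ≤ the ceiling; "amplifies" means at least one product.

## The synthetic-data generator

The generator is first-class, tested code: it emulates every input the
pipeline consumes, with machine-readable truth.

* **Genome**: i.i.d. uniform A/C/G/T with planted N-run gaps. Defaults:
  two 1 Mb chromosomes, two 2 kb gaps each.
* **Gene models**: 150 genes by default, placed with ≥ 4 kb spacing, in
  five coordinate-agreement categories (40% identical, 15% same bounds /
  different exons, 20% each set-specific, 5% overlapping conflict) and six
  class proportions (25/8/12/10/12/33% for N1..N6 — chosen once so that
  roughly 55% of genes carry expression support, the share reported for
  the crop genome this package models). Isoform variants preserve the
  span and shift one internal exon boundary in-frame. Near-neighbour
  pairs are planted at 100/149/151/200 nt same-strand gaps, one
  convergent overlapping-3'-ends pair and one opposite-strand non-overlap
  control per cycle of six.
* **Evidence** is drawn *consistent with the planted class* and, within
  multi-isoform genes, constructed so that a chosen winner is decided at a
  planted criterion depth: ties on all earlier criteria are exact by
  construction (identical e-value exponents, tissue counts, or TPM
  maxima), and the winner is strictly better at the deciding one. CAGE
  clusters sit within the association window of every isoform; decoy
  clusters are placed outside every window. Planted lncRNAs receive
  non-coding verdicts from both simulated callers and no homology hit, so
  the consensus filter's behaviour is fully determined; some
  homology-backed transcripts receive one stray non-coding verdict to
  exercise the keep branch.
* **Methylation** is drawn per cytosine of the actual simulated sequence
  (contexts derived from the neighbouring bases) as beta-distributed
  levels around class templates: expressed classes have CG/CHG ≈ 0.65
  gene bodies with Gaussian troughs to ≈ 0.12 at both translation sites
  (σ = 75 nt); silent classes sit flat at ≈ 0.85; CHH is 0.08 everywhere.
  Real evidence distributions (cluster widths, TPM ranges) are not
  published, so these values are chosen for discriminative power, not
  realism — passing tests show the pipeline recovers planted structure,
  not that real data look like this.
* **Genome pair**: deletions 0.5–20 kb, tandem duplications and
  intra-chromosomal translocations 50–80 kb, inversions 5–5.5 Mb, plus
  background SNPs at 0.5%/bp in collinear sequence (event-derived
  segments are SNP-free, a simplification that keeps primer truth exact).
  Spurious calls are fabricated under assembly gaps and below the size
  thresholds. On a 10 Mb single-chromosome pair a ≥ 5 Mb inversion almost
  inevitably spans a gap; it is then recorded (and must be filtered) as
  non-qualifying — the inclusive-threshold behaviour is covered by
  constructed unit tests instead.

Every generator draws from its own substream of the master seed (labelled
hashes), so adding one generator never perturbs another, and all outputs
are byte-identical across repeated calls.

## Problem sizes and numerical choices

The test suite runs the full pipeline at 60–230 genes per case, the
classification recovery check at 500 genes, the methylation contrast at
200 genes per class (1,200 genes, ≈ 1.4 million cytosine calls), and the
SV/primer soundness check on a 10 Mb genome pair with 20 planted events —
sizes at which every brute-force oracle (all-pairs merge comparison,
per-base mask comparison, window re-binning, row-scan support flags)
remains exact and fast. Percentages are reported rounded half-up to one
decimal, matching printed-table arithmetic; mean scaffold length is the
floored exact ratio. Ranking and merging are deterministic given inputs;
the only tie-breaks are the documented lexicographic ones.

## Known limitations

* Junction support is an input flag; the package never inspects read
  alignments.
* The generator's translocations are intra-chromosomal and non-inverted;
  the primer schemes do not depend on either restriction, but
  inter-chromosomal coordinate truth is not exercised.
* Inversions are filtered but no primer scheme is designed for them, as
  in the validation protocol this package models.
* Electronic PCR is exact-match only: primer thermodynamics, mismatches
  and degenerate bases are out of scope.
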