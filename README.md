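# palmannot

Post-processing toolkit for plant genome annotation, built around the two
oil palm reference genomes (*Elaeis guineensis* and *E. oleifera*). Genome
projects of this kind end up with two independent gene-prediction sets,
heterogeneous expression evidence, and a list of putative interspecific
structural variants; `palmannot` implements the stages that turn those raw
products into a single evidence-graded annotation and a validated variant
panel, for annotation engineers and comparative genomicists who need each
rule to be explicit and testable.

## What it computes

**Annotation consolidation.** Two prediction sets are merged by coordinate
rules: a transcript present in both sets with identical span endpoints and
an identical CDS coordinate list is kept once (from the designated set);
identical bounds with different exon boundaries are kept as isoforms of one
gene; gene grouping is recomputed from geometry. Candidate lncRNAs —
transcripts called non-coding by either of two coding-potential callers
*and* lacking a homology hit at e-value ≤ 1e-5 — are removed. Gene pairs on
the same strand < 150 nt apart, or on opposite strands < 300 nt apart with
overlapping 3′-terminal exons, are flagged, and flagged transcripts
without RNA-seq junction support are dropped.

**Evidence classification.** With per-gene support booleans C (a CAGE tag
cluster summit within [CDS start − 3000, CDS start + 10] in transcription
orientation; one tag never supports two genes), R (≥ 1 TPM in ≥ 1 tissue)
and B (a homology hit with ≥ 50% query coverage at e-value ≤ 1e-5), genes
are classified

    N1 = C∧R∧B   N2 = C + exactly one of {R,B}   N3 = R∧B (no C)
    N4 = one of {C,R} alone   N5 = B only   N6 = unsupported

and each gene's representative isoform is selected by the lexicographic
cascade: class → best e-value → tissue breadth → highest TPM → longest CDS
→ first predicted model.

**Methylation metaprofiles.** Per-cytosine CG/CHG/CHH levels are averaged
in 5 nt bins within ±500 nt of the representative isoform's translation
start and end, per gene class. Windowed (1 Mb) gene and repeat densities
are compared with Spearman correlation.

**SV validation.** Variant calls overlapping assembly gaps are dropped;
inversions ≥ 5 Mb and duplications/translocations ≥ 50 kb are kept
(deletions have no size threshold). Diagnostic PCR schemes are designed in
SNP-free sequence — D1/D2 flank+internal pairs and T1/T2 junction pairs
that amplify the reference genome only, and the U1 tandem-junction and
D1F+D2R spanning pairs that amplify the derived genome only — and every
design is validated by exact-match electronic PCR on both genomes.

A synthetic-data module generates all inputs (FASTA, GFF3, BED, TSV) with
machine-readable planted truth, so the full pipeline is testable without
any external download.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over the package functions and writes its tables under
`results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_consolidate.R
Rscript analysis/03_classify.R
Rscript analysis/04_methylation_density.R
Rscript analysis/05_sv_primers.R
```

prints, with the default configuration (seed 1):

```
simulated 2 chromosomes (2000000 bp, 0.4% gaps), 186 + 176 transcripts, 80 CAGE clusters, 186797 methylation calls
merged 186 + 176 transcripts: 92 collapsed on identical coordinates, 20 same-bounds isoforms retained, 8 candidate lncRNAs removed, 3 gene pairs flagged for proximity, 3 unsupported transcripts removed -> 259 final transcripts
classified 159 genes: N1=44 N2=7 N3=23 N4=17 N5=20 N6=48; 57.2% have expression support (N1-N4)
mean CG level at the translation start: expressed classes (N1-N4) 0.142, silent classes (N5-N6) 0.859
filtered 26 calls -> kept 19 (4 gap-overlapping, 3 below size)
designed 42 primer pairs over 19 SVs; 0 design failures; e-PCR pattern correct for 42/42 pairs
```

Reading the numbers: the 92 collapsed transcripts are the
coordinate-identical pairs the merge keeps once; 57.2% of classified genes
carry CAGE and/or RNA-Seq support (classes N1–N4); the expressed classes
show the characteristic CG trough at the translation start (0.142) against
densely methylated silent genes (0.859); and every surviving structural
variant gets a primer panel whose genome-specific amplification pattern is
confirmed in silico.

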