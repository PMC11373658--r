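#!/usr/bin/env Rscript
# Step 1 — simulate the full study inputs with planted ground truth.
#
# Emits, under results/sim/: the reference genome (FASTA) with its gap BED,
# two gene-prediction sets (GFF3), CAGE tag clusters (BED6+1), the
# transcripts-by-tissues TPM matrix, homology hits, coding-potential calls,
# junction support, per-cytosine methylation calls (TSV), and the truth
# tables (JSON) that later steps are scored against.

suppressMessages({library(palmannot); library(dplyr)})

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
g <- generate_genome(cfg)
gm <- generate_gene_models(cfg, g)
ev <- generate_evidence(cfg, gm, g)

write_fasta(g$genome, file.path(out, "genome_a.fa"))
write_bed3(g$gaps, file.path(out, "gaps_a.bed"))
write_gff3(gm$setA, file.path(out, "predictions_setA.gff3"))
write_gff3(gm$setB, file.path(out, "predictions_setB.gff3"))
write_cage_bed(ev$cage, file.path(out, "cage_clusters.bed"))
wtsv <- function(x, f) utils::write.table(
  x, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)
wtsv(ev$expression, "expression_tpm.tsv")
wtsv(ev$homology, "homology_hits.tsv")
wtsv(ev$coding_calls, "coding_potential.tsv")
wtsv(ev$junction_support, "junction_support.tsv")
wtsv(ev$methylation, "methylation_calls.tsv")
jsonlite::write_json(gm$truth, file.path(out, "truth.json"),
                     dataframe = "columns", auto_unbox = TRUE)

st <- assembly_stats(g$genome)
wtsv(st, "assembly_stats.tsv")
message(sprintf(
  "simulated %d chromosomes (%d bp, %.1f%% gaps), %d + %d transcripts, %d CAGE clusters, %d methylation calls",
  st$n_scaffolds, st$total_bases, st$gap_percent,
  length(unique(gm$setA$transcript_id)),
  length(unique(gm$setB$transcript_id)),
  nrow(ev$cage), nrow(ev$methylation)))
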