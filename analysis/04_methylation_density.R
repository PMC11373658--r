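#!/usr/bin/env Rscript
# Step 4 — methylation metaprofiles per gene class, and gene/repeat density
# correlation in 1 Mb windows.
#
# Metaprofiles average per-cytosine methylation levels in 5 nt bins within
# +/- 500 nt of the representative isoform's translation start and end, per
# context (CG/CHG/CHH) and class. The density analysis bins features into
# 1 Mb windows and reports Spearman correlations.

suppressMessages({library(palmannot); library(dplyr)})

sim <- "results/sim"
merged <- read_gff3("results/merged.gff3")
cl <- utils::read.delim("results/classified_genes.tsv")
meth <- utils::read.delim(file.path(sim, "methylation_calls.tsv"))
genome <- read_fasta(file.path(sim, "genome_a.fa"))

classes <- tibble::tibble(gene_id = cl$gene_id, gene_class = cl$gene_class,
                          representative = cl$representative)
mp <- methylation_metaprofile(meth, merged, classes)
utils::write.table(mp, "results/methylation_metaprofile.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cg <- mp[mp$context == "CG" & mp$anchor == "translation_start", ]
lvl <- function(cls) round(stats::weighted.mean(
  cg$mean_level[cg$class %in% cls & cg$bin %in% 99:100],
  cg$n_cytosines[cg$class %in% cls & cg$bin %in% 99:100], na.rm = TRUE), 3)
message("mean CG level at the translation start: expressed classes ",
        "(N1-N4) ", lvl(paste0("N", 1:4)), ", silent classes (N5-N6) ",
        lvl(c("N5", "N6")))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- ggplot2::ggplot(mp[!is.na(mp$mean_level), ],
                       ggplot2::aes(offset_start, mean_level,
                                    colour = context)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(class ~ anchor) +
    ggplot2::labs(x = "offset from anchor (nt)",
                  y = "mean methylation level") +
    ggplot2::theme_minimal()
  ggplot2::ggsave("results/methylation_metaprofile.pdf", p,
                  width = 8, height = 9)
}

# density correlation on gene starts vs a repeat-like track; with the
# simulated genome there is no repeat annotation, so demonstrate on gene
# density versus CAGE cluster density (100 kb windows for this genome size)
s <- tx_summary(merged)
genes <- s %>% group_by(gene_id) %>%
  summarise(chrom = dplyr::first(chrom), start = min(tx_start),
            .groups = "drop")
cage <- read_cage_bed(file.path(sim, "cage_clusters.bed"))
wd_g <- window_density(genes, genome, window_bp = 100000L)
wd_c <- window_density(cage[, c("chrom", "start")], genome,
                       window_bp = 100000L)
dc <- density_correlation(wd_g, wd_c)
utils::write.table(dplyr::bind_rows(
  tibble::tibble(track_a = "genes", track_b = "cage_clusters",
                 rho = dc$rho, n_windows = dc$n_windows)),
  "results/density_correlation.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
message(sprintf("gene vs CAGE-cluster density: Spearman rho = %.2f over %d windows",
                dc$rho, dc$n_windows))
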