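sv_row <- function(type, s, e, chrom = "c1", id = "sv1") {
  tibble::tibble(sv_id = id, type = type, chromA = chrom, startA = s,
                 endA = e, chromB = chrom, startB = s, endB = e,
                 size = e - s)
}
no_gaps <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())

test_that("SV size thresholds are inclusive and gap overlap drops calls", {
  svs <- dplyr::bind_rows(
    sv_row("inversion", 0L, 5000000L, id = "inv_at"),
    sv_row("inversion", 0L, 4999999L, id = "inv_under"),
    sv_row("duplication", 10L, 50010L, id = "dup_at"),
    sv_row("duplication", 10L, 50009L, id = "dup_under"),
    sv_row("translocation", 10L, 50010L, id = "tra_at"),
    sv_row("deletion", 100L, 600L, id = "del_small"))
  f <- filter_svs(svs, no_gaps, no_gaps)
  expect_setequal(f$kept$sv_id, c("inv_at", "dup_at", "tra_at", "del_small"))
  expect_setequal(f$dropped$drop_reason, "below_size_threshold")
  gaps <- tibble::tibble(chrom = "c1", start = 40000L, end = 42000L)
  f2 <- filter_svs(svs, gaps, no_gaps)
  expect_true(all(c("dup_at", "tra_at") %in%
                    f2$dropped$sv_id[f2$dropped$drop_reason ==
                                       "gap_overlap"]))
  expect_true("del_small" %in% f2$kept$sv_id)
})

test_that("filter matches a brute-force scan on a planted genome pair", {
  cfg <- sim_config(seed = 101, n_chroms = 1, chrom_length = 4000000L,
                    n_genes = 0, n_proximity_pairs = 0, lnc_fraction = 0,
                    sv_counts = c(deletion = 6, duplication = 3,
                                  translocation = 3, inversion = 0))
  g <- generate_genome(cfg)
  sv <- generate_sv_pair(cfg, g)
  gaps_b <- genome_gaps(sv$genome_b)
  f <- filter_svs(sv$svs, g$gaps, gaps_b)
  # independent brute force over every call
  keep <- logical(nrow(sv$svs))
  thr <- c(deletion = 0, duplication = 5e4, translocation = 5e4,
           inversion = 5e6)
  for (i in seq_len(nrow(sv$svs))) {
    r <- sv$svs[i, ]
    ga <- g$gaps[g$gaps$chrom == r$chromA, ]
    gb <- gaps_b[gaps_b$chrom == r$chromB, ]
    hit <- any(r$startA < ga$end & ga$start < r$endA) ||
      any(r$startB < gb$end & gb$start < r$endB)
    keep[i] <- !hit && r$size >= thr[[r$type]]
  }
  expect_setequal(f$kept$sv_id, sv$svs$sv_id[keep])
  # and the survivors are exactly the planted qualifying events
  expect_setequal(f$kept$sv_id, sv$truth$sv_id[sv$truth$qualifies])
})

test_that("invariant mask equals per-base comparison on a SNP-only pair", {
  cfg <- sim_config(seed = 102, n_chroms = 1, chrom_length = 50000L,
                    n_genes = 0, n_gaps_per_chrom = 0,
                    n_proximity_pairs = 0, lnc_fraction = 0,
                    divergence_snp_rate = 0.01,
                    sv_counts = c(deletion = 0, duplication = 0,
                                  translocation = 0, inversion = 0),
                    n_sv_decoys_gap = 0, n_sv_decoys_small = 0)
  g <- generate_genome(cfg)
  sv <- generate_sv_pair(cfg, g)
  m <- invariant_mask(g$genome, sv$genome_b, sv$snps)
  a <- strsplit(as.character(g$genome[[1]]), "")[[1]]
  b <- strsplit(as.character(sv$genome_b[[1]]), "")[[1]]
  same <- a == b
  in_mask <- rep(FALSE, length(a))
  for (i in seq_len(nrow(m$maskA))) {
    in_mask[(m$maskA$start[i] + 1):m$maskA$end[i]] <- TRUE
  }
  expect_identical(in_mask, same)
  expect_identical(m$maskA, m$maskB)
  # no SNPs: whole chromosome invariant; one SNP: that base excluded
  m0 <- invariant_mask(g$genome, g$genome,
                       sv$snps[0, ])
  expect_equal(nrow(m0$maskA), 1L)
  expect_equal(m0$maskA$end, 50000L)
  m1 <- invariant_mask(g$genome, g$genome, sv$snps[7, ])
  p <- sv$snps$posA[7]
  expect_equal(m1$maskA$end[1], p)
  expect_equal(m1$maskA$start[2], p + 1L)
})

test_that("electronic PCR reports convergent products only", {
  set.seed(103)
  left <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 460, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  genome <- as_genome(c(z = paste0(pad(1000), left, mid, right, pad(1000))))
  pair <- list(forward = list(seq = left),
               reverse = list(seq = as.character(
                 Biostrings::reverseComplement(Biostrings::DNAString(right)))))
  pr <- epcr(pair, genome)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$length, 500L)
  expect_equal(pr$start, 1000L)
  # absent primers give no product
  none <- list(forward = list(seq = strrep("ACGT", 6)),
               reverse = list(seq = strrep("TTAC", 6)))
  expect_equal(nrow(epcr(none, genome)), 0L)
  # divergent orientation (swap primer roles' strands) gives no product
  div <- list(forward = list(seq = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(left)))),
    reverse = list(seq = right))
  expect_equal(nrow(epcr(div, genome)), 0L)
  # product longer than max_product is suppressed
  expect_equal(nrow(epcr(pair, genome, max_product = 400L)), 0L)
  expect_error(epcr(list(forward = list(seq = "ACGTACGTAC"),
                         reverse = list(seq = right)), genome), "15 nt")
})

test_that("e-PCR verdicts are symmetric under reverse-complementing the genome", {
  set.seed(104)
  genome <- as_genome(c(z = paste(sample(c("A", "C", "G", "T"), 8000, TRUE),
                                  collapse = "")))
  fwd <- as.character(Biostrings::subseq(genome[[1]], 2001, 2020))
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[[1]], 2481, 2500)))
  pair <- list(forward = list(seq = fwd), reverse = list(seq = rev))
  rc <- as_genome(Biostrings::reverseComplement(genome))
  p1 <- epcr(pair, genome); p2 <- epcr(pair, rc)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(sort(p1$length), sort(p2$length))
})

test_that("deletions too small for internal primers or spanning assays fail", {
  cfg <- sim_config(seed = 105, n_chroms = 1, chrom_length = 200000L,
                    n_genes = 0, n_gaps_per_chrom = 0,
                    n_proximity_pairs = 0, lnc_fraction = 0,
                    divergence_snp_rate = 0,
                    sv_counts = c(deletion = 0, duplication = 0,
                                  translocation = 0, inversion = 0),
                    n_sv_decoys_gap = 0, n_sv_decoys_small = 0)
  g <- generate_genome(cfg)
  d15 <- design_deletion_primers(sv_row("deletion", 50000L, 50015L,
                                        chrom = "chr1"),
                                 g$genome, g$genome, tibble::tibble(
                                   chrom = character(), posA = integer()))
  expect_equal(d15$status, "failed")
  expect_match(d15$reason, "internal primer")
  d600 <- design_deletion_primers(sv_row("deletion", 50000L, 50600L,
                                         chrom = "chr1"),
                                  g$genome, g$genome, tibble::tibble(
                                    chrom = character(), posA = integer()))
  expect_equal(d600$status, "failed")
  expect_match(d600$reason, "spanning")
})

test_that("dense SNPs in the flanks abort the design with a reason", {
  cfg <- sim_config(seed = 106, n_chroms = 1, chrom_length = 100000L,
                    n_genes = 0, n_gaps_per_chrom = 0,
                    n_proximity_pairs = 0, lnc_fraction = 0,
                    divergence_snp_rate = 0,
                    sv_counts = c(deletion = 0, duplication = 0,
                                  translocation = 0, inversion = 0),
                    n_sv_decoys_gap = 0, n_sv_decoys_small = 0)
  g <- generate_genome(cfg)
  snps <- tibble::tibble(chrom = "chr1",
                         posA = as.integer(seq(43000, 45010, by = 8)))
  d <- design_deletion_primers(sv_row("deletion", 45000L, 50000L,
                                      chrom = "chr1"),
                               g$genome, g$genome, snps)
  expect_equal(d$status, "failed")
  expect_match(d$reason, "flank")
})

test_that("designed primers avoid every SNP and give scheme-true patterns", {
  cfg <- sim_config(seed = 107, n_chroms = 1, chrom_length = 4000000L,
                    n_genes = 0, n_proximity_pairs = 0, lnc_fraction = 0,
                    sv_counts = c(deletion = 6, duplication = 3,
                                  translocation = 3, inversion = 0))
  g <- generate_genome(cfg)
  sv <- generate_sv_pair(cfg, g)
  f <- filter_svs(sv$svs, g$gaps, genome_gaps(sv$genome_b))
  panel <- sv_primer_panel(f$kept, g$genome, sv$genome_b, sv$snps)
  ok <- panel[panel$status == "ok", ]
  expect_gt(nrow(ok), 12)
  expect_true(all(ok$pattern_ok))
  # scheme table: D/T pairs are A-only, U1 and spanning are B-only
  expect_true(all(ok$expected_a[ok$pair %in% c("D1", "D2", "T1", "T2")]))
  expect_true(all(!ok$expected_b[ok$pair %in% c("D1", "D2", "T1", "T2")]))
  expect_true(all(!ok$expected_a[ok$pair %in% c("U1", "spanning")]))
  expect_true(all(ok$expected_b[ok$pair %in% c("U1", "spanning")]))
  # every designed primer is SNP-free (inside the invariant mask)
  dels <- f$kept[f$kept$type == "deletion", ][1, ]
  des <- design_deletion_primers(dels, g$genome, sv$genome_b, sv$snps)
  has_snp <- function(chrom, s, e) {
    any(sv$snps$chrom == chrom & sv$snps$posA >= s & sv$snps$posA < e)
  }
  for (p in list(des$D1, des$D2, des$spanning)) {
    expect_false(has_snp(p$chrom, p$forward$start,
                         p$forward$start + p$primer_len))
    expect_false(has_snp(p$chrom, p$reverse$start,
                         p$reverse$start + p$primer_len))
  }
})

test_that("a non-duplicated region yields no junction product", {
  cfg <- sim_config(seed = 108, n_chroms = 1, chrom_length = 300000L,
                    n_genes = 0, n_gaps_per_chrom = 0,
                    n_proximity_pairs = 0, lnc_fraction = 0,
                    divergence_snp_rate = 0,
                    sv_counts = c(deletion = 0, duplication = 0,
                                  translocation = 0, inversion = 0),
                    n_sv_decoys_gap = 0, n_sv_decoys_small = 0)
  g <- generate_genome(cfg)
  # same sequence in both genomes: outward pair never converges
  d <- design_duplication_primers(sv_row("duplication", 100000L, 160000L,
                                         chrom = "chr1"),
                                  g$genome, g$genome,
                                  tibble::tibble(chrom = character(),
                                                 posA = integer()))
  expect_equal(d$status, "failed")
  expect_match(d$reason, "tandem")
})
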