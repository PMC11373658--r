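one_gene <- function(strand = "+") {
  mk_tx("t1", "g1", "chr1", strand, list(c(2000, 3200)),
        list(c(2200, 3000)))
}
one_class <- function() tibble::tibble(gene_id = "g1", gene_class = "N1",
                                       representative = "t1")

test_that("a single call lands in the expected 5 nt bin with its level", {
  f <- one_gene()
  # + strand: translation start at 2200; call at +2 -> bin [0,5) = bin 100
  calls <- tibble::tibble(chrom = "chr1", pos = 2202L, strand = "+",
                          context = "CG", n_meth = 10L, n_total = 10L)
  mp <- methylation_metaprofile(calls, f, one_class(),
                                anchors = "translation_start")
  hit <- mp[mp$context == "CG" & mp$n_cytosines > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$bin, 100L)
  expect_equal(hit$offset_start, 0L)
  expect_equal(hit$mean_level, 1)
  # all other bins are missing, not zero
  expect_true(all(is.na(mp$mean_level[mp$n_cytosines == 0])))
  expect_equal(nrow(mp), 3 * 200)
})

test_that("offsets flip with strand and anchor at the translation end", {
  f <- one_gene("-")
  # - strand: translation start at genomic 2999; a call 7 nt downstream of
  # the anchor in transcription orientation sits at genomic 2992
  calls <- tibble::tibble(chrom = "chr1", pos = 2992L, strand = "-",
                          context = "CHG", n_meth = 3L, n_total = 4L)
  mp <- methylation_metaprofile(calls, f, one_class(),
                                anchors = "translation_start")
  hit <- mp[mp$n_cytosines > 0, ]
  expect_equal(hit$context, "CHG")
  expect_equal(hit$bin, 101L)      # offset +7 -> [5,10)
  expect_equal(hit$mean_level, 0.75)
  # translation end anchor for the - gene is genomic 2200
  mp2 <- methylation_metaprofile(
    tibble::tibble(chrom = "chr1", pos = 2200L, strand = "+",
                   context = "CG", n_meth = 1L, n_total = 2L),
    f, one_class(), anchors = "translation_end")
  hit2 <- mp2[mp2$n_cytosines > 0, ]
  expect_equal(hit2$bin, 100L)
})

test_that("cytosines in range are conserved between calls and profile", {
  cfg <- sim_config(seed = 91, n_genes = 40, n_proximity_pairs = 0,
                    lnc_fraction = 0)
  g <- generate_genome(cfg)
  gm <- generate_gene_models(cfg, g)
  ev <- generate_evidence(cfg, gm, g)
  feats <- dplyr::bind_rows(gm$setA, gm$setB)
  tg <- gm$truth$genes[!is.na(gm$truth$genes$class), ]
  classes <- tibble::tibble(gene_id = tg$gene_id, gene_class = tg$class,
                            representative = tg$representative)
  mp <- methylation_metaprofile(ev$methylation, feats, classes,
                                anchors = "translation_start")
  s <- tx_summary(feats)
  reps <- s[match(classes$representative, s$transcript_id), ]
  expected <- 0L
  for (i in seq_len(nrow(reps))) {
    a <- reps$cds_start_pos[i]
    expected <- expected + sum(
      ev$methylation$chrom == reps$chrom[i] &
        (if (reps$strand[i] == "-")
          a - ev$methylation$pos else ev$methylation$pos - a) >= -500 &
        (if (reps$strand[i] == "-")
          a - ev$methylation$pos else ev$methylation$pos - a) < 500)
  }
  expect_equal(sum(mp$n_cytosines), expected)
})

test_that("metaprofiles are invariant under reverse-complementing the world", {
  cfg <- sim_config(seed = 92, n_genes = 25, n_proximity_pairs = 0,
                    lnc_fraction = 0)
  g <- generate_genome(cfg)
  gm <- generate_gene_models(cfg, g)
  ev <- generate_evidence(cfg, gm, g)
  feats <- dplyr::bind_rows(gm$setA, gm$setB)
  tg <- gm$truth$genes[!is.na(gm$truth$genes$class), ]
  classes <- tibble::tibble(gene_id = tg$gene_id, gene_class = tg$class,
                            representative = tg$representative)
  mp1 <- methylation_metaprofile(ev$methylation, feats, classes)
  rc <- revcomp_world(g$genome, feats)
  L <- stats::setNames(Biostrings::width(g$genome), names(g$genome))
  calls2 <- ev$methylation
  calls2$pos <- unname(L[calls2$chrom]) - 1L - calls2$pos
  calls2$strand <- c("+" = "-", "-" = "+")[calls2$strand]
  mp2 <- methylation_metaprofile(calls2, rc$features, classes)
  expect_equal(mp1, mp2)
})

test_that("window density counts features once by start position", {
  lens <- c(chrA = 2500000)
  none <- window_density(tibble::tibble(chrom = character(),
                                        start = integer()), lens)
  expect_equal(none$count, c(0, 0, 0))
  expect_equal(none$win_end[3], 2500000)
  ten <- window_density(tibble::tibble(chrom = rep("chrA", 10),
                                       start = as.integer(1e6 + 1:10)),
                        lens)
  expect_equal(ten$count, c(0, 10, 0))
  expect_error(window_density(tibble::tibble(chrom = "chrA",
                                             start = 3000000L), lens),
               "beyond")
  set.seed(93)
  pos <- sample(0:2499999, 500)
  wd <- window_density(tibble::tibble(chrom = "chrA", start = pos), lens)
  for (w in seq_len(nrow(wd))) {
    expect_equal(wd$count[w],
                 sum(pos >= wd$win_start[w] & pos < wd$win_start[w] + 1e6))
  }
  expect_equal(sum(wd$count), 500)
})

test_that("density correlation handles identity, reversal and symmetry", {
  lens <- c(c1 = 10000000)
  set.seed(94)
  a <- window_density(tibble::tibble(chrom = "c1",
                                     start = sample(0:9999999, 400)), lens)
  expect_equal(density_correlation(a, a)$rho, 1)
  rev_a <- a; rev_a$count <- rev(a$count)
  b <- window_density(tibble::tibble(chrom = "c1",
                                     start = sample(0:9999999, 700)), lens)
  expect_equal(density_correlation(a, b)$rho, density_correlation(b, a)$rho)
  expect_equal(density_correlation(a, rev_a)$n_windows, 10)
  # strictly monotone decreasing counts against increasing -> rho -1
  up <- a; up$count <- 1:10
  down <- a; down$count <- 10:1
  expect_equal(density_correlation(up, down)$rho, -1)
  expect_error(density_correlation(a[1:2, ], b[1:2, ]), "3 windows")
  expect_error(density_correlation(a[1:5, ], b), "windowing")
})

test_that("a pericentromeric repeat layout yields the planted correlation signs", {
  # genes dense on the arms, Copia-like repeats dense in the centre,
  # LINE-like repeats tracking the genes
  set.seed(95)
  L <- 20000000
  lens <- c(chr1 = L)
  centro <- c(8e6, 12e6)
  arm_pos <- function(n) {
    p <- sample(0:(L - 1), n * 3, replace = TRUE)
    p[p < centro[1] | p >= centro[2]][1:n]
  }
  centro_pos <- function(n) sample(centro[1]:(centro[2] - 1), n,
                                   replace = TRUE)
  genes <- tibble::tibble(chrom = "chr1", start = arm_pos(800))
  copia <- tibble::tibble(chrom = "chr1",
                          start = c(centro_pos(900), sample(0:(L - 1), 100,
                                                            TRUE)))
  line <- tibble::tibble(chrom = "chr1",
                         start = c(arm_pos(700), sample(0:(L - 1), 100,
                                                        TRUE)))
  dg <- window_density(genes, lens)
  dc <- window_density(copia, lens)
  dl <- window_density(line, lens)
  expect_lt(density_correlation(dg, dc)$rho, 0)
  expect_gt(density_correlation(dg, dl)$rho, 0)
})
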