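test_that("identical start/stop/CDS collapses to the set-B transcript", {
  a <- mk_tx("a1", "gA", "chr1", "+", list(c(100, 400)), list(c(150, 350)),
             source = "setA")
  b <- mk_tx("b1", "gB", "chr1", "+", list(c(100, 400)), list(c(150, 350)),
             source = "setB")
  m <- merge_predictions(a, b)
  expect_equal(unique(m$merged$transcript_id), "b1")
  expect_equal(unique(m$merged$source), "setB")
  expect_equal(m$report$n_collapsed_identical, 1L)
})

test_that("identical bounds with different exon boundaries keeps both in one gene", {
  a <- mk_tx("a1", "gA", "chr1", "+",
             list(c(100, 200), c(300, 500)), list(c(150, 200), c(300, 450)),
             source = "setA")
  b <- mk_tx("b1", "gB", "chr1", "+",
             list(c(100, 203), c(303, 500)), list(c(150, 203), c(303, 450)),
             source = "setB")
  m <- merge_predictions(a, b)
  expect_setequal(unique(m$merged$transcript_id), c("a1", "b1"))
  expect_equal(length(unique(m$merged$gene_id)), 1L)
  expect_equal(m$report$n_isoforms_added, 1L)
  expect_equal(m$report$n_collapsed_identical, 0L)
})

test_that("a tie on several identical set-B transcripts keeps the smallest id", {
  a <- mk_tx("a1", "gA", "chr1", "+", list(c(100, 400)), list(c(150, 350)))
  b <- dplyr::bind_rows(
    mk_tx("b9", "g1", "chr1", "+", list(c(100, 400)), list(c(150, 350)),
          source = "setB"),
    mk_tx("b2", "g2", "chr1", "+", list(c(100, 400)), list(c(150, 350)),
          source = "setB"))
  m <- merge_predictions(a, b)
  prov <- m$report$provenance
  expect_equal(prov$collapsed_into[prov$transcript_id == "a1"], "b2")
})

test_that("merge is idempotent and rejects duplicate ids", {
  cfg <- sim_config(seed = 31, n_genes = 30)
  gm <- generate_gene_models(cfg, generate_genome(cfg))
  m <- merge_predictions(gm$setA, gm$setB)
  empty <- gm$setA[0, ]
  m2 <- merge_predictions(m$merged, empty)
  expect_setequal(unique(m2$merged$transcript_id),
                  unique(m$merged$transcript_id))
  expect_equal(m2$report$n_collapsed_identical, 0L)
  expect_error(merge_predictions(gm$setB, gm$setB), "shared across sets")
})

test_that("merge equals the brute-force all-pairs oracle on planted categories", {
  for (seed in c(101, 102)) {
    cfg <- sim_config(seed = seed, n_genes = 80, n_proximity_pairs = 0,
                      lnc_fraction = 0)
    gm <- generate_gene_models(cfg, generate_genome(cfg))
    m <- merge_predictions(gm$setA, gm$setB)
    oracle <- brute_merge(gm$setA, gm$setB)
    expect_setequal(unique(m$merged$transcript_id), oracle$surviving)
    expect_equal(m$report$n_collapsed_identical, oracle$n_collapsed)
    expect_identical(partition_of(m$merged), oracle$partition)
    # count identity of the report
    expect_equal(length(unique(m$merged$transcript_id)),
                 m$report$n_input_A + m$report$n_input_B -
                   m$report$n_collapsed_identical)
  }
})

test_that("transcript fates match the planted agreement categories", {
  cfg <- sim_config(seed = 33, n_genes = 100, n_proximity_pairs = 0,
                    lnc_fraction = 0)
  gm <- generate_gene_models(cfg, generate_genome(cfg))
  m <- merge_predictions(gm$setA, gm$setB)
  prov <- m$report$provenance
  tr <- gm$truth$transcripts
  j <- match(prov$transcript_id, tr$transcript_id)
  expect_true(all((tr$fate[j] == "collapsed") ==
                    (prov$action == "collapsed")))
  # the survivors of identical genes are exactly the set-B copies
  idb <- tr$transcript_id[tr$agreement == "identical" & tr$fate == "kept"]
  expect_true(all(idb %in% m$merged$transcript_id))
})

test_that("lncRNA consensus removal follows the both-or-either rule", {
  f <- dplyr::bind_rows(
    mk_tx("t1", "g1", "chr1", "+", list(c(0, 500)), list(c(100, 400))),
    mk_tx("t2", "g2", "chr1", "+", list(c(1000, 1500)), list(c(1100, 1400))),
    mk_tx("t3", "g3", "chr1", "+", list(c(2000, 2500)), list(c(2100, 2400))),
    mk_tx("t4", "g4", "chr1", "+", list(c(3000, 3500)), list(c(3100, 3400))))
  calls <- tibble::tibble(
    transcript_id = c("t1", "t1", "t2", "t3", "t4"),
    caller = c("caller_a", "caller_b", "caller_a", "caller_b", "caller_a"),
    verdict = c("noncoding", "noncoding", "noncoding", "noncoding", "coding"))
  hits <- tibble::tibble(query = c("t2", "t3"), evalue = c(1e-6, 1e-4))
  out <- filter_lncrna(f, calls, hits)
  # t1: non-coding by both, no hit -> removed
  # t2: non-coding by one, hit at 1e-6 -> kept
  # t3: non-coding by one, hit only at 1e-4 (> cutoff) -> removed
  # t4: coding -> kept
  expect_setequal(out$removed_ids, c("t1", "t3"))
})

test_that("planted lncRNAs are recovered exactly", {
  cfg <- sim_config(seed = 35, n_genes = 80, lnc_fraction = 0.1)
  g <- generate_genome(cfg)
  gm <- generate_gene_models(cfg, g)
  ev <- generate_evidence(cfg, gm, g)
  m <- merge_predictions(gm$setA, gm$setB)
  out <- suppressWarnings(
    filter_lncrna(m$merged, ev$coding_calls, ev$homology))
  planted <- gm$truth$transcripts$transcript_id[
    gm$truth$transcripts$is_lncrna]
  expect_setequal(out$removed_ids, planted)
})

test_that("proximity thresholds are exclusive and strand rules apply", {
  g1 <- mk_tx("t1", "g1", "chr1", "+", list(c(1000, 2000)),
              list(c(1100, 1900)))
  mk_pair <- function(gap, strand2) dplyr::bind_rows(
    g1, mk_tx("t2", "g2", "chr1", strand2,
              list(c(2000 + gap, 3000 + gap)),
              list(c(2100 + gap, 2900 + gap))))
  sup_none <- tibble::tibble(transcript_id = "t2", supported = FALSE)
  # same strand 149 apart: flagged, unsupported transcript removed
  r149 <- proximity_review(mk_pair(149, "+"), sup_none)
  expect_equal(nrow(r149$flags), 1L)
  expect_equal(r149$removed_ids, "t2")
  # 151 apart: not flagged, nothing removed
  r151 <- proximity_review(mk_pair(151, "+"), sup_none)
  expect_equal(nrow(r151$flags), 0L)
  expect_length(r151$removed_ids, 0)
  # opposite strands 149 apart without 3' overlap: not rule (a) or (b)
  r_opp <- proximity_review(mk_pair(149, "-"), sup_none)
  expect_equal(nrow(r_opp$flags), 0L)
})

test_that("opposite strands with overlapping 3' ends are flagged", {
  plus <- mk_tx("t1", "g1", "chr1", "+", list(c(1000, 2000)),
                list(c(1100, 1900)))
  minus <- mk_tx("t2", "g2", "chr1", "-", list(c(1990, 2800)),
                 list(c(2050, 2700)))
  sup <- tibble::tibble(transcript_id = c("t1", "t2"),
                        supported = c(TRUE, FALSE))
  r <- proximity_review(dplyr::bind_rows(plus, minus), sup)
  expect_equal(r$flags$rule, "opp_strand_3p_overlap")
  expect_equal(r$removed_ids, "t2")
  # same geometry but the minus gene's 3' exon ends before the plus 3' exon
  minus2 <- mk_tx("t2", "g2", "chr1", "-",
                  list(c(2100, 2300), c(2400, 2800)),
                  list(c(2150, 2300), c(2400, 2700)))
  r2 <- proximity_review(dplyr::bind_rows(plus, minus2), sup)
  expect_equal(nrow(r2$flags), 0L)
})

test_that("planted proximity scenarios resolve as designed", {
  cfg <- sim_config(seed = 37, n_genes = 20, n_proximity_pairs = 6)
  g <- generate_genome(cfg)
  gm <- generate_gene_models(cfg, g)
  ev <- generate_evidence(cfg, gm, g)
  m <- merge_predictions(gm$setA, gm$setB)
  px <- proximity_review(m$merged, ev$junction_support)
  planted_rm <- gm$truth$transcripts$transcript_id[
    !gm$truth$transcripts$junction_support]
  expect_setequal(px$removed_ids, planted_rm)
})
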