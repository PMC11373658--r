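# Shared fixtures and independent brute-force oracles.

# a single-transcript feature table from exon/CDS coordinate vectors
mk_tx <- function(tid, gid, chrom, strand, exons, cds = NULL,
                  source = "setA") {
  ex <- do.call(rbind, exons)
  cd <- if (is.null(cds)) NULL else do.call(rbind, cds)
  tibble::tibble(
    chrom = chrom,
    start = as.integer(c(ex[, 1], if (!is.null(cd)) cd[, 1])),
    end = as.integer(c(ex[, 2], if (!is.null(cd)) cd[, 2])),
    strand = strand,
    type = c(rep("exon", nrow(ex)),
             if (!is.null(cd)) rep("CDS", nrow(cd))),
    transcript_id = tid, gene_id = gid, source = source)
}

# brute-force N50-style statistic by explicit cumulation
brute_nxx <- function(lengths, frac) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(as.numeric(s))
  run <- 0
  for (x in s) {
    run <- run + x
    if (run >= frac * tot) return(x)
  }
  NA_integer_
}

# brute-force all-pairs merge: returns surviving transcript ids, collapse
# count, and the gene partition as a sorted list of sorted member vectors
brute_merge <- function(setA, setB) {
  per_tx <- function(f) {
    out <- list()
    for (tid in unique(f$transcript_id)) {
      t <- f[f$transcript_id == tid, ]
      ex <- t[t$type == "exon", ]; cd <- t[t$type == "CDS", ]
      ex <- ex[order(ex$start), ]; cd <- cd[order(cd$start), ]
      out[[tid]] <- list(chrom = t$chrom[1], strand = t$strand[1],
                         span = c(min(ex$start), max(ex$end)),
                         exons = cbind(ex$start, ex$end),
                         cds = cbind(cd$start, cd$end))
    }
    out
  }
  A <- per_tx(setA); B <- per_tx(setB)
  same_span <- function(x, y) {
    x$chrom == y$chrom && x$strand == y$strand &&
      all(x$span == y$span)
  }
  same_cds <- function(x, y) {
    nrow(x$cds) == nrow(y$cds) && all(x$cds == y$cds)
  }
  collapsed <- character(0)
  for (ta in names(A)) {
    for (tb in sort(names(B))) {
      if (same_span(A[[ta]], B[[tb]]) && same_cds(A[[ta]], B[[tb]])) {
        collapsed <- c(collapsed, ta)
        break
      }
    }
  }
  surv <- c(setdiff(names(A), collapsed), names(B))
  all_tx <- c(A, B)[surv]
  ov <- function(a, b) any(outer(a[, 1], b[, 2], `<`) &
                             outer(a[, 2], b[, 1], `>`))
  n <- length(surv)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      x <- all_tx[[i]]; y <- all_tx[[j]]
      if (x$chrom != y$chrom || x$strand != y$strand) next
      if (all(x$span == y$span)) { adj[i, j] <- TRUE; next }
      if (x$span[1] < y$span[2] && y$span[1] < x$span[2] &&
          nrow(x$cds) > 0 && nrow(y$cds) > 0 && ov(x$cds, y$cds)) {
        adj[i, j] <- TRUE
      }
    }
  }
  # transitive closure by repeated matrix products
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1
      comp[which(adj[i, ])] <- k
    }
  }
  partition <- unname(lapply(split(surv, comp), sort))
  partition <- partition[order(vapply(partition, `[`, character(1), 1))]
  list(surviving = sort(surv), n_collapsed = length(collapsed),
       partition = partition)
}

# gene partition of a merged feature table, in the oracle's normal form
partition_of <- function(features) {
  s <- split(unique(features[, c("transcript_id", "gene_id")])$transcript_id,
             unique(features[, c("transcript_id", "gene_id")])$gene_id)
  p <- unname(lapply(s, sort))
  p[order(vapply(p, `[`, character(1), 1))]
}

# full synthetic pipeline through classification; returns everything the
# truth-recovery tests compare
run_pipeline <- function(cfg) {
  g <- generate_genome(cfg)
  gm <- generate_gene_models(cfg, g)
  ev <- generate_evidence(cfg, gm, g)
  m <- merge_predictions(gm$setA, gm$setB)
  fl <- suppressWarnings(
    filter_lncrna(m$merged, ev$coding_calls, ev$homology,
                  report = m$report))
  px <- proximity_review(fl$kept, ev$junction_support, report = fl$report)
  final <- px$kept
  ca <- associate_cage(ev$cage, final)
  rn <- rnaseq_support(ev$expression, cfg$tpm_threshold)
  bl <- blast_support(ev$homology, unique(final$transcript_id))
  eb <- build_evidence(final, ca, rn, bl,
                       gm$truth$transcripts[, c("transcript_id",
                                                "prediction_order")])
  cl <- classify_gene_models(final, eb)
  reps <- select_representative(eb)
  s <- tx_summary(final)
  tr <- gm$truth$transcripts
  merged_to_planted <- tapply(tr$gene_id[match(s$transcript_id,
                                               tr$transcript_id)],
                              s$gene_id, function(x) x[1])
  list(genome = g, models = gm, evidence = ev, merge = m, lnc = fl,
       prox = px, final = final, cage = ca, rnaseq = rn, blast = bl,
       bundle = eb, classes = cl, reps = reps,
       merged_to_planted = merged_to_planted)
}

# reverse-complement a genome plus coordinate-transformed annotation tables
revcomp_world <- function(genome, features, summits = NULL) {
  L <- stats::setNames(Biostrings::width(genome), names(genome))
  rc <- Biostrings::reverseComplement(genome)
  f <- features
  s <- f$start; e <- f$end
  f$start <- L[f$chrom] - e
  f$end <- L[f$chrom] - s
  f$strand <- c("+" = "-", "-" = "+", "." = ".")[f$strand]
  out <- list(genome = rc, features = f)
  if (!is.null(summits)) {
    sm <- summits
    st <- sm$start; en <- sm$end
    sm$start <- L[sm$chrom] - en
    sm$end <- L[sm$chrom] - st
    sm$summit <- L[sm$chrom] - 1L - sm$summit
    out$summits <- sm
  }
  out
}
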