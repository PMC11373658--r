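# Synthetic data with planted ground truth.
#
# Every generator draws from its own deterministic substream of the master
# seed, so adding or re-running one generator never perturbs the others.

#' Simulation configuration
#'
#' Defaults describe a compact but fully structured annotation problem: two
#' 1 Mb chromosomes, 150 protein-coding genes in six evidence classes, two
#' gene-prediction sets in controlled coordinate-agreement categories,
#' candidate lncRNAs, near-neighbour gene pairs around the 150/300 nt review
#' thresholds, and an interspecific genome pair with planted structural
#' variants and background SNPs.
#'
#' @param seed master seed (integer)
#' @param n_chroms,chrom_length genome shape
#' @param n_genes number of class-planted protein-coding genes
#' @param class_mixture named proportions over N1..N6 (sums to 1)
#' @param agreement_mixture named proportions over the coordinate-agreement
#'   categories `identical`, `same_bounds_diff_exons`, `setA_only`,
#'   `setB_only`, `overlapping_conflict` (sums to 1)
#' @param n_tissues tissue columns of the expression matrix
#' @param tpm_threshold expression presence threshold (TPM)
#' @param lnc_fraction candidate lncRNAs as a fraction of `n_genes`
#' @param n_proximity_pairs planted near-neighbour gene pairs
#' @param n_gaps_per_chrom,gap_length planted assembly gaps (N runs)
#' @param n_cage_decoys CAGE clusters planted outside every association window
#' @param sv_counts named counts of planted qualifying SV events
#' @param sv_size_ranges named list of `c(min, max)` event sizes in bp
#' @param n_sv_decoys_gap,n_sv_decoys_small spurious SV calls overlapping
#'   assembly gaps / below the size thresholds
#' @param divergence_snp_rate per-bp interspecific SNP probability
#' @param min_gene_spacing minimum distance between planted gene spans (bp)
#' @return validated config list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1000000L,
                       n_genes = 150L,
                       class_mixture = c(N1 = 0.25, N2 = 0.08, N3 = 0.12,
                                         N4 = 0.10, N5 = 0.12, N6 = 0.33),
                       agreement_mixture = c(identical = 0.40,
                                             same_bounds_diff_exons = 0.15,
                                             setA_only = 0.20,
                                             setB_only = 0.20,
                                             overlapping_conflict = 0.05),
                       n_tissues = 8L,
                       tpm_threshold = 1,
                       lnc_fraction = 0.05,
                       n_proximity_pairs = 6L,
                       n_gaps_per_chrom = 2L,
                       gap_length = 2000L,
                       n_cage_decoys = 20L,
                       sv_counts = c(deletion = 9L, duplication = 5L,
                                     translocation = 5L, inversion = 1L),
                       sv_size_ranges = list(deletion = c(500, 20000),
                                             duplication = c(50000, 80000),
                                             translocation = c(50000, 80000),
                                             inversion = c(5000000, 5500000)),
                       n_sv_decoys_gap = 3L,
                       n_sv_decoys_small = 3L,
                       divergence_snp_rate = 0.005,
                       min_gene_spacing = 4000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              class_mixture = class_mixture,
              agreement_mixture = agreement_mixture,
              n_tissues = as.integer(n_tissues),
              tpm_threshold = tpm_threshold,
              lnc_fraction = lnc_fraction,
              n_proximity_pairs = as.integer(n_proximity_pairs),
              n_gaps_per_chrom = as.integer(n_gaps_per_chrom),
              gap_length = as.integer(gap_length),
              n_cage_decoys = as.integer(n_cage_decoys),
              sv_counts = sv_counts, sv_size_ranges = sv_size_ranges,
              n_sv_decoys_gap = as.integer(n_sv_decoys_gap),
              n_sv_decoys_small = as.integer(n_sv_decoys_small),
              divergence_snp_rate = divergence_snp_rate,
              min_gene_spacing = as.integer(min_gene_spacing))
  stopifnot(cfg$seed >= 0, cfg$n_chroms >= 1, cfg$chrom_length >= 10000,
            cfg$n_genes >= 0, cfg$n_tissues >= 2)
  if (abs(sum(class_mixture) - 1) > 1e-9) stop("class_mixture must sum to 1")
  if (!setequal(names(class_mixture), paste0("N", 1:6))) {
    stop("class_mixture must be named N1..N6")
  }
  if (abs(sum(agreement_mixture) - 1) > 1e-9) {
    stop("agreement_mixture must sum to 1")
  }
  if (!setequal(names(agreement_mixture),
                c("identical", "same_bounds_diff_exons", "setA_only",
                  "setB_only", "overlapping_conflict"))) {
    stop("agreement_mixture has wrong category names")
  }
  if (any(cfg$sv_counts < 0)) stop("sv_counts must be >= 0")
  # generous feasibility bound: worst-case gene footprint plus spacing
  footprint <- 4 * 450 + 3 * 400 + cfg$min_gene_spacing
  need <- (cfg$n_genes + 2 * cfg$n_proximity_pairs +
             ceiling(cfg$lnc_fraction * cfg$n_genes)) * footprint
  avail <- cfg$n_chroms *
    (cfg$chrom_length - 2 * 3000 -
       cfg$n_gaps_per_chrom * (cfg$gap_length + 2 * 3000))
  if (need > avail) {
    stop("config error: chrom_length too small to place ", cfg$n_genes,
         " genes with spacing ", cfg$min_gene_spacing)
  }
  class(cfg) <- "sim_config"
  cfg
}

random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a random genome with planted assembly gaps
#'
#' Uniform i.i.d. A/C/G/T background with `n_gaps_per_chrom` N-runs of
#' `gap_length` bp planted at recorded positions. Deterministic for a fixed
#' config seed.
#'
#' @param config [sim_config()]
#' @return list with `genome` (DNAStringSet) and `gaps` (tibble
#'   `chrom`,`start`,`end`, 0-based half-open)
#' @export
generate_genome <- function(config) {
  set.seed(substream_seed(config$seed, "genome"))
  L <- config$chrom_length
  gl <- config$gap_length
  ng <- config$n_gaps_per_chrom
  if (ng > 0 && ng * (gl + 20000) > L - 20000) {
    stop("config error: cannot place ", ng, " gaps of ", gl, " bp")
  }
  seqs <- character(config$n_chroms)
  gaps <- list()
  for (i in seq_len(config$n_chroms)) {
    s <- random_chrom(L)
    if (ng > 0) {
      # evenly spread slots, jittered; keeps gaps well separated
      slot <- floor(L / (ng + 1)) * seq_len(ng)
      starts <- slot + sample(-2000:2000, ng, replace = TRUE)
      for (g in starts) {
        substr(s, g + 1, g + gl) <- paste(rep("N", gl), collapse = "")
      }
      gaps[[i]] <- tibble::tibble(chrom = paste0("chr", i),
                                  start = as.integer(starts),
                                  end = as.integer(starts + gl))
    }
    seqs[i] <- s
  }
  names(seqs) <- paste0("chr", seq_len(config$n_chroms))
  gaps <- if (length(gaps)) dplyr::bind_rows(gaps) else
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  list(genome = as_genome(seqs), gaps = gaps)
}

# -- gene structure templates -----------------------------------------------

# relative exon table for one transcript; coordinates relative to span start
gene_template <- function(min_exons = 1L) {
  n_exons <- sample(min_exons:4, 1,
                    prob = c(0.25, 0.3, 0.25, 0.2)[min_exons:4])
  exon_len <- sample(150:450, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1) sample(80:400, n_exons - 1, TRUE) else integer()
  starts <- cumsum(c(0L, head(exon_len, -1) + intron_len))
  list(exon_start = as.integer(starts),
       exon_end = as.integer(starts + exon_len),
       span = as.integer(sum(exon_len) + sum(intron_len)))
}

# CDS intervals for a template given 5'/3' UTR lengths (transcription sense)
template_cds <- function(tpl, strand, utr5, utr3) {
  lo <- if (strand == "-") utr3 else utr5
  hi <- tpl$span - (if (strand == "-") utr5 else utr3)
  cs <- pmax(tpl$exon_start, lo)
  ce <- pmin(tpl$exon_end, hi)
  keep <- cs < ce
  list(cds_start = as.integer(cs[keep]), cds_end = as.integer(ce[keep]),
       len = sum(ce[keep] - cs[keep]))
}

# shift one internal boundary by delta; span is preserved
template_variant <- function(tpl, delta) {
  n <- length(tpl$exon_start)
  stopifnot(n >= 2)
  j <- sample(seq_len(n - 1), 1)                 # boundary after exon j
  e <- tpl$exon_end
  new_end <- e[j] + delta
  # keep exon >= 50 and intron >= 40
  if (new_end - tpl$exon_start[j] < 50 ||
      tpl$exon_start[j + 1] - new_end < 40) {
    delta <- -delta
    new_end <- e[j] + delta
  }
  e[j] <- new_end
  out <- tpl
  out$exon_end <- as.integer(e)
  out
}

CLASS_AXES <- list(N1 = c(C = 1, R = 1, B = 1), N3 = c(C = 0, R = 1, B = 1),
                   N5 = c(C = 0, R = 0, B = 1), N6 = c(C = 0, R = 0, B = 0))

draw_axes <- function(class) {
  switch(class,
    N2 = if (sample(c(TRUE, FALSE), 1)) c(C = 1, R = 1, B = 0)
         else c(C = 1, R = 0, B = 1),
    N4 = if (sample(c(TRUE, FALSE), 1)) c(C = 1, R = 0, B = 0)
         else c(C = 0, R = 1, B = 0),
    CLASS_AXES[[class]])
}

# which ranking criterion can separate isoforms of a gene with these axes;
# the CAGE axis is never dropped (a planted cluster would flag every
# in-window isoform anyway)
feasible_depths <- function(axes) {
  d <- 5L                                        # CDS length always separates
  if (axes[["R"]] == 1 || axes[["B"]] == 1) d <- c(1L, d)
  if (axes[["B"]] == 1) d <- c(d, 2L)
  if (axes[["R"]] == 1) d <- c(d, 3L, 4L)
  sort(unique(d))
}

#' Generate two gene-prediction sets with planted ground truth
#'
#' Places non-overlapping genes on the genome (skipping assembly gaps),
#' assigns each gene a coordinate-agreement category between the two
#' prediction sets, a six-class evidence plan, a planted representative
#' isoform with a known deciding criterion, candidate lncRNAs, and
#' near-neighbour gene pairs at distances around the 150/300 nt review
#' thresholds.
#'
#' @param config [sim_config()]
#' @param genome result of [generate_genome()] (list with `genome`, `gaps`)
#' @return list with feature tibbles `setA` and `setB` plus `truth`
#'   (per-gene and per-transcript tables)
#' @export
generate_gene_models <- function(config, genome) {
  set.seed(substream_seed(config$seed, "genes"))
  gaps <- genome$gaps
  chrom_names <- names(genome$genome)
  chrom_len <- stats::setNames(Biostrings::width(genome$genome), chrom_names)

  n_lnc <- ceiling(config$lnc_fraction * config$n_genes)
  classes <- sample(names(config$class_mixture), config$n_genes,
                    replace = TRUE, prob = config$class_mixture)
  agreements <- sample(names(config$agreement_mixture), config$n_genes,
                       replace = TRUE, prob = config$agreement_mixture)

  pair_scenarios <- c("same_strand_100", "same_strand_149", "same_strand_151",
                      "same_strand_200", "opp_overlap_3p", "opp_apart_250")
  scen <- if (config$n_proximity_pairs > 0) {
    pair_scenarios[((seq_len(config$n_proximity_pairs) - 1) %%
                      length(pair_scenarios)) + 1]
  } else character()

  genes <- list(); txs <- list()
  featA <- list(); featB <- list()
  gi <- 0L

  # --- free placement runs: complement of gaps with margins ---------------
  runs <- list()
  for (cn in chrom_names) {
    g <- gaps[gaps$chrom == cn, , drop = FALSE]
    bounds <- sort(c(3000L, g$start - 3000L, g$end + 3000L,
                     chrom_len[[cn]] - 3000L))
    for (k in seq(1, length(bounds) - 1, by = 2)) {
      if (bounds[k + 1] - bounds[k] > 20000) {
        runs[[length(runs) + 1]] <- list(chrom = cn, at = bounds[k],
                                         end = bounds[k + 1])
      }
    }
  }
  run_i <- 1L
  place <- function(footprint) {
    while (run_i <= length(runs)) {
      r <- runs[[run_i]]
      if (r$at + footprint + config$min_gene_spacing <= r$end) {
        pos <- r$at
        runs[[run_i]]$at <<- r$at + footprint + config$min_gene_spacing
        return(list(chrom = r$chrom, pos = pos))
      }
      run_i <<- run_i + 1L
    }
    stop("config error: infeasible gene placement")
  }

  emit_tx <- function(gid, set, tid, chrom, offset, strand, tpl, utr5, utr3) {
    cds <- template_cds(tpl, strand, utr5, utr3)
    tibble::tibble(
      chrom = chrom,
      start = as.integer(offset + c(tpl$exon_start, cds$cds_start)),
      end = as.integer(offset + c(tpl$exon_end, cds$cds_end)),
      strand = strand,
      type = c(rep("exon", length(tpl$exon_start)),
               rep("CDS", length(cds$cds_start))),
      transcript_id = tid,
      gene_id = paste0(gid, if (set == "setA") "A" else "B"),
      source = set)
  }

  # ---- evidence plan for one gene's surviving isoform set ----------------
  # depth = the ranking criterion planted to decide the representative
  # (0 = single isoform, 6 = everything ties, first prediction wins)
  plan_gene <- function(axes, n_iso, cds_lens, allowed = 1:5) {
    pred_order <- sample(n_iso)
    depth <- if (n_iso == 1) 0L else {
      fd <- intersect(feasible_depths(axes), allowed)
      if (length(fd) == 0) 6L else fd[sample(length(fd), 1)]
    }
    winner <- if (n_iso == 1) 1L else if (depth == 5L) which.max(cds_lens)
      else if (depth == 6L) which.min(pred_order) else sample(n_iso, 1)
    p <- list(depth = depth, winner = winner)
    ax <- matrix(rep(axes, n_iso), nrow = n_iso, byrow = TRUE,
                 dimnames = list(NULL, c("C", "R", "B")))
    if (depth == 1L) {
      droppable <- c("R", "B")[c(axes[["R"]] == 1, axes[["B"]] == 1)]
      for (i in seq_len(n_iso)[-winner]) {
        ax[i, sample(droppable, 1)] <- 0
      }
    }
    ev <- rep(NA_real_, n_iso)
    if (any(ax[, "B"] == 1)) {
      if (depth == 2L) {
        ev[winner] <- 20 + sample(1:20, 1)
        los <- seq_len(n_iso)[-winner]
        ev[los] <- sample(6:18, length(los), replace = TRUE)
      } else {
        ev[ax[, "B"] == 1] <- 20 + sample(1:20, 1)   # exact tie
      }
      ev[ax[, "B"] == 0] <- NA_real_
    }
    k <- integer(n_iso)
    if (any(ax[, "R"] == 1)) {
      if (depth == 3L) {
        kw <- sample(2:config$n_tissues, 1)
        k[winner] <- kw
        los <- seq_len(n_iso)[-winner]
        k[los] <- sample(seq_len(kw - 1), length(los), replace = TRUE)
      } else {
        k[ax[, "R"] == 1] <- sample(seq_len(config$n_tissues), 1)
      }
      k[ax[, "R"] == 0] <- 0L
    }
    tpm <- numeric(n_iso)
    if (any(ax[, "R"] == 1)) {
      if (depth == 4L) {
        tpm[winner] <- 50 + stats::runif(1) * 50
        los <- seq_len(n_iso)[-winner]
        tpm[los] <- config$tpm_threshold + stats::runif(length(los)) * 20
      } else {
        tpm[ax[, "R"] == 1] <- 5 + stats::runif(1) * 45  # exact tie
      }
      tpm[ax[, "R"] == 0] <- 0
    }
    p$axes <- ax; p$evalue_exp <- ev; p$k_tissues <- k; p$tpm_target <- tpm
    p$pred_order <- pred_order
    p
  }

  add_gene <- function(class, agreement, pair_id = NA_character_,
                       pair_scenario = NA_character_,
                       chrom, offset, strand,
                       junction_unsupported = FALSE) {
    gi <<- gi + 1L
    gid <- sprintf("G%04d", gi)
    axes <- draw_axes(class)
    multi_iso <- agreement %in% c("identical", "setA_only", "setB_only") &&
      is.na(pair_id)
    n_struct <- if (multi_iso) sample(1:3, 1, prob = c(0.55, 0.3, 0.15)) else 1L
    min_exons <- if (n_struct > 1 ||
                     agreement %in% c("same_bounds_diff_exons")) 2L else 1L
    tpl <- gene_template(min_exons)
    utr5 <- sample(20:100, 1); utr3 <- sample(20:100, 1)
    if (length(tpl$exon_start) == 1L) {
      # single-exon gene: keep a real ORF between the UTRs
      budget <- (tpl$exon_end[1] - tpl$exon_start[1]) - 60L
      utr5 <- min(utr5, budget %/% 2L)
      utr3 <- min(utr3, budget - utr5)
    }
    # isoform structural variants (span-preserving boundary shifts)
    tpls <- list(tpl)
    if (n_struct > 1) {
      for (j in 2:n_struct) {
        repeat {
          v <- template_variant(tpl, sample(c(-1, 1), 1) * sample(3:30, 1) * 3)
          lens_so_far <- vapply(tpls, function(t)
            template_cds(t, strand, utr5, utr3)$len, numeric(1))
          if (!identical(v$exon_end, tpl$exon_end) &&
              !template_cds(v, strand, utr5, utr3)$len %in% lens_so_far) break
        }
        tpls[[j]] <- v
      }
    }
    cds_lens <- vapply(tpls, function(t)
      template_cds(t, strand, utr5, utr3)$len, numeric(1))

    fa <- list(); fb <- list(); trow <- list()
    surv_ids <- character(); surv_tpl_idx <- integer()

    if (agreement == "identical") {
      for (j in seq_len(n_struct)) {
        ta <- sprintf("%s.tA%d", gid, j); tb <- sprintf("%s.tB%d", gid, j)
        fa[[j]] <- emit_tx(gid, "setA", ta, chrom, offset, strand, tpls[[j]],
                           utr5, utr3)
        fb[[j]] <- emit_tx(gid, "setB", tb, chrom, offset, strand, tpls[[j]],
                           utr5, utr3)
        surv_ids <- c(surv_ids, tb); surv_tpl_idx <- c(surv_tpl_idx, j)
      }
    } else if (agreement == "same_bounds_diff_exons") {
      ta <- sprintf("%s.tA1", gid); tb <- sprintf("%s.tB1", gid)
      repeat {
        v <- template_variant(tpl, sample(c(-1, 1), 1) * sample(3:30, 1) * 3)
        if (!identical(v$exon_end, tpl$exon_end)) break
      }
      tpls <- list(tpl, v)
      cds_lens <- vapply(tpls, function(t)
        template_cds(t, strand, utr5, utr3)$len, numeric(1))
      fa[[1]] <- emit_tx(gid, "setA", ta, chrom, offset, strand, tpl,
                         utr5, utr3)
      fb[[1]] <- emit_tx(gid, "setB", tb, chrom, offset, strand, v,
                         utr5, utr3)
      surv_ids <- c(ta, tb); surv_tpl_idx <- c(1L, 2L)
    } else if (agreement == "overlapping_conflict") {
      ta <- sprintf("%s.tA1", gid); tb <- sprintf("%s.tB1", gid)
      # the shifted copy must keep >= 1 bp of CDS overlap: stay below the
      # longest single CDS interval
      cds0 <- template_cds(tpl, strand, utr5, utr3)
      max_piece <- max(cds0$cds_end - cds0$cds_start)
      shift <- sample(seq(30L, max(31L, min(300L, max_piece - 10L))), 1)
      fa[[1]] <- emit_tx(gid, "setA", ta, chrom, offset, strand, tpl,
                         utr5, utr3)
      fb[[1]] <- emit_tx(gid, "setB", tb, chrom, offset + shift, strand, tpl,
                         utr5, utr3)
      tpls <- list(tpl, tpl)
      cds_lens <- c(cds_lens[1], cds_lens[1])
      surv_ids <- c(ta, tb); surv_tpl_idx <- c(1L, 2L)
    } else {  # setA_only / setB_only
      set <- if (agreement == "setA_only") "setA" else "setB"
      for (j in seq_len(n_struct)) {
        tid <- sprintf("%s.t%s%d", gid, if (set == "setA") "A" else "B", j)
        row <- emit_tx(gid, set, tid, chrom, offset, strand, tpls[[j]],
                       utr5, utr3)
        if (set == "setA") fa[[j]] <- row else fb[[j]] <- row
        surv_ids <- c(surv_ids, tid); surv_tpl_idx <- c(surv_tpl_idx, j)
      }
    }

    # overlapping_conflict copies share a CDS length, so criterion 5 cannot
    # separate them; fall back to prediction order (depth 6) if nothing else
    plan <- if (agreement == "overlapping_conflict" && length(surv_ids) > 1) {
      plan_gene(axes, length(surv_ids), cds_lens, allowed = 1:4)
    } else plan_gene(axes, length(surv_ids), cds_lens[surv_tpl_idx])

    rep_id <- surv_ids[plan$winner]
    genes[[gi]] <<- tibble::tibble(
      gene_id = gid, chrom = chrom, strand = strand, class = class,
      agreement = agreement, n_isoforms = length(surv_ids),
      representative = rep_id, depth = plan$depth,
      pair_id = pair_id, pair_scenario = pair_scenario)

    mk_rows <- function(ids, set, fate, iso_idx) {
      tibble::tibble(
        transcript_id = ids, set = set, gene_id = gid,
        agreement = agreement, fate = fate, is_lncrna = FALSE,
        junction_support = TRUE,
        cage = plan$axes[iso_idx, "C"] == 1,
        rna = plan$axes[iso_idx, "R"] == 1,
        blast = plan$axes[iso_idx, "B"] == 1,
        evalue_exp = plan$evalue_exp[iso_idx],
        k_tissues = plan$k_tissues[iso_idx],
        tpm_target = plan$tpm_target[iso_idx],
        prediction_order = plan$pred_order[iso_idx])
    }
    surv_set <- ifelse(grepl("\\.tA", surv_ids), "setA", "setB")
    rows <- mk_rows(surv_ids, surv_set, "kept", seq_along(surv_ids))
    if (agreement == "identical") {
      a_ids <- sub("\\.tB", ".tA", surv_ids)
      rows <- dplyr::bind_rows(rows,
        mk_rows(a_ids, "setA", "collapsed", seq_along(surv_ids)))
    }
    if (junction_unsupported) {
      # one transcript of a flagged pair gene loses RNA-seq junction support
      rows$junction_support[1] <- FALSE
    }
    txs[[gi]] <<- rows
    featA[[gi]] <<- dplyr::bind_rows(fa)
    featB[[gi]] <<- dplyr::bind_rows(fb)
    list(gid = gid, span = max(vapply(tpls, function(t) t$span, numeric(1))))
  }

  # --- regular genes -------------------------------------------------------
  for (i in seq_len(config$n_genes)) {
    strand <- sample(c("+", "-"), 1)
    # worst-case footprint: span + conflict shift
    tpl_foot <- 4 * 450 + 3 * 400 + 300
    at <- place(tpl_foot)
    add_gene(classes[i], agreements[i], chrom = at$chrom, offset = at$pos,
             strand = strand)
  }

  # --- proximity pairs (single-isoform, CAGE-free classes) ----------------
  for (p in seq_along(scen)) {
    s <- scen[p]
    pid <- sprintf("pair%02d", p)
    at <- place(2 * (4 * 450 + 3 * 400) + 400)
    cls <- sample(c("N3", "N5", "N6"), 2, replace = TRUE)
    flagged <- s %in% c("same_strand_100", "same_strand_149", "opp_overlap_3p")
    if (startsWith(s, "same_strand")) {
      gap <- as.integer(sub("same_strand_", "", s))
      strand <- sample(c("+", "-"), 1)
      g1 <- add_gene(cls[1], "setB_only", pid, s, at$chrom, at$pos, strand,
                     junction_unsupported = flagged)
      add_gene(cls[2], "setB_only", pid, s, at$chrom,
               at$pos + g1$span + gap, strand)
    } else if (s == "opp_overlap_3p") {
      # convergent genes whose 3'-terminal exons share 10 bp
      g1 <- add_gene(cls[1], "setB_only", pid, s, at$chrom, at$pos, "+",
                     junction_unsupported = TRUE)
      add_gene(cls[2], "setB_only", pid, s, at$chrom,
               at$pos + g1$span - 10L, "-")
    } else {  # opp_apart_250: opposite strands, no 3' overlap, not flagged
      g1 <- add_gene(cls[1], "setB_only", pid, s, at$chrom, at$pos, "+")
      add_gene(cls[2], "setB_only", pid, s, at$chrom,
               at$pos + g1$span + 250L, "-")
    }
  }

  # --- candidate lncRNAs: single-exon, weak ORF, no homology --------------
  for (j in seq_len(n_lnc)) {
    gi <- gi + 1L
    gid <- sprintf("L%04d", j)
    len <- sample(300:1500, 1)
    at <- place(len)
    strand <- sample(c("+", "-"), 1)
    set <- sample(c("setA", "setB"), 1)
    tid <- sprintf("%s.t%s1", gid, if (set == "setA") "A" else "B")
    orf <- sample(90:240, 1)
    orf_off <- sample(10:(len - orf - 10), 1)
    f <- tibble::tibble(
      chrom = at$chrom,
      start = as.integer(at$pos + c(0L, orf_off)),
      end = as.integer(at$pos + c(len, orf_off + orf)),
      strand = strand, type = c("exon", "CDS"),
      transcript_id = tid,
      gene_id = paste0(gid, if (set == "setA") "A" else "B"),
      source = set)
    if (set == "setA") featA[[gi]] <- f else featB[[gi]] <- f
    genes[[gi]] <- tibble::tibble(
      gene_id = gid, chrom = at$chrom, strand = strand, class = NA_character_,
      agreement = set, n_isoforms = 1L, representative = tid, depth = 0L,
      pair_id = NA_character_, pair_scenario = NA_character_)
    txs[[gi]] <- tibble::tibble(
      transcript_id = tid, set = set, gene_id = gid, agreement = set,
      fate = "lncrna_removed", is_lncrna = TRUE, junction_support = TRUE,
      cage = FALSE, rna = FALSE, blast = FALSE, evalue_exp = NA_real_,
      k_tissues = 0L, tpm_target = 0, prediction_order = 1L)
  }

  setA <- dplyr::bind_rows(featA)
  setB <- dplyr::bind_rows(featB)
  validate_tx(setA); validate_tx(setB)
  list(setA = setA, setB = setB,
       truth = list(genes = dplyr::bind_rows(genes),
                    transcripts = dplyr::bind_rows(txs)))
}

# window of positions whose CAGE summit would support a transcript, genomic
# coordinates, both bounds inclusive
cage_window <- function(strand, cds_start_pos, upstream = 3000L,
                        downstream = 10L) {
  if (strand == "-") c(cds_start_pos - downstream, cds_start_pos + upstream)
  else c(cds_start_pos - upstream, cds_start_pos + downstream)
}

#' Generate evidence tables consistent with each gene's planted class
#'
#' Emits CAGE tag clusters (inside the association window for CAGE-supported
#' genes, plus decoys outside every window), a transcripts-by-tissues TPM
#' matrix, a homology hit table, coding-potential verdicts from two simulated
#' callers, RNA-seq junction-support flags, and per-cytosine methylation
#' calls drawn from class-dependent templates (CG/CHG troughs at translation
#' start/end for expressed classes, uniformly dense CG/CHG for silent
#' classes, low CHH everywhere).
#'
#' @param config [sim_config()]
#' @param models result of [generate_gene_models()]
#' @param genome result of [generate_genome()]
#' @return list of tibbles: `cage`, `expression`, `homology`, `coding_calls`,
#'   `junction_support`, `methylation`, and `cage_truth` (cluster-to-gene
#'   assignment ground truth with ambiguity flags)
#' @export
generate_evidence <- function(config, models, genome) {
  set.seed(substream_seed(config$seed, "evidence"))
  feats <- dplyr::bind_rows(models$setA, models$setB)
  summ <- tx_summary(feats)
  plan <- dplyr::left_join(models$truth$transcripts,
                           summ[, c("transcript_id", "chrom", "strand",
                                    "cds_start_pos", "tx_start", "tx_end")],
                           by = "transcript_id")
  chrom_len <- stats::setNames(Biostrings::width(genome$genome),
                               names(genome$genome))

  # ---- CAGE clusters ------------------------------------------------------
  cage_rows <- list(); truth_rows <- list()
  gene_cage <- plan %>% group_by(.data$gene_id) %>%
    summarise(any_cage = any(.data$cage), .groups = "drop")
  for (gid in gene_cage$gene_id[gene_cage$any_cage]) {
    p <- plan[plan$gene_id == gid, ]
    if (p$strand[1] == "+") {
      lo <- max(p$cds_start_pos) - 3000L
      hi <- min(p$cds_start_pos) + 10L
      summit <- min(p$cds_start_pos) - sample(0:600, 1)
    } else {
      lo <- max(p$cds_start_pos) - 10L
      hi <- min(p$cds_start_pos) + 3000L
      summit <- max(p$cds_start_pos) + sample(0:600, 1)
    }
    summit <- max(min(summit, hi), lo)
    w <- sample(5:40, 1)
    cstart <- max(summit - sample(0:(w - 1), 1), 0L)
    cage_rows[[gid]] <- tibble::tibble(
      chrom = p$chrom[1], start = as.integer(cstart),
      end = as.integer(cstart + w), name = paste0("cage_", gid),
      score = sample(5:500, 1), strand = ".",
      summit = as.integer(summit))
    truth_rows[[gid]] <- tibble::tibble(name = paste0("cage_", gid),
                                        target_gene = gid)
  }

  # decoys: anywhere outside every (padded) association window
  win <- plan[!is.na(plan$cds_start_pos), ]
  win_lo <- ifelse(win$strand == "-", win$cds_start_pos - 10L - 50L,
                   win$cds_start_pos - 3000L - 50L)
  win_hi <- ifelse(win$strand == "-", win$cds_start_pos + 3000L + 50L,
                   win$cds_start_pos + 10L + 50L)
  for (d in seq_len(config$n_cage_decoys)) {
    repeat {
      cn <- sample(names(chrom_len), 1)
      pos <- sample(chrom_len[[cn]] - 100L, 1)
      hit <- win$chrom == cn & win_lo <= pos & pos <= win_hi
      if (!any(hit)) break
    }
    w <- sample(5:40, 1)
    cstart <- max(pos - sample(0:(w - 1), 1), 0L)
    nm <- sprintf("cage_decoy%03d", d)
    cage_rows[[nm]] <- tibble::tibble(
      chrom = cn, start = as.integer(cstart), end = as.integer(cstart + w),
      name = nm, score = sample(5:500, 1), strand = ".",
      summit = as.integer(pos))
    truth_rows[[nm]] <- tibble::tibble(name = nm, target_gene = NA_character_)
  }
  cage <- dplyr::bind_rows(cage_rows)
  cage_truth <- dplyr::bind_rows(truth_rows)
  # generator-side ambiguity audit: how many genes' windows hold each summit
  n_genes_hit <- vapply(seq_len(nrow(cage)), function(i) {
    hit <- win$chrom == cage$chrom[i] & win_lo <= cage$summit[i] &
      cage$summit[i] <= win_hi
    length(unique(win$gene_id[hit]))
  }, integer(1))
  cage_truth$ambiguous <- n_genes_hit[match(cage_truth$name, cage$name)] >= 2L

  # ---- expression matrix --------------------------------------------------
  thr <- config$tpm_threshold
  g_iso <- models$truth$genes
  n_iso <- g_iso$n_isoforms[match(plan$gene_id, g_iso$gene_id)]
  expr <- matrix(0, nrow = nrow(plan), ncol = config$n_tissues,
                 dimnames = list(plan$transcript_id,
                                 paste0("tissue_", seq_len(config$n_tissues))))
  for (i in seq_len(nrow(plan))) {
    k <- plan$k_tissues[i]
    if (k > 0) {
      cols <- sample(config$n_tissues, k)
      vals <- thr + (plan$tpm_target[i] - thr) * 0.8 * stats::runif(k)
      vals[1] <- plan$tpm_target[i]
      expr[i, cols] <- vals
    } else if (!plan$is_lncrna[i] && n_iso[i] == 1L &&
               stats::runif(1) < 0.3) {
      # sub-threshold noise exercises the presence cutoff; single-isoform
      # genes only, so it can never reorder a ranking cascade
      expr[i, sample(config$n_tissues, 1)] <- stats::runif(1, 0, 0.9 * thr)
    }
  }
  expression <- dplyr::bind_cols(
    tibble::tibble(transcript_id = plan$transcript_id),
    tibble::as_tibble(expr))

  # ---- homology hits ------------------------------------------------------
  hom <- list()
  for (i in seq_len(nrow(plan))) {
    tid <- plan$transcript_id[i]
    if (plan$blast[i]) {
      hom[[length(hom) + 1]] <- tibble::tibble(
        query = tid, subject = paste0("hom_", tid),
        pident = round(stats::runif(1, 60, 99), 1),
        qcov = round(stats::runif(1, 55, 100), 1),
        evalue = 10^(-plan$evalue_exp[i]))
      if (stats::runif(1) < 0.2) {  # extra non-qualifying hit: low coverage
        hom[[length(hom) + 1]] <- tibble::tibble(
          query = tid, subject = paste0("junk_", tid),
          pident = round(stats::runif(1, 60, 99), 1),
          qcov = round(stats::runif(1, 10, 45), 1), evalue = 1e-40)
      }
    } else if (!plan$is_lncrna[i] && stats::runif(1) < 0.15) {
      # weak hit above the e-value cutoff: must not confer support
      hom[[length(hom) + 1]] <- tibble::tibble(
        query = tid, subject = paste0("weak_", tid),
        pident = round(stats::runif(1, 40, 70), 1),
        qcov = round(stats::runif(1, 55, 95), 1),
        evalue = 10^(-stats::runif(1, 1, 4.5)))
    }
  }
  homology <- dplyr::bind_rows(hom)

  # ---- coding-potential calls --------------------------------------------
  verdicts <- tibble::tibble(transcript_id = rep(plan$transcript_id, 2),
                             caller = rep(c("caller_a", "caller_b"),
                                          each = nrow(plan)),
                             verdict = "coding")
  verdicts$verdict[verdicts$transcript_id %in%
                     plan$transcript_id[plan$is_lncrna]] <- "noncoding"
  # some homology-backed transcripts get one stray non-coding verdict;
  # the consensus rule must keep them
  stray <- plan$transcript_id[plan$blast & !plan$is_lncrna &
                                stats::runif(nrow(plan)) < 0.1]
  pick <- sample(c("caller_a", "caller_b"), length(stray), replace = TRUE)
  verdicts$verdict[match(paste(stray, pick),
                         paste(verdicts$transcript_id, verdicts$caller))] <-
    "noncoding"
  coding_calls <- verdicts

  junction_support <- plan[, c("transcript_id", "junction_support")]
  names(junction_support)[2] <- "supported"

  # ---- methylation calls --------------------------------------------------
  meth <- simulate_methylation(config, models, genome)

  list(cage = cage, expression = expression, homology = homology,
       coding_calls = coding_calls, junction_support = junction_support,
       methylation = meth, cage_truth = cage_truth)
}

# class-dependent per-cytosine methylation templates around the planted
# representative isoform of each classified gene
simulate_methylation <- function(config, models, genome) {
  set.seed(substream_seed(config$seed, "methylation"))
  feats <- dplyr::bind_rows(models$setA, models$setB)
  summ <- tx_summary(feats)
  g <- models$truth$genes
  g <- g[!is.na(g$class), ]
  reps <- summ[match(g$representative, summ$transcript_id), ]
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    cn <- reps$chrom[i]
    L <- Biostrings::width(genome$genome)[match(cn, names(genome$genome))]
    lo <- max(reps$tx_start[i] - 600L, 0L)
    hi <- min(reps$tx_end[i] + 600L, L)
    s <- as.character(Biostrings::subseq(genome$genome[[cn]], lo + 1, hi))
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    nch <- length(ch)
    posC <- which(ch == "C"); posG <- which(ch == "G")
    at <- function(i, fill) {
      ok <- i >= 1 & i <= nch
      out <- rep(fill, length(i))
      out[ok] <- ch[i[ok]]
      out
    }
    ctx_of <- function(p, plus) {
      if (plus) {
        n1 <- at(p + 1L, "A"); n2 <- at(p + 2L, "A")
      } else {
        n1 <- chartr("ACGTN", "TGCAN", at(p - 1L, "T"))
        n2 <- chartr("ACGTN", "TGCAN", at(p - 2L, "T"))
      }
      ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
    }
    pos <- c(posC, posG)
    strand <- rep(c("+", "-"), c(length(posC), length(posG)))
    ctx <- c(ctx_of(posC, TRUE), ctx_of(posG, FALSE))
    abs_pos <- lo + pos - 1L
    d <- pmin(abs(abs_pos - reps$cds_start_pos[i]),
              abs(abs_pos - reps$cds_end_pos[i]))
    expressed <- g$class[i] %in% c("N1", "N2", "N3", "N4")
    m <- ifelse(ctx == "CHH", 0.08,
                if (expressed) 0.65 - 0.53 * exp(-d^2 / (2 * 75^2)) else 0.85)
    lev <- stats::rbeta(length(m), m * 20, (1 - m) * 20)
    n_tot <- 5L + stats::rpois(length(m), 8)
    n_met <- stats::rbinom(length(m), n_tot, lev)
    out[[i]] <- tibble::tibble(chrom = cn, pos = abs_pos, strand = strand,
                               context = ctx, n_meth = n_met, n_total = n_tot)
  }
  dplyr::bind_rows(out) %>% dplyr::arrange(.data$chrom, .data$pos)
}

#' Derive a diverged genome with planted structural variants
#'
#' Applies the configured deletions, tandem duplications, intra-chromosomal
#' translocations and inversions to the input genome, plus background SNPs in
#' collinear sequence, tracking both-genome coordinates of every event. Also
#' fabricates spurious SV calls (overlapping assembly gaps, or below the size
#' thresholds) that the filter must reject.
#'
#' @param config [sim_config()]
#' @param genome result of [generate_genome()] for species A
#' @return list: `genome_b`, `svs` (call table for [filter_svs()]), `truth`
#'   (planted events with `applied`, `gap_overlap` and `qualifies` flags),
#'   `snps` (posA/posB/refA/altB), `blocks` (collinear A<->B intervals)
#' @export
generate_sv_pair <- function(config, genome) {
  set.seed(substream_seed(config$seed, "sv"))
  gen <- genome$genome
  gaps <- genome$gaps
  chrom_len <- stats::setNames(Biostrings::width(gen), names(gen))

  # ---- plant true events --------------------------------------------------
  ev <- list()
  for (tp in names(config$sv_counts)) {
    n <- config$sv_counts[[tp]]
    if (n == 0) next
    rng <- config$sv_size_ranges[[tp]]
    sz <- as.integer(round(stats::runif(n, rng[1], rng[2])))
    for (k in seq_len(n)) {
      ev[[length(ev) + 1]] <- list(type = tp, size = sz[k],
                                   needs_target = tp == "translocation")
    }
  }
  # largest first; big inversions may span gaps (recorded, not avoided)
  ev <- ev[order(-vapply(ev, function(e) e$size, numeric(1)))]

  occupied <- stats::setNames(vector("list", length(gen)), names(gen))
  margin <- 5000L; spacing <- 2000L
  fits <- function(cn, s, e, avoid_gaps = TRUE) {
    if (s < margin || e > chrom_len[[cn]] - margin) return(FALSE)
    occ <- occupied[[cn]]
    for (o in occ) if (s < o[2] + spacing && o[1] - spacing < e) return(FALSE)
    if (avoid_gaps) {
      g <- gaps[gaps$chrom == cn, ]
      if (any(s < g$end + spacing & g$start - spacing < e)) return(FALSE)
    }
    TRUE
  }
  claim <- function(cn, s, e) {
    occupied[[cn]][[length(occupied[[cn]]) + 1]] <<- c(s, e)
  }
  pick_spot <- function(size, avoid_gaps) {
    for (try in 1:4000) {
      cn <- sample(names(gen), 1,
                   prob = chrom_len / sum(as.numeric(chrom_len)))
      s <- sample.int(max(chrom_len[[cn]] - size - 2L * margin, 1), 1) + margin
      if (fits(cn, s, s + size, avoid_gaps)) {
        claim(cn, s, s + size)
        return(list(chrom = cn, start = as.integer(s),
                    end = as.integer(s + size)))
      }
    }
    stop("config error: cannot place SV of size ", size)
  }
  truth <- list()
  for (i in seq_along(ev)) {
    e <- ev[[i]]
    # inversions are allowed to span gaps; everything else must avoid them
    spot <- pick_spot(e$size, avoid_gaps = e$type != "inversion")
    tgt <- NA_integer_
    if (e$needs_target) {
      tspot <- pick_spot(2L, avoid_gaps = TRUE)  # insertion locus
      if (tspot$chrom != spot$chrom) {
        # keep translocations intra-chromosomal: retry on the origin chrom
        for (try in 1:4000) {
          s <- sample.int(chrom_len[[spot$chrom]] - 2L * margin, 1) + margin
          if (fits(spot$chrom, s, s + 2L)) {
            claim(spot$chrom, s, s + 2L)
            tspot <- list(chrom = spot$chrom, start = as.integer(s))
            break
          }
        }
        if (tspot$chrom != spot$chrom) stop("config error: no insertion locus")
      }
      tgt <- tspot$start
    }
    truth[[i]] <- tibble::tibble(
      sv_id = sprintf("sv%02d_%s", i, substr(e$type, 1, 3)),
      type = e$type, chromA = spot$chrom, startA = spot$start,
      endA = spot$end, size = e$size, target = tgt, applied = TRUE)
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(sv_id = character(), type = character(),
                   chromA = character(), startA = integer(),
                   endA = integer(), size = integer(), target = integer(),
                   applied = logical())

  # ---- build genome B chromosome by chromosome ---------------------------
  rate <- config$divergence_snp_rate
  b_seqs <- character(length(gen)); names(b_seqs) <- names(gen)
  rec <- list(); snps <- list(); blocks <- list()
  for (cn in names(gen)) {
    a <- as.character(gen[[cn]])
    evc <- truth[truth$chromA == cn, ]
    evc <- evc[order(evc$startA), ]
    ins <- list()   # insertion position -> list(seq, sv_id)
    for (j in seq_len(nrow(evc))) {
      seg <- substr(a, evc$startA[j] + 1, evc$endA[j])
      if (evc$type[j] == "duplication") {
        ins[[length(ins) + 1]] <- list(pos = evc$endA[j], seq = seg,
                                       id = evc$sv_id[j], kind = "dup_copy")
      } else if (evc$type[j] == "translocation") {
        ins[[length(ins) + 1]] <- list(pos = evc$target[j], seq = seg,
                                       id = evc$sv_id[j], kind = "tra_insert")
      }
    }
    cut <- sort(unique(c(0L, evc$startA, evc$endA,
                         vapply(ins, function(x) as.integer(x$pos),
                                integer(1)),
                         chrom_len[[cn]])))
    pieces <- character(0); b_at <- 0L
    emit <- function(seq, kind, id, a_start = NA_integer_,
                     a_end = NA_integer_) {
      pieces[[length(pieces) + 1]] <<- seq
      rec[[length(rec) + 1]] <<- tibble::tibble(
        chrom = cn, kind = kind, id = id, a_start = a_start, a_end = a_end,
        b_start = b_at, b_end = b_at + nchar(seq))
      b_at <<- b_at + nchar(seq)
    }
    for (k in seq_len(length(cut) - 1)) {
      s <- cut[k]; e <- cut[k + 1]
      # insertions registered at position s go first
      for (x in ins) if (x$pos == s) emit(x$seq, x$kind, x$id)
      if (e <= s) next
      j <- which(evc$startA < e & s < evc$endA)
      if (length(j) == 0) {
        seg <- substr(a, s + 1, e)
        # background SNPs in collinear sequence, never inside an N run
        len <- e - s
        k_snp <- stats::rbinom(1, len, rate)
        if (k_snp > 0) {
          p <- sort(sample.int(len, k_snp))
          chs <- substring(seg, p, p)
          ok <- chs != "N"
          p <- p[ok]; chs <- chs[ok]
          if (length(p)) {
            alt <- vapply(chs, function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
            sp <- strsplit(seg, "", fixed = TRUE)[[1]]
            sp[p] <- alt
            seg <- paste(sp, collapse = "")
            snps[[length(snps) + 1]] <- tibble::tibble(
              chrom = cn, posA = s + p - 1L, posB = b_at + p - 1L,
              refA = chs, altB = unname(alt))
          }
        }
        blocks[[length(blocks) + 1]] <- tibble::tibble(
          chromA = cn, startA = s, endA = e, chromB = cn,
          startB = b_at, endB = b_at + (e - s))
        emit(seg, "collinear", NA_character_, s, e)
      } else {
        jj <- j[1]
        seg <- substr(a, s + 1, e)
        tp <- evc$type[jj]
        if (tp == "deletion" || tp == "translocation") {
          rec[[length(rec) + 1]] <- tibble::tibble(
            chrom = cn, kind = paste0(tp, "_cut"), id = evc$sv_id[jj],
            a_start = s, a_end = e, b_start = b_at, b_end = b_at)
        } else if (tp == "duplication") {
          emit(seg, "dup_first", evc$sv_id[jj], s, e)
        } else if (tp == "inversion") {
          rc <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(seg)))
          emit(rc, "inversion", evc$sv_id[jj], s, e)
        }
      }
    }
    b_seqs[[cn]] <- paste(pieces, collapse = "")
  }
  rec <- dplyr::bind_rows(rec)
  snps <- if (length(snps)) dplyr::bind_rows(snps) else
    tibble::tibble(chrom = character(), posA = integer(), posB = integer(),
                   refA = character(), altB = character())
  blocks <- dplyr::bind_rows(blocks)
  genome_b <- as_genome(b_seqs)

  # ---- coordsB per event --------------------------------------------------
  coordsB <- lapply(seq_len(nrow(truth)), function(i) {
    id <- truth$sv_id[i]; tp <- truth$type[i]
    r <- rec[!is.na(rec$id) & rec$id == id, ]
    if (tp == "deletion") {
      cutrow <- r[r$kind == "deletion_cut", ]
      c(cutrow$b_start[1], cutrow$b_start[1] + 1L)
    } else if (tp == "duplication") {
      c(min(r$b_start), max(r$b_end))
    } else if (tp == "inversion") {
      c(r$b_start[r$kind == "inversion"], r$b_end[r$kind == "inversion"])
    } else {
      c(r$b_start[r$kind == "tra_insert"], r$b_end[r$kind == "tra_insert"])
    }
  })
  truth$startB <- vapply(coordsB, `[`, numeric(1), 1)
  truth$endB <- vapply(coordsB, `[`, numeric(1), 2)
  truth$chromB <- truth$chromA

  # ---- spurious calls -----------------------------------------------------
  decoys <- list()
  if (config$n_sv_decoys_gap > 0 && nrow(gaps) > 0) {
    for (d in seq_len(config$n_sv_decoys_gap)) {
      g <- gaps[sample(nrow(gaps), 1), ]
      tp <- sample(c("duplication", "translocation", "deletion"), 1)
      sz <- if (tp == "deletion") sample(2000:15000, 1) else
        sample(55000:80000, 1)
      s <- max(g$start - sample(500:2000, 1), 0L)
      decoys[[length(decoys) + 1]] <- tibble::tibble(
        sv_id = sprintf("decoy_gap%02d", d), type = tp, chromA = g$chrom,
        startA = as.integer(s), endA = as.integer(s + sz), size = sz,
        target = NA_integer_, applied = FALSE,
        startB = as.integer(s), endB = as.integer(s + sz), chromB = g$chrom)
    }
  }
  for (d in seq_len(config$n_sv_decoys_small)) {
    tp <- sample(c("duplication", "translocation", "inversion"), 1)
    cn <- names(gen)[which.max(chrom_len)]
    sz_cap <- max(chrom_len[[cn]] - 2L * margin - 10L, 2000L)
    sz <- if (tp == "inversion")
      sample(seq(min(1000000L, sz_cap %/% 2L), min(4900000L, sz_cap)), 1) else
      sample(5000:min(49000L, sz_cap), 1)
    for (try in 1:4000) {
      s <- sample.int(chrom_len[[cn]] - sz - 2L * margin, 1) + margin
      g <- gaps[gaps$chrom == cn, ]
      if (!any(s < g$end & g$start < s + sz)) break
    }
    decoys[[length(decoys) + 1]] <- tibble::tibble(
      sv_id = sprintf("decoy_small%02d", d), type = tp, chromA = cn,
      startA = as.integer(s), endA = as.integer(s + sz), size = sz,
      target = NA_integer_, applied = FALSE,
      startB = as.integer(s), endB = as.integer(s + sz), chromB = cn)
  }
  decoys <- dplyr::bind_rows(decoys)
  all_calls <- dplyr::bind_rows(truth, decoys)

  # generator-side audit: gap overlap and qualification, brute force
  gapsB <- genome_gaps(genome_b)
  overlaps <- function(cn, s, e, tab) {
    t2 <- tab[tab$chrom == cn, ]
    any(s < t2$end & t2$start < e)
  }
  all_calls$gap_overlap <- vapply(seq_len(nrow(all_calls)), function(i) {
    overlaps(all_calls$chromA[i], all_calls$startA[i], all_calls$endA[i],
             gaps) ||
      overlaps(all_calls$chromB[i], all_calls$startB[i], all_calls$endB[i],
               gapsB)
  }, logical(1))
  min_size <- c(deletion = 0, duplication = 50000, translocation = 50000,
                inversion = 5000000)
  all_calls$qualifies <- !all_calls$gap_overlap &
    all_calls$size >= min_size[all_calls$type] & all_calls$applied

  calls <- all_calls[sample(nrow(all_calls)),
                     c("sv_id", "type", "chromA", "startA", "endA",
                       "chromB", "startB", "endB", "size")]
  list(genome_b = genome_b, svs = calls, truth = all_calls, snps = snps,
       blocks = blocks)
}
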