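# Methylation metaprofiles around translation start/end sites, and windowed
# feature-density correlation.

#' Methylation metaprofile per gene class
#'
#' For each classified gene, offsets of per-cytosine methylation levels are
#' computed in transcription orientation relative to the representative
#' isoform's translation start (first base of the start codon) and
#' translation end (last base of the stop codon). Levels are averaged per
#' (class, context, anchor, 5 nt bin) over \[-flank, +flank); the per-bin
#' value is the unweighted mean of per-cytosine levels
#' (methylated/total per position), and empty bins are reported as `NA`,
#' not zero.
#'
#' @param calls methylation tibble: `chrom`, `pos` (0-based), `strand`,
#'   `context` (`CG`/`CHG`/`CHH`), `n_meth`, `n_total`
#' @param features feature tibble containing the representative isoforms
#' @param classes tibble `gene_id`, `gene_class`, `representative`
#' @param flank half-window in nt (default 500)
#' @param window bin width in nt (default 5)
#' @param anchors `"translation_start"`, `"translation_end"` or both
#' @return tibble `anchor`, `class`, `context`, `bin`, `offset_start`,
#'   `mean_level`, `n_cytosines`
#' @export
methylation_metaprofile <- function(calls, features, classes, flank = 500L,
                                    window = 5L,
                                    anchors = c("translation_start",
                                                "translation_end")) {
  anchors <- match.arg(anchors, several.ok = TRUE)
  s <- tx_summary(features)
  reps <- s[match(classes$representative, s$transcript_id), ]
  no_cds <- is.na(reps$cds_start_pos)
  if (any(no_cds)) {
    warning(sum(no_cds), " genes without CDS skipped in metaprofile")
  }
  keep <- which(!no_cds & !is.na(reps$transcript_id))
  n_bins <- as.integer(2L * flank / window)
  calls <- calls[order(calls$chrom, calls$pos), ]
  by_chrom <- split(seq_len(nrow(calls)), calls$chrom)
  level <- calls$n_meth / calls$n_total

  acc <- list()
  for (i in keep) {
    cn <- reps$chrom[i]
    idx_all <- by_chrom[[cn]]
    if (is.null(idx_all)) next
    pos <- calls$pos[idx_all]
    for (anchor in anchors) {
      a <- if (anchor == "translation_start") reps$cds_start_pos[i] else
        reps$cds_end_pos[i]
      lo <- a - flank; hi <- a + flank
      r <- findInterval(c(lo - 1L, hi), pos)
      if (r[2] <= r[1]) next
      idx <- idx_all[(r[1] + 1L):r[2]]
      off <- if (reps$strand[i] == "-") a - calls$pos[idx] else
        calls$pos[idx] - a
      inw <- off >= -flank & off < flank
      if (!any(inw)) next
      idx <- idx[inw]; off <- off[inw]
      acc[[length(acc) + 1]] <- tibble::tibble(
        anchor = anchor,
        class = classes$gene_class[i],
        context = calls$context[idx],
        bin = as.integer((off + flank) %/% window),
        level = level[idx])
    }
  }
  long <- dplyr::bind_rows(acc)
  grid <- expand.grid(anchor = anchors,
                      class = sort(unique(classes$gene_class)),
                      context = c("CG", "CHG", "CHH"),
                      bin = 0:(n_bins - 1L), stringsAsFactors = FALSE)
  agg <- long %>%
    group_by(.data$anchor, .data$class, .data$context, .data$bin) %>%
    summarise(mean_level = mean(.data$level), n_cytosines = dplyr::n(),
              .groups = "drop")
  out <- dplyr::left_join(tibble::as_tibble(grid), agg,
                          by = c("anchor", "class", "context", "bin"))
  out$n_cytosines[is.na(out$n_cytosines)] <- 0L
  out$offset_start <- out$bin * window - flank
  dplyr::arrange(out, .data$anchor, .data$class, .data$context, .data$bin)
}

#' Windowed feature density
#'
#' Tiles each chromosome with fixed-size windows and counts features by
#' their start position, so each feature is counted exactly once. The last
#' window of a chromosome may be short.
#'
#' @param intervals tibble `chrom`, `start` (0-based; `end` optional)
#' @param genome genome object or named vector of chromosome lengths
#' @param window_bp window size in bp (default 1e6)
#' @return tibble `chrom`, `win_start`, `win_end`, `count`
#' @export
window_density <- function(intervals, genome, window_bp = 1000000L) {
  lens <- if (is.numeric(genome)) genome else
    stats::setNames(Biostrings::width(as_genome(genome)),
                    names(as_genome(genome)))
  bad <- !(intervals$chrom %in% names(lens))
  if (any(bad)) stop("features on unknown chromosome: ",
                     paste(unique(intervals$chrom[bad]), collapse = ", "))
  if (any(intervals$start >= lens[intervals$chrom])) {
    stop("feature start beyond chromosome end")
  }
  out <- lapply(names(lens), function(cn) {
    n_win <- ceiling(lens[[cn]] / window_bp)
    starts <- (seq_len(n_win) - 1L) * window_bp
    cnt <- tabulate(intervals$start[intervals$chrom == cn] %/% window_bp + 1L,
                    nbins = n_win)
    tibble::tibble(chrom = cn, win_start = as.numeric(starts),
                   win_end = pmin(starts + window_bp, lens[[cn]]),
                   count = cnt)
  })
  dplyr::bind_rows(out)
}

#' Spearman correlation between two density tracks
#'
#' Both tracks must share the same windowing. Ties get average ranks
#' (standard Spearman).
#'
#' @param track_a,track_b tibbles from [window_density()]
#' @return list with `rho` and `n_windows`
#' @export
density_correlation <- function(track_a, track_b) {
  if (nrow(track_a) != nrow(track_b) ||
      !all(track_a$chrom == track_b$chrom) ||
      !all(track_a$win_start == track_b$win_start)) {
    stop("tracks have different windowing")
  }
  if (nrow(track_a) < 3) stop("need at least 3 windows")
  list(rho = stats::cor(track_a$count, track_b$count, method = "spearman"),
       n_windows = nrow(track_a))
}
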