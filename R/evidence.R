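# Per-transcript support evidence from CAGE, RNA-Seq and homology inputs.

#' Associate CAGE tag clusters with genes
#'
#' The association window of a transcript is \[CDS start - 3000, CDS start +
#' 10\] in transcription orientation, both bounds inclusive. A cluster whose
#' summit falls in windows of transcripts from exactly one gene is assigned
#' to that gene and all its in-window isoforms are flagged as
#' CAGE-supported. A summit hitting windows of two or more genes is assigned
#' to the gene with the nearest CDS start; an exact distance tie leaves the
#' cluster unassigned. One cluster is never assigned to more than one gene.
#'
#' @param clusters tibble with `chrom`, `summit` (and `name`); see
#'   [read_cage_bed()]
#' @param features feature tibble
#' @param upstream,downstream window extent in nt (defaults 3000 and 10)
#' @return list with `assignment` (per-cluster tibble: `name`, `gene_id`,
#'   `n_genes_in_window`, `status`) and `flags` (per-transcript tibble:
#'   `transcript_id`, `cage_supported`)
#' @export
associate_cage <- function(clusters, features, upstream = 3000L,
                           downstream = 10L) {
  s <- tx_summary(features)
  no_cds <- is.na(s$cds_start_pos)
  if (any(no_cds)) {
    warning(sum(no_cds), " transcripts without CDS excluded from CAGE ",
            "association")
    s <- s[!no_cds, ]
  }
  win_lo <- ifelse(s$strand == "-", s$cds_start_pos - downstream,
                   s$cds_start_pos - upstream)
  win_hi <- ifelse(s$strand == "-", s$cds_start_pos + upstream,
                   s$cds_start_pos + downstream)
  nm <- clusters$name %||% paste0("cage_", seq_len(nrow(clusters)))
  assignment <- vector("list", nrow(clusters))
  supported <- character(0)
  for (i in seq_len(nrow(clusters))) {
    hit <- which(s$chrom == clusters$chrom[i] &
                   win_lo <= clusters$summit[i] &
                   clusters$summit[i] <= win_hi)
    gs <- unique(s$gene_id[hit])
    status <- "unassigned"; gene <- NA_character_
    if (length(gs) == 1) {
      gene <- gs; status <- "assigned"
    } else if (length(gs) >= 2) {
      dmin <- vapply(gs, function(g) {
        min(abs(clusters$summit[i] -
                  s$cds_start_pos[hit][s$gene_id[hit] == g]))
      }, numeric(1))
      best <- which(dmin == min(dmin))
      if (length(best) == 1) {
        gene <- gs[best]; status <- "assigned_nearest"
      } else {
        status <- "ambiguous_tie"
      }
    }
    if (!is.na(gene)) {
      supported <- c(supported, s$transcript_id[hit][s$gene_id[hit] == gene])
    }
    assignment[[i]] <- tibble::tibble(
      name = nm[i], gene_id = gene, n_genes_in_window = length(gs),
      status = status)
  }
  flags <- tibble::tibble(
    transcript_id = s$transcript_id,
    cage_supported = s$transcript_id %in% supported)
  list(assignment = dplyr::bind_rows(assignment), flags = flags)
}

#' RNA-Seq expression support from a TPM matrix
#'
#' A transcript is supported when its TPM reaches `tpm_threshold` in at
#' least one tissue (threshold inclusive).
#'
#' @param expression tibble: `transcript_id` plus one numeric column per
#'   tissue
#' @param tpm_threshold presence threshold in TPM (default 1)
#' @return tibble `transcript_id`, `rnaseq_supported`, `n_tissues_expressed`,
#'   `max_tpm`
#' @export
rnaseq_support <- function(expression, tpm_threshold = 1) {
  m <- as.matrix(expression[, setdiff(names(expression), "transcript_id")])
  if (any(m < 0)) stop("negative expression values")
  tibble::tibble(
    transcript_id = expression$transcript_id,
    rnaseq_supported = apply(m, 1, function(r) any(r >= tpm_threshold)),
    n_tissues_expressed = apply(m, 1, function(r) sum(r >= tpm_threshold)),
    max_tpm = apply(m, 1, max))
}

#' Homology support from a hit table
#'
#' A transcript is supported when it has at least one hit with query
#' coverage >= `coverage_min` percent and e-value <= `evalue_max` (both
#' bounds inclusive); `best_evalue` is the minimum e-value among qualifying
#' hits.
#'
#' @param hits tibble with `query`, `qcov` (percent), `evalue`
#' @param transcripts character vector of transcript ids to report on
#' @param coverage_min,evalue_max thresholds (defaults 50 and 1e-5)
#' @return tibble `transcript_id`, `blast_supported`, `best_evalue`
#' @export
blast_support <- function(hits, transcripts, coverage_min = 50,
                          evalue_max = 1e-5) {
  if (nrow(hits) > 0 && (any(hits$qcov < 0) || any(hits$qcov > 100))) {
    stop("query coverage outside [0, 100]")
  }
  q <- hits[hits$qcov >= coverage_min & hits$evalue <= evalue_max, ]
  best <- stats::aggregate(evalue ~ query, data = q, FUN = min)
  idx <- match(transcripts, best$query)
  tibble::tibble(
    transcript_id = transcripts,
    blast_supported = !is.na(idx),
    best_evalue = best$evalue[idx])
}

#' Assemble per-transcript evidence bundles
#'
#' Joins the three support computations with CDS length and prediction
#' order into the table consumed by classification and representative
#' selection.
#'
#' @param features feature tibble
#' @param cage result of [associate_cage()]
#' @param rnaseq result of [rnaseq_support()]
#' @param blast result of [blast_support()]
#' @param prediction_order optional tibble `transcript_id`,
#'   `prediction_order`; defaults to order of appearance within each gene
#' @return evidence tibble, one row per transcript
#' @export
build_evidence <- function(features, cage, rnaseq, blast,
                           prediction_order = NULL) {
  s <- tx_summary(features)
  ev <- tibble::tibble(transcript_id = s$transcript_id, gene_id = s$gene_id)
  cf <- cage$flags
  ev$cage_supported <- cf$cage_supported[match(ev$transcript_id,
                                               cf$transcript_id)]
  ev$cage_supported[is.na(ev$cage_supported)] <- FALSE
  i <- match(ev$transcript_id, rnaseq$transcript_id)
  ev$rnaseq_supported <- ifelse(is.na(i), FALSE, rnaseq$rnaseq_supported[i])
  ev$n_tissues_expressed <- ifelse(is.na(i), 0L,
                                   rnaseq$n_tissues_expressed[i])
  ev$max_tpm <- ifelse(is.na(i), 0, rnaseq$max_tpm[i])
  j <- match(ev$transcript_id, blast$transcript_id)
  ev$blast_supported <- ifelse(is.na(j), FALSE, blast$blast_supported[j])
  ev$best_evalue <- ifelse(is.na(j), NA_real_, blast$best_evalue[j])
  ev$cds_length <- s$cds_len
  if (is.null(prediction_order)) {
    ev <- ev %>% group_by(.data$gene_id) %>%
      mutate(prediction_order = seq_len(dplyr::n())) %>% ungroup()
  } else {
    k <- match(ev$transcript_id, prediction_order$transcript_id)
    ev$prediction_order <- prediction_order$prediction_order[k]
  }
  ev
}
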