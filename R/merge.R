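# Consolidation of two gene-prediction sets.
#
# Rule 1: a transcript present in both sets with the same transcript start
# and stop and the same full CDS coordinate list is kept once, from set B.
# Rule 2: same start/stop but different exon boundaries -> both retained as
# isoforms of one gene. Everything else passes through, and gene grouping is
# recomputed from coordinates.

#' Merge two gene-prediction sets by coordinate rules
#'
#' @param setA,setB feature tibbles (see [tx_tbl()]); set B is the
#'   kept-on-identity set
#' @return list with `merged` (feature tibble with recomputed `gene_id`) and
#'   `report` (a `merge_report` list; see Details)
#' @details The report carries `n_input_A`, `n_input_B`,
#'   `n_collapsed_identical`, `n_isoforms_added`, `n_lncrna_removed`,
#'   `n_proximity_flagged`, `n_removed_no_junction_support` and a
#'   `provenance` tibble with one row per input transcript and its fate.
#'   The count identity
#'   `n_output = n_input_A + n_input_B - n_collapsed_identical` holds on
#'   return (the lncRNA and proximity counters are filled by the later
#'   stages, which update the same report structure).
#' @export
merge_predictions <- function(setA, setB) {
  for (s in list(setA, setB)) if (nrow(s) > 0) validate_tx(s)
  sA <- if (nrow(setA)) tx_summary(setA) else NULL
  sB <- if (nrow(setB)) tx_summary(setB) else NULL
  if (!is.null(sA) && anyDuplicated(sA$transcript_id)) {
    stop("duplicate transcript_ids within set A")
  }
  if (!is.null(sB) && anyDuplicated(sB$transcript_id)) {
    stop("duplicate transcript_ids within set B")
  }
  if (!is.null(sA) && !is.null(sB) &&
      length(intersect(sA$transcript_id, sB$transcript_id))) {
    stop("transcript_ids shared across sets")
  }

  span_key <- function(s) paste(s$chrom, s$strand, s$tx_start, s$tx_end)
  full_key <- function(s) paste(span_key(s), s$cds_key)

  collapsed <- character(0); collapsed_into <- character(0)
  isoform_added <- character(0)
  if (!is.null(sA) && !is.null(sB)) {
    kA <- full_key(sA); kB <- full_key(sB)
    for (i in seq_len(nrow(sA))) {
      hits <- which(kB == kA[i])
      if (length(hits)) {
        # tie on several identical set-B transcripts: keep the
        # lexicographically smallest id (determinism)
        keep <- hits[order(sB$transcript_id[hits])][1]
        collapsed <- c(collapsed, sA$transcript_id[i])
        collapsed_into <- c(collapsed_into, sB$transcript_id[keep])
      }
    }
    spA <- span_key(sA); spB <- span_key(sB)
    same_span_only <- sA$transcript_id[spA %in% spB & !(full_key(sA) %in% kB)]
    isoform_added <- same_span_only
  }

  keepA <- if (nrow(setA)) setA[!(setA$transcript_id %in% collapsed), ] else setA
  merged <- dplyr::bind_rows(keepA, setB)
  merged <- regroup_genes(merged)

  prov <- dplyr::bind_rows(
    if (!is.null(sA)) tibble::tibble(
      transcript_id = sA$transcript_id, from_set = "setA",
      action = dplyr::case_when(
        sA$transcript_id %in% collapsed ~ "collapsed",
        sA$transcript_id %in% isoform_added ~ "isoform_added",
        TRUE ~ "passed"),
      collapsed_into = collapsed_into[match(sA$transcript_id, collapsed)]),
    if (!is.null(sB)) tibble::tibble(
      transcript_id = sB$transcript_id, from_set = "setB", action = "passed",
      collapsed_into = NA_character_))

  report <- list(
    n_input_A = if (is.null(sA)) 0L else nrow(sA),
    n_input_B = if (is.null(sB)) 0L else nrow(sB),
    n_collapsed_identical = length(collapsed),
    n_isoforms_added = length(isoform_added),
    n_lncrna_removed = 0L,
    n_proximity_flagged = 0L,
    n_removed_no_junction_support = 0L,
    provenance = prov)
  class(report) <- "merge_report"
  n_out <- length(unique(merged$transcript_id))
  stopifnot(n_out == report$n_input_A + report$n_input_B -
              report$n_collapsed_identical)
  list(merged = merged, report = report)
}

#' Recompute gene grouping from transcript coordinates
#'
#' Transcripts are grouped under one gene when they share an identical span
#' on the same strand, or overlap on the same strand with at least 1 bp of
#' shared CDS. The merged `gene_id` is derived from the lexicographically
#' smallest member transcript id.
#'
#' @param features feature tibble
#' @return feature tibble with rewritten `gene_id`
#' @export
regroup_genes <- function(features) {
  if (nrow(features) == 0) return(features)
  s <- tx_summary(features)
  n <- nrow(s)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  # candidate pairs via span overlap on the same strand
  gr <- GenomicRanges::GRanges(s$chrom,
                               IRanges::IRanges(s$tx_start + 1L, s$tx_end),
                               strand = s$strand)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  cds_ranges <- lapply(strsplit(s$cds_key, ";", fixed = TRUE), function(k) {
    if (length(k) == 0 || identical(k, "")) return(NULL)
    m <- do.call(rbind, strsplit(k, ":", fixed = TRUE))
    cbind(as.integer(m[, 1]), as.integer(m[, 2]))
  })
  cds_overlap <- function(i, j) {
    a <- cds_ranges[[i]]; b <- cds_ranges[[j]]
    if (is.null(a) || is.null(b)) return(FALSE)
    for (x in seq_len(nrow(a))) {
      if (any(a[x, 1] < b[, 2] & b[, 1] < a[x, 2])) return(TRUE)
    }
    FALSE
  }
  same_span <- function(i, j) {
    s$tx_start[i] == s$tx_start[j] && s$tx_end[i] == s$tx_end[j]
  }
  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]; j <- S4Vectors::subjectHits(hits)[h]
    if (same_span(i, j) || cds_overlap(i, j)) union2(i, j)
  }
  root <- vapply(seq_len(n), find, integer(1))
  gid <- vapply(split(s$transcript_id, root), function(ids)
    paste0("gene:", min(ids)), character(1))[as.character(root)]
  features$gene_id <- unname(gid[match(features$transcript_id,
                                       s$transcript_id)])
  features
}

#' Remove candidate lncRNAs by coding-potential/homology consensus
#'
#' A transcript is removed as a candidate lncRNA iff at least one of the two
#' coding-potential callers says non-coding AND it has no homology hit at
#' e-value <= `evalue_max`. A transcript absent from `coding_calls` counts as
#' coding.
#'
#' @param features feature tibble
#' @param coding_calls tibble `transcript_id`, `caller`, `verdict`
#'   (`"coding"`/`"noncoding"`)
#' @param homology_hits tibble with `query` and `evalue` columns
#' @param evalue_max homology significance cutoff (default 1e-5)
#' @param report optional `merge_report` to update
#' @return list `kept`, `removed` (feature tibbles), `report`
#' @export
filter_lncrna <- function(features, coding_calls, homology_hits,
                          evalue_max = 1e-5, report = NULL) {
  ids <- unique(features$transcript_id)
  unknown <- setdiff(unique(c(coding_calls$transcript_id,
                              homology_hits$query)), ids)
  if (length(unknown)) {
    warning(length(unknown), " transcripts in evidence tables not in the ",
            "annotation; ignored")
  }
  nc <- coding_calls$transcript_id[coding_calls$verdict == "noncoding"]
  has_hit <- unique(homology_hits$query[homology_hits$evalue <= evalue_max])
  removed_ids <- intersect(setdiff(nc, has_hit), ids)
  kept <- features[!(features$transcript_id %in% removed_ids), ]
  removed <- features[features$transcript_id %in% removed_ids, ]
  if (!is.null(report)) {
    report$n_lncrna_removed <- length(removed_ids)
  }
  list(kept = kept, removed = removed, removed_ids = removed_ids,
       report = report)
}

#' Review near-neighbour gene pairs and drop unsupported transcripts
#'
#' Flags a gene pair when (a) the genes are on the same strand less than
#' 150 nt apart, or (b) on opposite strands less than 300 nt apart with
#' their 3'-terminal exons overlapping by at least 1 bp. Within flagged
#' pairs, transcripts whose exon boundaries lack RNA-seq junction support
#' are removed. Distance is measured between nearest span endpoints;
#' overlapping spans have distance 0.
#'
#' @param features feature tibble (post-merge gene grouping)
#' @param junction_support tibble `transcript_id`, `supported` (logical);
#'   transcripts absent from the table count as supported
#' @param same_strand_max,opp_strand_max distance thresholds in nt
#'   (exclusive; defaults 150 and 300)
#' @param report optional `merge_report` to update
#' @return list `kept`, `removed`, `flags` (pair audit tibble), `report`
#' @export
proximity_review <- function(features, junction_support,
                             same_strand_max = 150L, opp_strand_max = 300L,
                             report = NULL) {
  s <- tx_summary(features)
  genes <- s %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$tx_start), end = max(.data$tx_end),
              .groups = "drop")
  # 3'-terminal exon per transcript (genomically last for +, first for -)
  ex <- features[features$type == "exon", ]
  ex3 <- ex %>%
    group_by(.data$transcript_id) %>%
    summarise(gene_id = first(.data$gene_id),
              e3_start = ifelse(first(.data$strand) == "-",
                                min(.data$start),
                                .data$start[which.max(.data$end)][1]),
              e3_end = ifelse(first(.data$strand) == "-",
                              .data$end[which.min(.data$start)][1],
                              max(.data$end)),
              .groups = "drop")
  flags <- list()
  for (cn in unique(genes$chrom)) {
    g <- genes[genes$chrom == cn, ]
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    idx <- utils::combn(nrow(g), 2)
    d <- pmax(0L, pmax(g$start[idx[2, ]], g$start[idx[1, ]]) -
                pmin(g$end[idx[1, ]], g$end[idx[2, ]]))
    same <- g$strand[idx[1, ]] == g$strand[idx[2, ]]
    cand_a <- which(same & d < same_strand_max)
    cand_b <- which(!same & d < opp_strand_max)
    for (k in cand_a) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        gene1 = g$gene_id[idx[1, k]], gene2 = g$gene_id[idx[2, k]],
        rule = "same_strand_lt150", distance = d[k])
    }
    for (k in cand_b) {
      g1 <- g$gene_id[idx[1, k]]; g2 <- g$gene_id[idx[2, k]]
      e1 <- ex3[ex3$gene_id == g1, ]; e2 <- ex3[ex3$gene_id == g2, ]
      ov <- FALSE
      for (x in seq_len(nrow(e1))) {
        if (any(e1$e3_start[x] < e2$e3_end & e2$e3_start < e1$e3_end[x])) {
          ov <- TRUE; break
        }
      }
      if (ov) {
        flags[[length(flags) + 1]] <- tibble::tibble(
          gene1 = g1, gene2 = g2, rule = "opp_strand_3p_overlap",
          distance = d[k])
      }
    }
  }
  flags <- if (length(flags)) dplyr::bind_rows(flags) else
    tibble::tibble(gene1 = character(), gene2 = character(),
                   rule = character(), distance = integer())
  flagged_genes <- unique(c(flags$gene1, flags$gene2))
  sup <- junction_support$supported[match(s$transcript_id,
                                          junction_support$transcript_id)]
  sup[is.na(sup)] <- TRUE
  removed_ids <- s$transcript_id[s$gene_id %in% flagged_genes & !sup]
  kept <- features[!(features$transcript_id %in% removed_ids), ]
  removed <- features[features$transcript_id %in% removed_ids, ]
  if (!is.null(report)) {
    report$n_proximity_flagged <- nrow(flags)
    report$n_removed_no_junction_support <- length(removed_ids)
  }
  list(kept = kept, removed = removed, removed_ids = removed_ids,
       flags = flags, report = report)
}
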