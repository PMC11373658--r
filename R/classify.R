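# Six-class evidence classification and representative-isoform selection.
#
# With support booleans (C = CAGE, R = RNA-Seq, B = homology):
#   N1: C & R & B          N2: C & exactly one of {R, B}
#   N3: !C & R & B         N4: exactly one of {C, R}, no B
#   N5: B only             N6: nothing
# The "either"/"only" wordings are read exclusively, which makes the eight
# (C,R,B) combinations a partition with no gaps or overlaps.

#' Map evidence booleans to a gene class
#'
#' @param cage,rnaseq,blast logical vectors (recycled to common length)
#' @return character vector of classes `"N1"`..`"N6"`
#' @export
axes_class <- function(cage, rnaseq, blast) {
  n <- max(length(cage), length(rnaseq), length(blast))
  C <- rep_len(as.logical(cage), n)
  R <- rep_len(as.logical(rnaseq), n)
  B <- rep_len(as.logical(blast), n)
  dplyr::case_when(
    C & R & B ~ "N1",
    C & xor(R, B) ~ "N2",
    !C & R & B ~ "N3",
    xor(C, R) & !B ~ "N4",
    !C & !R & B ~ "N5",
    TRUE ~ "N6")
}

#' Classify gene models from per-transcript evidence
#'
#' Gene-level support on each axis is the OR over the gene's isoforms. A
#' gene with no evidence rows is classified with all-false axes and a
#' warning.
#'
#' @param features feature tibble
#' @param evidence evidence tibble from [build_evidence()]
#' @return tibble `gene_id`, `cage`, `rnaseq`, `blast`, `gene_class`
#' @export
classify_gene_models <- function(features, evidence) {
  s <- tx_summary(features)
  miss <- setdiff(s$transcript_id, evidence$transcript_id)
  if (length(miss)) {
    warning(length(miss), " transcripts without evidence rows treated as ",
            "unsupported")
  }
  i <- match(s$transcript_id, evidence$transcript_id)
  ax <- tibble::tibble(
    gene_id = s$gene_id,
    cage = ifelse(is.na(i), FALSE, evidence$cage_supported[i]),
    rnaseq = ifelse(is.na(i), FALSE, evidence$rnaseq_supported[i]),
    blast = ifelse(is.na(i), FALSE, evidence$blast_supported[i]))
  g <- ax %>% group_by(.data$gene_id) %>%
    summarise(cage = any(.data$cage), rnaseq = any(.data$rnaseq),
              blast = any(.data$blast), .groups = "drop")
  g$gene_class <- axes_class(g$cage, g$rnaseq, g$blast)
  g
}

#' Select the representative isoform of each gene
#'
#' Strict lexicographic cascade: (1) best per-isoform class, (2) best
#' (smallest) homology e-value with absent ranking worst, (3) most tissues
#' expressed, (4) highest TPM, (5) longest CDS, (6) first predicted model.
#' A later criterion is consulted only on an exact tie of all earlier ones.
#'
#' @param evidence evidence tibble from [build_evidence()]
#' @return tibble `gene_id`, `representative` (transcript id), `decided_by`
#'   (index of the first criterion that separated the top candidates;
#'   0 for single-isoform genes)
#' @export
select_representative <- function(evidence) {
  ev <- evidence
  ev$iso_class <- axes_class(ev$cage_supported, ev$rnaseq_supported,
                             ev$blast_supported)
  ev$class_rank <- as.integer(substring(ev$iso_class, 2))
  ev$evalue_rank <- ifelse(is.na(ev$best_evalue), Inf, ev$best_evalue)
  pick <- function(d) {
    if (nrow(d) == 1) {
      return(tibble::tibble(gene_id = d$gene_id[1],
                            representative = d$transcript_id[1],
                            decided_by = 0L))
    }
    crit <- list(d$class_rank, d$evalue_rank, -d$n_tissues_expressed,
                 -d$max_tpm, -d$cds_length, d$prediction_order)
    alive <- rep(TRUE, nrow(d)); decided <- 6L
    for (k in seq_along(crit)) {
      v <- crit[[k]][alive]
      if (length(unique(v)) > 1) {
        keep <- crit[[k]] == min(v) & alive
        if (sum(keep) < sum(alive)) decided <- min(decided, k)
        alive <- keep
        if (sum(alive) == 1) {
          return(tibble::tibble(gene_id = d$gene_id[1],
                                representative = d$transcript_id[alive][1],
                                decided_by = as.integer(k)))
        }
      }
    }
    tibble::tibble(gene_id = d$gene_id[1],
                   representative = d$transcript_id[alive][
                     which.min(d$prediction_order[alive])],
                   decided_by = 6L)
  }
  dplyr::bind_rows(lapply(split(ev, ev$gene_id), pick))
}

#' Summarise a gene-model classification
#'
#' Accepts either a classification tibble (with `gene_class`) or a named
#' count vector over N1..N6. `percent_expression_supported` is the share of
#' genes in N1-N4 (the classes with CAGE and/or RNA-Seq evidence), as a
#' percentage rounded half-up to one decimal.
#'
#' @param classification tibble with a `gene_class` column, or named counts
#' @return list with `counts` (named, N1..N6), `n_genes_total`,
#'   `percent_expression_supported`
#' @export
summarize_classes <- function(classification) {
  counts <- if (is.numeric(classification)) {
    cl <- stats::setNames(rep(0, 6), paste0("N", 1:6))
    cl[names(classification)] <- classification
    cl
  } else {
    if (nrow(classification) == 0) stop("empty classification")
    tab <- table(factor(classification$gene_class, paste0("N", 1:6)))
    stats::setNames(as.numeric(tab), names(tab))
  }
  total <- sum(counts)
  if (total == 0) stop("empty classification")
  expressed <- sum(counts[c("N1", "N2", "N3", "N4")])
  list(counts = counts, n_genes_total = total,
       percent_expression_supported = percent_of(expressed, total))
}
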