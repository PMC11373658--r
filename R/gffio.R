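#' @importFrom dplyr %>% arrange group_by summarise ungroup mutate filter
#'   select distinct left_join bind_rows n first last
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Genome sequences
# ---------------------------------------------------------------------------

#' Coerce to an internal genome object
#'
#' A genome is a named [Biostrings::DNAStringSet] restricted to the alphabet
#' A, C, G, T, N. Lower-case letters are upper-cased; IUPAC ambiguity codes
#' other than N are mapped to N with a warning (the downstream model only
#' needs a gap / non-gap distinction).
#'
#' @param x named character vector or `DNAStringSet`
#' @return `DNAStringSet` with unique names and upper-case A/C/G/T/N
#' @export
as_genome <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("genome sequences must be named")
    }
    x <- Biostrings::DNAStringSet(toupper(x))
  } else if (methods::is(x, "DNAStringSet")) {
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  } else {
    stop("cannot coerce object of class ", class(x)[1], " to a genome")
  }
  if (anyDuplicated(names(x))) stop("chromosome names must be unique")
  if (any(Biostrings::width(x) == 0)) stop("genome sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(x, baseOnly = FALSE, collapse = TRUE)
  bad <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (bad > 0) {
    warning(bad, " non-ACGTN letters mapped to N")
    seqs <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", as.character(x))
    x <- Biostrings::DNAStringSet(seqs)
  }
  x
}

#' Read a genome from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record)
#' @return genome `DNAStringSet` (see [as_genome()])
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Write a genome to FASTA
#'
#' @param genome genome object
#' @param path output file
#' @param width line width
#' @export
write_fasta <- function(genome, path, width = 70) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = width)
  invisible(path)
}

#' Maximal N-runs (assembly gaps) of a genome
#'
#' @param genome genome object
#' @return tibble with `chrom`, `start`, `end` (0-based half-open)
#' @export
genome_gaps <- function(genome) {
  genome <- as_genome(genome)
  out <- lapply(seq_along(genome), function(i) {
    r <- IRanges::reduce(methods::as(
      Biostrings::matchPattern("N", genome[[i]]), "IRanges"))
    if (length(r) == 0) return(NULL)
    tibble(chrom = names(genome)[i],
           start = BiocGenerics::start(r) - 1L,
           end = BiocGenerics::end(r))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
  }
  out
}

#' Assembly summary statistics
#'
#' Computes the usual per-assembly summary: scaffold count, total bases, GC
#' content over non-N bases, gap (N) content, length extremes, mean length as
#' the floored exact ratio, and N50/N90 (the length L such that scaffolds of
#' length >= L cover at least 50% / 90% of the total bases). Percentages are
#' rounded half-up to one decimal, matching how such tables are printed.
#'
#' @param genome genome object
#' @return one-row tibble with columns `n_scaffolds`, `total_bases`,
#'   `gc_percent`, `gap_percent`, `max_len`, `min_len`, `mean_len`, `n50`,
#'   `n90`
#' @export
assembly_stats <- function(genome) {
  genome <- as_genome(genome)
  if (length(genome) == 0) stop("empty genome")
  len <- Biostrings::width(genome)
  total <- sum(as.numeric(len))
  freq <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
  n_n <- freq[["N"]]
  gc <- (freq[["G"]] + freq[["C"]]) / (total - n_n) * 100
  tibble(
    n_scaffolds = length(genome),
    total_bases = total,
    gc_percent = round_half_up(gc, 1),
    gap_percent = round_half_up(100 * n_n / total, 1),
    max_len = max(len),
    min_len = min(len),
    mean_len = floor(total / length(genome)),
    n50 = nxx_length(len, 0.5),
    n90 = nxx_length(len, 0.9)
  )
}

# N50-style statistic: smallest length whose descending cumulative sum first
# reaches `frac` of the total.
nxx_length <- function(lengths, frac) {
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(as.numeric(s)) >= frac * sum(as.numeric(s)))[1]
  s[i]
}

# ---------------------------------------------------------------------------
# Transcript feature tables
# ---------------------------------------------------------------------------

#' Construct a transcript feature table
#'
#' The package's core annotation container: a tidy tibble with one row per
#' exon or CDS interval. Coordinates are 0-based half-open; GFF3 (1-based
#' closed) and BED are converted at the I/O boundary.
#'
#' @param chrom,start,end,strand interval columns (`strand` in `+`, `-`, `.`)
#' @param type `"exon"` or `"CDS"`
#' @param transcript_id,gene_id identifiers
#' @param source prediction set of origin: `"setA"`, `"setB"` or `"merged"`
#' @return validated feature tibble
#' @export
tx_tbl <- function(chrom, start, end, strand, type, transcript_id, gene_id,
                   source = "setA") {
  f <- tibble(chrom = as.character(chrom), start = as.integer(start),
              end = as.integer(end), strand = as.character(strand),
              type = as.character(type),
              transcript_id = as.character(transcript_id),
              gene_id = as.character(gene_id),
              source = as.character(source))
  validate_tx(f)
  f
}

#' Validate a transcript feature table
#'
#' Checks the structural invariants: known feature types, positive-width
#' intervals, per-transcript uniform chromosome and strand, non-overlapping
#' sorted exons, and every CDS interval contained in some exon.
#'
#' @param features feature tibble
#' @return the input, invisibly
#' @export
validate_tx <- function(features) {
  req <- c("chrom", "start", "end", "strand", "type", "transcript_id",
           "gene_id", "source")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (!all(features$type %in% c("exon", "CDS"))) {
    stop("feature types must be 'exon' or 'CDS'")
  }
  if (any(features$end <= features$start)) stop("intervals must satisfy end > start")
  if (!all(features$strand %in% c("+", "-", "."))) stop("invalid strand")
  split_tx <- split(features, features$transcript_id)
  for (tx in split_tx) {
    if (length(unique(tx$chrom)) != 1 || length(unique(tx$strand)) != 1) {
      stop("transcript ", tx$transcript_id[1],
           ": mixed chromosome or strand across intervals")
    }
    ex <- tx[tx$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) == 0) stop("transcript ", tx$transcript_id[1], " has no exons")
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("transcript ", tx$transcript_id[1], ": overlapping exons")
    }
    cds <- tx[tx$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 0) {
      ok <- vapply(seq_len(nrow(cds)), function(i) {
        any(ex$start <= cds$start[i] & cds$end[i] <= ex$end)
      }, logical(1))
      if (!all(ok)) {
        stop("transcript ", tx$transcript_id[1], ": CDS outside exon")
      }
    }
  }
  invisible(features)
}

#' Per-transcript summary of a feature table
#'
#' @param features feature tibble
#' @return tibble with one row per transcript: span endpoints, exon/CDS
#'   coordinate keys, CDS length, and the strand-aware translation start
#'   (`cds_start_pos`, first base of the start codon, 0-based) and
#'   translation end (`cds_end_pos`, last base of the stop codon)
#' @export
tx_summary <- function(features) {
  features %>%
    arrange(.data$transcript_id, .data$type, .data$start) %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      source = first(.data$source),
      tx_start = min(.data$start[.data$type == "exon"]),
      tx_end = max(.data$end[.data$type == "exon"]),
      n_exons = sum(.data$type == "exon"),
      exon_key = paste(.data$start[.data$type == "exon"],
                       .data$end[.data$type == "exon"],
                       sep = ":", collapse = ";"),
      cds_key = paste(.data$start[.data$type == "CDS"],
                      .data$end[.data$type == "CDS"],
                      sep = ":", collapse = ";"),
      cds_len = sum((.data$end - .data$start)[.data$type == "CDS"]),
      cds_min = if (any(.data$type == "CDS"))
        min(.data$start[.data$type == "CDS"]) else NA_integer_,
      cds_max = if (any(.data$type == "CDS"))
        max(.data$end[.data$type == "CDS"]) else NA_integer_,
      .groups = "drop"
    ) %>%
    mutate(
      cds_start_pos = ifelse(.data$strand == "-", .data$cds_max - 1L, .data$cds_min),
      cds_end_pos = ifelse(.data$strand == "-", .data$cds_min, .data$cds_max - 1L)
    ) %>%
    select(-"cds_min", -"cds_max")
}

# ---------------------------------------------------------------------------
# GFF3 I/O (rtracklayer-backed)
# ---------------------------------------------------------------------------

#' Read transcripts from GFF3
#'
#' Expects the usual gene/mRNA/exon/CDS hierarchy with `Parent` attributes.
#' Coordinates are converted to the internal 0-based half-open convention.
#' Unknown feature types are skipped with a warning; an exon or CDS whose
#' parent is not an mRNA in the file is a format error.
#'
#' @param path GFF3 file
#' @return feature tibble (see [tx_tbl()])
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  known <- c("gene", "mRNA", "exon", "CDS")
  if (any(!type %in% known)) {
    warning("ignoring ", sum(!type %in% known), " features of unknown type: ",
            paste(unique(type[!type %in% known]), collapse = ", "))
  }
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrna <- which(type == "mRNA")
  gene <- which(type == "gene")
  mrna_ids <- ids[mrna]
  tx_gene <- parents[mrna]
  names(tx_gene) <- mrna_ids
  leaf <- which(type %in% c("exon", "CDS"))
  bad <- leaf[!(parents[leaf] %in% mrna_ids)]
  if (length(bad)) {
    stop("GFF3 format error: ", type[bad[1]], " feature at ",
         GenomicRanges::seqnames(gr)[bad[1]], ":",
         BiocGenerics::start(gr)[bad[1]], " has no mRNA parent")
  }
  src <- as.character(gr$source)
  # provenance recorded in column 2 on write; anything else means external file
  src[!src %in% c("setA", "setB", "merged")] <- "setA"
  f <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[leaf],
    start = BiocGenerics::start(gr)[leaf] - 1L,
    end = BiocGenerics::end(gr)[leaf],
    strand = as.character(BiocGenerics::strand(gr))[leaf],
    type = type[leaf],
    transcript_id = parents[leaf],
    gene_id = unname(tx_gene[parents[leaf]]),
    source = src[leaf]
  ) %>% arrange(.data$transcript_id, .data$type, .data$start)
  validate_tx(f)
  f
}

#' Write transcripts to GFF3
#'
#' Emits the gene/mRNA/exon/CDS hierarchy in 1-based closed coordinates with
#' the `##gff-version 3` pragma. Provenance goes in the source column; an
#' optional `gene_class` column is recorded as an mRNA attribute.
#'
#' @param features feature tibble
#' @param path output file
#' @export
write_gff3 <- function(features, path) {
  if (nrow(features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  validate_tx(features)
  txs <- tx_summary(features)
  genes <- txs %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$tx_start), end = max(.data$tx_end),
              .groups = "drop")
  has_class <- "gene_class" %in% names(features)
  cls <- if (has_class) {
    features %>% distinct(.data$transcript_id, .data$gene_class)
  } else NULL

  mk <- function(chrom, start, end, strand, type, id, parent, source) {
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start + 1L, end = end),
      strand = strand, type = type,
      ID = id, Parent = ifelse(is.na(parent), NA_character_, parent),
      source_tag = source)
  }
  g_gr <- mk(genes$chrom, genes$start, genes$end, genes$strand, "gene",
             genes$gene_id, NA_character_, "merged")
  t_gr <- mk(txs$chrom, txs$tx_start, txs$tx_end, txs$strand, "mRNA",
             txs$transcript_id, txs$gene_id, txs$source)
  if (has_class) {
    t_gr$gene_class <- cls$gene_class[match(txs$transcript_id, cls$transcript_id)]
  }
  feat <- features %>% arrange(.data$transcript_id, .data$type, .data$start)
  f_gr <- mk(feat$chrom, feat$start, feat$end, feat$strand, feat$type,
             NA_character_, feat$transcript_id, feat$source)
  # CDS phase in transcription order
  if (any(feat$type == "CDS")) {
    phase <- rep(NA_integer_, length(f_gr))
    cds_idx <- which(feat$type == "CDS")
    for (tid in unique(feat$transcript_id[cds_idx])) {
      sel <- cds_idx[feat$transcript_id[cds_idx] == tid]
      sel <- sel[order(feat$start[sel],
                       decreasing = feat$strand[sel][1] == "-")]
      lens <- feat$end[sel] - feat$start[sel]
      phase[sel] <- c(0L, (3L - cumsum(lens)[-length(lens)] %% 3L) %% 3L)
    }
    f_gr$phase <- phase
  }
  gr <- c(g_gr, t_gr, f_gr)
  gr$source <- gr$source_tag
  gr$source_tag <- NULL
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr),
             match(as.character(gr$type), c("gene", "mRNA", "exon", "CDS")))
  rtracklayer::export(gr[o], path, format = "gff3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED I/O
# ---------------------------------------------------------------------------

#' Read CAGE tag clusters from BED6+1
#'
#' Column 7, when present, is the summit offset from the interval start; the
#' returned `summit` is an absolute 0-based position. Without a seventh
#' column the interval midpoint is used.
#'
#' @param path BED file
#' @return tibble `chrom`, `start`, `end`, `name`, `score`, `strand`, `summit`
#' @export
read_cage_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(summit_offset = "integer"))
  start0 <- BiocGenerics::start(gr) - 1L
  off <- S4Vectors::mcols(gr)$summit_offset
  if (is.null(off)) off <- (BiocGenerics::end(gr) - start0) %/% 2L
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = BiocGenerics::end(gr),
    name = gr$name %||% paste0("cage_", seq_along(gr)),
    score = as.numeric(gr$score %||% 0),
    strand = as.character(BiocGenerics::strand(gr)),
    summit = start0 + off
  )
}

#' Write CAGE tag clusters to BED6+1
#'
#' @param clusters tibble as returned by [read_cage_bed()]
#' @param path output file
#' @export
write_cage_bed <- function(clusters, path) {
  stopifnot(all(clusters$summit >= clusters$start),
            all(clusters$summit < clusters$end))
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%d",
                   clusters$chrom, clusters$start, clusters$end,
                   clusters$name, clusters$score, clusters$strand,
                   clusters$summit - clusters$start)
  writeLines(lines, path)
  invisible(path)
}

#' Write plain intervals to BED3
#'
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open)
#' @param path output file
#' @export
write_bed3 <- function(intervals, path) {
  writeLines(sprintf("%s\t%d\t%d", intervals$chrom, intervals$start,
                     intervals$end), path)
  invisible(path)
}

#' Read BED3 intervals
#'
#' @param path BED file
#' @return tibble `chrom`, `start`, `end`
#' @export
read_bed3 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1L,
         end = BiocGenerics::end(gr))
}
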