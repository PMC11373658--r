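# Interspecific structural-variant filtering and diagnostic PCR design.
#
# Primer schemes (genome A is the reference carrying the sequence that the
# other genome lacks or rearranges):
#   deletions    D1 (shared 5' flank + inside), D2 (inside + shared 3'
#                flank) amplify genome A only; the spanning pair D1F+D2R
#                amplifies genome B only (the A product exceeds the maximum
#                product size)
#   duplications U1: outward-facing pair across the tandem junction,
#                amplifies genome B only
#   translocations T1/T2: pairs straddling the two origin-locus junctions,
#                amplify genome A only
# All predictions are validated by exact-match electronic PCR.

#' Filter structural-variant calls
#'
#' Drops calls whose coordinates overlap an assembly gap in either genome,
#' then applies the size selection: inversions >= `inv_min`, duplications
#' >= `dup_min`, translocations/transpositions >= `tra_min` (thresholds
#' inclusive). Deletions have no size threshold (they feed the small-SV
#' validation track).
#'
#' @param svs tibble: `sv_id`, `type`, `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`, `size`
#' @param gaps_a,gaps_b gap tibbles (`chrom`, `start`, `end`) per genome
#' @param inv_min,dup_min,tra_min size thresholds in bp
#' @return list `kept`, `dropped` (with a `drop_reason` column)
#' @export
filter_svs <- function(svs, gaps_a, gaps_b, inv_min = 5000000,
                       dup_min = 50000, tra_min = 50000) {
  gap_hit <- function(chrom, s, e, gaps) {
    vapply(seq_along(chrom), function(i) {
      g <- gaps[gaps$chrom == chrom[i], ]
      any(s[i] < g$end & g$start < e[i])
    }, logical(1))
  }
  in_gap <- gap_hit(svs$chromA, svs$startA, svs$endA, gaps_a) |
    (!is.na(svs$startB) &
       gap_hit(svs$chromB, svs$startB, svs$endB, gaps_b))
  min_size <- c(deletion = 0, duplication = dup_min,
                translocation = tra_min, transposition = tra_min,
                inversion = inv_min)
  too_small <- svs$size < min_size[svs$type]
  reason <- dplyr::case_when(in_gap ~ "gap_overlap",
                             too_small ~ "below_size_threshold",
                             TRUE ~ NA_character_)
  dropped <- svs[!is.na(reason), ]
  dropped$drop_reason <- reason[!is.na(reason)]
  list(kept = svs[is.na(reason), ], dropped = dropped)
}

#' Species-invariant sequence mask
#'
#' Per-genome intervals free of interspecific small variants (SNPs), i.e.
#' the positions where a primer cannot be compromised by a known
#' single-base difference. For a SNP-only genome pair this equals the
#' base-identity mask of the alignment; genome-specific segments (deleted,
#' duplicated or moved sequence) are retained in their own genome's mask
#' since no small variant applies there.
#'
#' @param genome_a,genome_b genome objects
#' @param snps tibble `chrom`, `posA`, `posB` (0-based positions)
#' @return list `maskA`, `maskB`: tibbles `chrom`, `start`, `end`
#' @export
invariant_mask <- function(genome_a, genome_b, snps) {
  one <- function(genome, pos_col) {
    out <- lapply(names(genome), function(cn) {
      L <- Biostrings::width(genome)[match(cn, names(genome))]
      p <- sort(snps[[pos_col]][snps$chrom == cn])
      full <- IRanges::IRanges(1L, L)
      if (length(p)) {
        full <- BiocGenerics::setdiff(full, IRanges::IRanges(p + 1L, p + 1L))
      }
      tibble::tibble(chrom = cn, start = BiocGenerics::start(full) - 1L,
                     end = BiocGenerics::end(full))
    })
    dplyr::bind_rows(out)
  }
  list(maskA = one(as_genome(genome_a), "posA"),
       maskB = one(as_genome(genome_b), "posB"))
}

# ---------------------------------------------------------------------------
# primer placement helpers
# ---------------------------------------------------------------------------

snp_lookup <- function(snps) {
  by <- split(snps$posA, snps$chrom)
  function(chrom, s, e) {
    p <- by[[chrom]]
    !is.null(p) && any(p >= s & p < e)
  }
}

primer_seq <- function(genome, chrom, start, len, orientation) {
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, start + len)
  if (orientation == "reverse") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

count_occurrences <- function(genome, seq) {
  p <- Biostrings::DNAString(seq)
  sum(Biostrings::vcountPattern(p, genome)) +
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), genome))
}

# first placement in candidate order that is N-free, SNP-free and unique in
# genome A; candidates = vector of start positions
find_site <- function(genome_a, has_snp, chrom, candidates, len) {
  L <- Biostrings::width(genome_a)[match(chrom, names(genome_a))]
  if (is.na(L)) stop("unknown chromosome: ", chrom)
  for (p in candidates) {
    if (p < 0 || p + len > L) next
    if (has_snp(chrom, p, p + len)) next
    seq <- primer_seq(genome_a, chrom, p, len, "forward")
    if (grepl("N", seq, fixed = TRUE)) next
    if (count_occurrences(genome_a, seq) != 1L) next
    return(p)
  }
  NA_integer_
}

primer_pair <- function(name, chrom, f_start, r_start, len, genome_a,
                        expected) {
  list(name = name, chrom = chrom, primer_len = len,
       forward = list(start = f_start,
                      seq = primer_seq(genome_a, chrom, f_start, len,
                                       "forward")),
       reverse = list(start = r_start,
                      seq = primer_seq(genome_a, chrom, r_start, len,
                                       "reverse")),
       expected = expected)
}

expected_tbl <- function(a_amplifies, a_size, b_amplifies, b_size) {
  tibble::tibble(genome = c("A", "B"),
                 amplifies = c(a_amplifies, b_amplifies),
                 product_size = c(a_size, b_size))
}

design_failure <- function(reason) {
  structure(list(status = "failed", reason = reason),
            class = "primer_design")
}

# ---------------------------------------------------------------------------
# deletion scheme: D1, D2 and the spanning pair
# ---------------------------------------------------------------------------

#' Design diagnostic primers for a deletion
#'
#' The deletion is present in genome B relative to genome A (A carries the
#' sequence). D1F sits in the shared 5' flank and D1R inside the A-only
#' sequence; D2F inside the A-only sequence and D2R in the shared 3' flank;
#' both amplify genome A only. The spanning pair D1F+D2R amplifies genome B
#' only, because in genome A the product is stretched beyond `max_product`
#' by the deleted sequence — for deletions smaller than
#' `max_product - 2*search_radius` no placement can achieve that and the
#' design fails with a reason.
#'
#' @param sv one-row tibble with `chromA`, `startA`, `endA`
#' @param genome_a,genome_b genome objects
#' @param snps interspecific SNP table (`chrom`, `posA`)
#' @param primer_len primer length in nt (default 20)
#' @param search_radius how far from the junction flank primers may sit
#'   (default 1000)
#' @param max_product electronic-PCR product ceiling in bp (default 3000)
#' @return list with `status`, and on success `D1`, `D2`, `spanning` primer
#'   pairs with expected amplification patterns
#' @export
design_deletion_primers <- function(sv, genome_a, genome_b, snps,
                                    primer_len = 20L, search_radius = 1000L,
                                    max_product = 3000L) {
  has_snp <- snp_lookup(snps)
  cn <- sv$chromA; s <- sv$startA; e <- sv$endA
  size <- e - s
  inset <- 150L
  if (size < primer_len + 20L) {
    return(design_failure("deletion too small to host an internal primer"))
  }
  inset <- min(inset, size - primer_len - 5L)
  # internal primers (A-only sequence, SNP-free by definition)
  d1r <- find_site(genome_a, has_snp, cn,
                   (s + inset):(s + min(size - primer_len, inset + 200L)),
                   primer_len)
  d2f <- find_site(genome_a, has_snp, cn,
                   (e - inset - primer_len):(max(s, e - inset - 200L -
                                                   primer_len)),
                   primer_len)
  if (is.na(d1r) || is.na(d2f)) {
    return(design_failure("no usable internal primer site"))
  }
  # spanning feasibility: B product = left_ext + right_ext must be
  # amplifiable while the A product (B product + size) is not
  if (size > max_product) {
    left_target <- 200L; right_target <- 200L
  } else {
    need <- max_product - size   # B product must exceed this
    if (need >= 2L * search_radius) {
      return(design_failure(
        "deletion too small for a genome-specific spanning product"))
    }
    half <- as.integer(need / 2) + 120L
    left_target <- min(half, search_radius - 50L)
    right_target <- min(need - left_target + 240L, search_radius - 50L)
  }
  d1f <- find_site(genome_a, has_snp, cn,
                   (s - left_target - primer_len):(s - search_radius),
                   primer_len)
  if (is.na(d1f)) return(design_failure("no invariant 5' flank"))
  left_ext <- s - d1f
  lo_right <- max(max_product - size - left_ext + 1L, 180L)
  if (lo_right > search_radius) {
    return(design_failure(
      "deletion too small for a genome-specific spanning product"))
  }
  d2r <- find_site(genome_a, has_snp, cn,
                   (e + lo_right - primer_len):(e + search_radius -
                                                  primer_len),
                   primer_len)
  if (is.na(d2r)) return(design_failure("no invariant 3' flank"))
  right_ext <- d2r + primer_len - e
  span_b <- left_ext + right_ext
  span_a <- span_b + size
  if (span_b > max_product || span_a <= max_product) {
    return(design_failure(
      "deletion too small for a genome-specific spanning product"))
  }
  list(status = "ok",
       D1 = primer_pair("D1", cn, d1f, d1r, primer_len, genome_a,
                        expected_tbl(TRUE, d1r + primer_len - d1f,
                                     FALSE, NA_real_)),
       D2 = primer_pair("D2", cn, d2f, d2r, primer_len, genome_a,
                        expected_tbl(TRUE, d2r + primer_len - d2f,
                                     FALSE, NA_real_)),
       spanning = primer_pair("spanning", cn, d1f, d2r, primer_len,
                              genome_a,
                              expected_tbl(FALSE, NA_real_, TRUE, span_b)))
}

# ---------------------------------------------------------------------------
# duplication scheme: U1 across the tandem junction
# ---------------------------------------------------------------------------

#' Design the outward-facing duplication junction pair
#'
#' U1F points out of the 3' end of the duplicated region and U1R out of its
#' 5' end; the pair converges only across the junction between tandem
#' copies, so it amplifies genome B (where the duplication is) and not
#' genome A. If no junction product is found in genome B (copies not
#' tandem), the design is flagged as failed.
#'
#' @inheritParams design_deletion_primers
#' @return list with `status` and on success `U1`
#' @export
design_duplication_primers <- function(sv, genome_a, genome_b, snps,
                                       primer_len = 20L,
                                       search_radius = 1000L,
                                       max_product = 3000L) {
  has_snp <- snp_lookup(snps)
  cn <- sv$chromA; s <- sv$startA; e <- sv$endA
  if (e - s < 2L * (primer_len + 120L)) {
    return(design_failure("duplicated region too small"))
  }
  u1f <- find_site(genome_a, has_snp, cn,
                   (e - 120L - primer_len):(e - min(search_radius, e - s -
                                                      primer_len)),
                   primer_len)
  u1r <- find_site(genome_a, has_snp, cn,
                   (s + 100L):(s + min(search_radius, e - s - primer_len)),
                   primer_len)
  if (is.na(u1f) || is.na(u1r)) {
    return(design_failure("no usable primer site inside duplication"))
  }
  junction_product <- (e - u1f) + (u1r + primer_len - s)
  if (junction_product > max_product) {
    return(design_failure("junction product exceeds maximum size"))
  }
  pair <- primer_pair("U1", cn, u1f, u1r, primer_len, genome_a,
                      expected_tbl(FALSE, NA_real_, TRUE, junction_product))
  hitsB <- epcr(pair, genome_b, max_product)
  if (nrow(hitsB) == 0) {
    return(design_failure("no tandem junction in genome B"))
  }
  list(status = "ok", U1 = pair)
}

# ---------------------------------------------------------------------------
# translocation scheme: T1/T2 across the origin-locus junctions
# ---------------------------------------------------------------------------

#' Design the two translocation junction pairs
#'
#' The moved segment sits at `startA..endA` in genome A and elsewhere in
#' genome B. T1 = forward primer in the 5' flank plus reverse primer inside
#' the segment's 5' end; T2 = forward primer inside the segment's 3' end
#' plus reverse primer in the 3' flank. Both adjacencies exist only in
#' genome A, so both pairs amplify genome A and not genome B.
#'
#' @inheritParams design_deletion_primers
#' @return list with `status` and on success `T1`, `T2`
#' @export
design_translocation_primers <- function(sv, genome_a, genome_b, snps,
                                         primer_len = 20L,
                                         search_radius = 1000L,
                                         max_product = 3000L) {
  has_snp <- snp_lookup(snps)
  cn <- sv$chromA; s <- sv$startA; e <- sv$endA
  if (e - s < 2L * (primer_len + 120L)) {
    return(design_failure("translocated segment too small"))
  }
  t1f <- find_site(genome_a, has_snp, cn,
                   (s - 120L - primer_len):(s - search_radius), primer_len)
  t1r <- find_site(genome_a, has_snp, cn, (s + 120L):(s + search_radius),
                   primer_len)
  t2f <- find_site(genome_a, has_snp, cn,
                   (e - 120L - primer_len):(e - search_radius), primer_len)
  t2r <- find_site(genome_a, has_snp, cn, (e + 120L):(e + search_radius),
                   primer_len)
  if (is.na(t1f) || is.na(t1r) || is.na(t2f) || is.na(t2r)) {
    return(design_failure("no invariant site around a junction"))
  }
  p1 <- (t1r + primer_len) - t1f
  p2 <- (t2r + primer_len) - t2f
  if (p1 > max_product || p2 > max_product) {
    return(design_failure("junction products exceed maximum size"))
  }
  T1 <- primer_pair("T1", cn, t1f, t1r, primer_len, genome_a,
                    expected_tbl(TRUE, p1, FALSE, NA_real_))
  T2 <- primer_pair("T2", cn, t2f, t2r, primer_len, genome_a,
                    expected_tbl(TRUE, p2, FALSE, NA_real_))
  # a target locus closer than max_product would leave a genome-B product
  if (nrow(epcr(T1, genome_b, max_product)) > 0 ||
      nrow(epcr(T2, genome_b, max_product)) > 0) {
    return(design_failure("junction still amplifiable in genome B"))
  }
  list(status = "ok", T1 = T1, T2 = T2)
}

# ---------------------------------------------------------------------------
# electronic PCR
# ---------------------------------------------------------------------------

#' Electronic PCR by exact primer matching
#'
#' Searches both primers of a pair on both strands of a genome and reports
#' every convergent, non-overlapping placement whose product length (outer
#' primer ends inclusive) does not exceed `max_product`. A pair "amplifies"
#' a genome iff at least one product is reported.
#'
#' @param pair primer pair (from a design function, or a list with
#'   `forward$seq` and `reverse$seq`)
#' @param genome genome object
#' @param max_product product length ceiling in bp (default 3000)
#' @return tibble `chrom`, `start`, `end`, `length`, `plus_primer`
#' @export
epcr <- function(pair, genome, max_product = 3000L) {
  genome <- as_genome(genome)
  fw <- Biostrings::DNAString(pair$forward$seq)
  rv <- Biostrings::DNAString(pair$reverse$seq)
  if (length(fw) < 15L || length(rv) < 15L) stop("primers must be >= 15 nt")
  hits <- function(p) {
    m <- Biostrings::vmatchPattern(p, genome)
    out <- lapply(seq_along(m), function(i) {
      r <- m[[i]]
      if (length(r) == 0) return(NULL)
      tibble::tibble(chrom = names(genome)[i],
                     start = BiocGenerics::start(r) - 1L,
                     end = BiocGenerics::end(r))
    })
    dplyr::bind_rows(out)
  }
  products <- list()
  combos <- list(list(plus = fw, minus = rv, label = "forward"),
                 list(plus = rv, minus = fw, label = "reverse"))
  for (cb in combos) {
    ph <- hits(cb$plus)
    mh <- hits(Biostrings::reverseComplement(cb$minus))
    if (nrow(ph) == 0 || nrow(mh) == 0) next
    for (i in seq_len(nrow(ph))) {
      same <- mh[mh$chrom == ph$chrom[i], ]
      ok <- same$start >= ph$end[i] &
        (same$end - ph$start[i]) <= max_product
      if (any(ok)) {
        products[[length(products) + 1]] <- tibble::tibble(
          chrom = ph$chrom[i], start = ph$start[i],
          end = same$end[ok], length = same$end[ok] - ph$start[i],
          plus_primer = cb$label)
      }
    }
  }
  out <- dplyr::bind_rows(products)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), length = integer(),
                          plus_primer = character())
  }
  out
}

#' Design and validate primers for a filtered SV set
#'
#' Runs the type-appropriate design for every deletion, duplication and
#' translocation in `svs`, validates each successful design by electronic
#' PCR on both genomes, and reports whether the observed genome-specific
#' amplification pattern matches the expectation of the scheme.
#'
#' @param svs filtered SV tibble
#' @param genome_a,genome_b genome objects
#' @param snps interspecific SNP table
#' @param ... passed to the design functions
#' @return tibble: one row per primer pair with design status, expectation
#'   and e-PCR outcome (`pattern_ok`)
#' @export
sv_primer_panel <- function(svs, genome_a, genome_b, snps, ...) {
  rows <- list()
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    des <- switch(sv$type,
      deletion = design_deletion_primers(sv, genome_a, genome_b, snps, ...),
      duplication = design_duplication_primers(sv, genome_a, genome_b, snps,
                                               ...),
      translocation = design_translocation_primers(sv, genome_a, genome_b,
                                                   snps, ...),
      NULL)
    if (is.null(des)) next
    if (des$status != "ok") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sv_id = sv$sv_id, type = sv$type, pair = NA_character_,
        status = "failed", reason = des$reason, amplifies_a = NA,
        amplifies_b = NA, expected_a = NA, expected_b = NA,
        pattern_ok = NA)
      next
    }
    for (nmp in setdiff(names(des), "status")) {
      pair <- des[[nmp]]
      pa <- epcr(pair, genome_a)
      pb <- epcr(pair, genome_b)
      exp_a <- pair$expected$amplifies[pair$expected$genome == "A"]
      exp_b <- pair$expected$amplifies[pair$expected$genome == "B"]
      rows[[length(rows) + 1]] <- tibble::tibble(
        sv_id = sv$sv_id, type = sv$type, pair = pair$name, status = "ok",
        reason = NA_character_, amplifies_a = nrow(pa) > 0,
        amplifies_b = nrow(pb) > 0, expected_a = exp_a, expected_b = exp_b,
        pattern_ok = (nrow(pa) > 0) == exp_a && (nrow(pb) > 0) == exp_b)
    }
  }
  dplyr::bind_rows(rows)
}
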