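#' Merge two contigs on an exact terminal overlap
#'
#' Finds the longest exact suffix-of-one / prefix-of-the-other match of at
#' least `min_overlap` bases (both orderings are tried; forward orientation
#' only) and concatenates the two contigs, de-duplicating the overlap. This is
#' the operation used to join two assembly fragments of one transcript that
#' share a clean terminal overlap (15 bp by default).
#'
#' @param a,b one-row sequence tibbles (see [seq_record()]), nucleotide.
#' @param min_overlap minimum exact overlap length (default 15).
#' @return A list with elements `merged` (one-row sequence tibble, or `NULL`
#'   when no qualifying overlap exists), `overlap_len` (0 when unmerged) and
#'   `orientation` (`"a_then_b"`, `"b_then_a"`, or `NA`).
#' @examples
#' a <- seq_record("x", "AAAACCCCCCCCCCCCCCC")
#' b <- seq_record("y", "CCCCCCCCCCCCCCCGGGG")
#' merge_overlap(a, b, min_overlap = 15)$overlap_len
#' @export
merge_overlap <- function(a, b, min_overlap = 15) {
  stopifnot(is.data.frame(a), is.data.frame(b), nrow(a) == 1L, nrow(b) == 1L)
  if (a$alphabet != "nucleotide" || b$alphabet != "nucleotide") {
    stop("merge_overlap() requires nucleotide records")
  }
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  sa <- a$residues; sb <- b$residues
  best <- list(len = 0L, orientation = NA_character_)
  kmax <- min(nchar(sa), nchar(sb))
  for (k in seq(kmax, min_overlap)) {
    if (best$len) break
    if (substr(sa, nchar(sa) - k + 1L, nchar(sa)) == substr(sb, 1L, k)) {
      best <- list(len = k, orientation = "a_then_b")
    } else if (substr(sb, nchar(sb) - k + 1L, nchar(sb)) == substr(sa, 1L, k)) {
      best <- list(len = k, orientation = "b_then_a")
    }
  }
  if (best$len == 0L) {
    return(list(merged = NULL, overlap_len = 0L, orientation = NA_character_))
  }
  merged_seq <- if (best$orientation == "a_then_b") {
    paste0(sa, substr(sb, best$len + 1L, nchar(sb)))
  } else {
    paste0(sb, substr(sa, best$len + 1L, nchar(sa)))
  }
  merged <- seq_record(paste0(a$id, "/", b$id, "_merged"), merged_seq,
                       alphabet = "nucleotide")
  list(merged = merged, overlap_len = best$len, orientation = best$orientation)
}

#' Find ORFs in a contig over six frames
#'
#' Reports all ATG-initiated open reading frames of at least `min_aa` codons
#' on both strands and all three frames. Nested ORFs sharing a stop codon keep
#' only the longest (ORF-Finder convention). Minus-strand ORFs are reported in
#' forward-strand coordinates. Coordinates are 0-based half-open and include
#' the terminating stop codon when one is present (`end - start` equals
#' `3 * aa_len + 3` for stop-terminated ORFs, `3 * aa_len` when the ORF runs
#' off the contig end).
#'
#' @param contig one-row nucleotide sequence tibble.
#' @param min_aa minimum protein length in amino acids (>= 1).
#' @return A tibble with columns `contig_id`, `strand` (`"+"`/`"-"`), `frame`
#'   (0-2 on the reported strand), `start`, `end`, `aa_len`, `has_stop`,
#'   `nt` (coding sequence, start through last sense codon), `aa`; sorted by
#'   descending `aa_len`, then `start`, then `strand`.
#' @export
find_orfs <- function(contig, min_aa = 100) {
  stopifnot(is.data.frame(contig), nrow(contig) == 1L)
  if (contig$alphabet != "nucleotide") stop("find_orfs() requires a nucleotide record")
  if (min_aa < 1) stop("min_aa must be >= 1")
  L <- nchar(contig$residues)
  scan_strand <- function(s, strand) {
    out <- list()
    for (frame in 0:2) {
      n_codon <- (nchar(s) - frame) %/% 3L
      if (n_codon < 1L) next
      starts_nt <- frame + seq(1L, by = 3L, length.out = n_codon)
      codons <- substring(s, starts_nt, starts_nt + 2L)
      aa <- unname(.codon_table()[codons])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      is_atg <- codons == "ATG"
      # segment id: codons between stops (stop closes the segment it ends)
      seg <- cumsum(c(0L, utils::head(is_stop, -1L)))
      for (g in unique(seg)) {
        idx <- which(seg == g & !is_stop)
        if (!length(idx)) next
        atg <- idx[is_atg[idx]]
        if (!length(atg)) next
        first_atg <- atg[1]                      # longest ORF for this stop
        seg_all <- which(seg == g)
        stop_idx <- seg_all[is_stop[seg_all]]
        has_stop <- length(stop_idx) > 0L
        last_sense <- if (has_stop) stop_idx[1] - 1L else max(idx)
        aa_seq <- paste(aa[first_atg:last_sense], collapse = "")
        if (nchar(aa_seq) < min_aa) next
        nt_start <- frame + (first_atg - 1L) * 3L          # 0-based on s
        nt_end <- frame + last_sense * 3L + if (has_stop) 3L else 0L
        out[[length(out) + 1L]] <- tibble::tibble(
          contig_id = contig$id, strand = strand, frame = frame,
          start = nt_start, end = nt_end,
          aa_len = nchar(aa_seq), has_stop = has_stop,
          nt = substr(s, nt_start + 1L, nt_start + 3L * nchar(aa_seq)),
          aa = aa_seq
        )
      }
    }
    out
  }
  fwd <- scan_strand(contig$residues, "+")
  rev <- scan_strand(revcomp(contig$residues), "-")
  # map minus-strand coordinates (on revcomp) back to forward strand
  rev <- lapply(rev, function(o) {
    new_start <- L - o$end
    o$end <- L - o$start
    o$start <- new_start
    o
  })
  orfs <- dplyr::bind_rows(c(fwd, rev))
  if (nrow(orfs) == 0L) {
    return(tibble::tibble(
      contig_id = character(), strand = character(), frame = integer(),
      start = integer(), end = integer(), aa_len = integer(),
      has_stop = logical(), nt = character(), aa = character()
    ))
  }
  dplyr::arrange(orfs, dplyr::desc(.data$aa_len), .data$start, .data$strand)
}

#' Is an ORF a full-length family member?
#'
#' True iff the protein length falls inside the family's expected length
#' window and the ORF is terminated by a stop codon inside the contig (i.e. it
#' is not truncated by the contig end).
#'
#' @param orf a one-row tibble as returned by [find_orfs()].
#' @param len_range integer pair `c(min_aa, max_aa)`.
#' @return logical.
#' @export
is_full_length <- function(orf, len_range) {
  stopifnot(length(len_range) == 2L, len_range[1] <= len_range[2])
  isTRUE(orf$has_stop) &&
    orf$aa_len >= len_range[1] && orf$aa_len <= len_range[2]
}
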