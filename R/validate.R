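#' Classify a single-codon difference
#'
#' @param codon_a,codon_b 3-mers over A/C/G/T.
#' @return `"identical"`, `"synonymous"` (different codon, same amino acid) or
#'   `"nonsynonymous"`.
#' @examples
#' classify_snp("CTG", "CTA")
#' @export
classify_snp <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (nchar(codon_a) != 3L || nchar(codon_b) != 3L) stop("codons must be 3 nt")
  .check_alphabet(codon_a, "nucleotide"); .check_alphabet(codon_b, "nucleotide")
  if (codon_a == codon_b) return("identical")
  if (translate(codon_a) == translate(codon_b) &&
      nzchar(translate(codon_a))) "synonymous" else "nonsynonymous"
}

# round half away from zero to `digits` decimals (printed-value convention)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Compare a Sanger clone to an assembled ORF
#'
#' Aligns the clone to the assembled coding sequence with free end gaps (the
#' clone may carry UTR overhang), counts mismatch columns within the ORF
#' span, classifies each mismatch as synonymous or nonsynonymous by
#' translating both codons in the assembled reading frame, and reports
#' percent nucleotide identity over the ORF (rounded half-up to one decimal,
#' matching the printed-value convention). When the clone aligns with
#' internal frame-breaking indels the comparison is still returned, with
#' `n_indel_cols > 0` and identity computed over aligned columns.
#'
#' @param assembled_orf the assembled coding sequence: an ORF row from
#'   [find_orfs()] (its `nt` field is used) or a nucleotide string whose
#'   length is a multiple of 3.
#' @param clone_nt clone nucleotide string covering the ORF.
#' @param scheme nucleotide scheme; default [scheme_clone_validation()]
#'   (free end gaps).
#' @return A one-row tibble: `orf_len_nt`, `n_mismatch`, `n_synonymous`,
#'   `n_nonsynonymous`, `n_indel_cols`, `pct_identity`.
#' @export
compare_orfs <- function(assembled_orf, clone_nt,
                         scheme = scheme_clone_validation()) {
  orf_nt <- if (is.data.frame(assembled_orf)) assembled_orf$nt else
    toupper(assembled_orf)
  if (nchar(orf_nt) %% 3L != 0L) stop("assembled ORF length not a multiple of 3")
  al <- global_align(seq_record("assembled", orf_nt),
                     seq_record("clone", toupper(clone_nt)), scheme)$alignment
  arow <- strsplit(al$gapped[1], "")[[1]]
  crow <- strsplit(al$gapped[2], "")[[1]]
  in_orf <- arow != "-"
  # clone coverage: end gaps (UTR overhang / missing ends) are not mismatches
  clone_cols <- which(crow != "-")
  covered <- seq_along(arow) >= min(clone_cols) &
    seq_along(arow) <= max(clone_cols)
  # indel columns: gaps strictly inside the ORF span of the alignment
  orf_cols <- which(in_orf)
  span <- seq(min(orf_cols), max(orf_cols))
  n_indel_cols <- sum(arow[span] == "-") +
    sum(in_orf[span] & covered[span] & crow[span] == "-")
  orf_pos <- cumsum(in_orf)                      # 1-based ORF coordinate
  mism_cols <- which(in_orf & covered & crow != "-" & arow != crow)
  classes <- vapply(mism_cols, function(col) {
    codon_i <- (orf_pos[col] - 1L) %/% 3L        # 0-based codon index
    a_codon <- substr(orf_nt, codon_i * 3L + 1L, codon_i * 3L + 3L)
    b_codon <- a_codon
    within <- (orf_pos[col] - 1L) %% 3L + 1L
    substr(b_codon, within, within) <- crow[col]
    classify_snp(a_codon, b_codon)
  }, character(1))
  orf_len <- nchar(orf_nt)
  n_mismatch <- length(mism_cols)
  pct <- if (n_indel_cols == 0L) {
    round_half_up(100 * (orf_len - n_mismatch) / orf_len, 1)
  } else {
    denom <- sum(in_orf & covered & crow != "-") + n_indel_cols
    round_half_up(100 * (sum(in_orf & covered & crow != "-") - n_mismatch) / denom, 1)
  }
  tibble::tibble(
    orf_len_nt = orf_len,
    n_mismatch = n_mismatch,
    n_synonymous = sum(classes == "synonymous"),
    n_nonsynonymous = sum(classes == "nonsynonymous"),
    n_indel_cols = n_indel_cols,
    pct_identity = pct
  )
}
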