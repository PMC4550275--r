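#' Scoring schemes for global alignment
#'
#' A scoring scheme bundles a symmetric substitution matrix with affine gap
#' costs. Gap costs are stored as non-negative numbers and subtracted: a gap
#' run of length L costs `gap_open + L * gap_extend`. With
#' `end_gaps_free = TRUE` gaps before the first or after the last residue of
#' either sequence are free (the variant used for clone-versus-assembly
#' validation).
#'
#' `scheme_protein()` uses BLOSUM62 over the 20 amino acids plus `X`
#' (`X` scores taken from the matrix). `scheme_nucleotide()` uses
#' match/mismatch scoring with `N` neutral (0 against everything).
#' `scheme_clone_validation()` is the nucleotide scheme with free end gaps,
#' standing in for the free-end-gap similarity preset used when comparing
#' Sanger clones to assembled transcripts.
#'
#' @param gap_open,gap_extend non-negative affine gap costs.
#' @param end_gaps_free logical; are leading/trailing gaps free?
#' @param match,mismatch nucleotide match/mismatch scores.
#' @return A list of class `scoring_scheme` with elements `alphabet`,
#'   `matrix`, `matrix_name`, `gap_open`, `gap_extend`, `end_gaps_free`.
#' @export
scheme_protein <- function(gap_open = 10, gap_extend = 1, end_gaps_free = FALSE) {
  chars <- c(setdiff(.AA_CHARS, c("X", "*")), "X")
  m <- blosum62()[chars, chars]
  .new_scheme("protein", m, "BLOSUM62", gap_open, gap_extend, end_gaps_free)
}

#' @rdname scheme_protein
#' @export
scheme_nucleotide <- function(match = 5, mismatch = -4, gap_open = 10,
                              gap_extend = 1, end_gaps_free = FALSE) {
  chars <- .NT_CHARS
  m <- matrix(mismatch, 5, 5, dimnames = list(chars, chars))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  .new_scheme("nucleotide", m, sprintf("match%+d/mismatch%+d", match, mismatch),
              gap_open, gap_extend, end_gaps_free)
}

#' @rdname scheme_protein
#' @export
scheme_clone_validation <- function() {
  scheme_nucleotide(end_gaps_free = TRUE)
}

.new_scheme <- function(alphabet, m, name, gap_open, gap_extend, end_gaps_free) {
  stopifnot(isSymmetric(unname(m)), gap_open >= 0, gap_extend >= 0)
  structure(list(alphabet = alphabet, matrix = m, matrix_name = name,
                 gap_open = gap_open, gap_extend = gap_extend,
                 end_gaps_free = end_gaps_free),
            class = "scoring_scheme")
}

.seq_profile <- function(s, chars) {
  L <- nchar(s)
  prof <- matrix(0, L, length(chars), dimnames = list(NULL, chars))
  if (L == 0L) return(prof)
  cs <- strsplit(toupper(s), "")[[1]]
  cs[cs == "*"] <- "X"   # translated stops never appear, but be safe
  bad <- setdiff(unique(cs), chars)
  if (length(bad)) stop("characters outside scheme alphabet: ",
                        paste(bad, collapse = ""))
  prof[cbind(seq_len(L), match(cs, chars))] <- 1
  prof
}

.rows_profile <- function(gapped, chars) {
  L <- nchar(gapped[1])
  prof <- matrix(0, L, length(chars), dimnames = list(NULL, chars))
  for (s in gapped) {
    cs <- strsplit(toupper(s), "")[[1]]
    cs[cs == "*"] <- "X"
    keep <- cs != "-"
    idx <- match(cs[keep], chars)
    if (anyNA(idx)) stop("characters outside scheme alphabet in alignment row")
    tab <- cbind(which(keep), idx)
    for (r in seq_len(nrow(tab))) prof[tab[r, 1], tab[r, 2]] <-
        prof[tab[r, 1], tab[r, 2]] + 1
  }
  prof / length(gapped)
}

.apply_path <- function(path, rows_a, rows_b) {
  # path moves: 0 diagonal, 1 consume A (gap in B), 2 consume B (gap in A)
  split_a <- lapply(rows_a, function(s) strsplit(s, "")[[1]])
  split_b <- lapply(rows_b, function(s) strsplit(s, "")[[1]])
  n <- length(path)
  out_a <- lapply(split_a, function(x) character(n))
  out_b <- lapply(split_b, function(x) character(n))
  ia <- 0L; ib <- 0L
  for (k in seq_len(n)) {
    mv <- path[k]
    if (mv != 2L) ia <- ia + 1L
    if (mv != 1L) ib <- ib + 1L
    for (r in seq_along(out_a)) out_a[[r]][k] <-
        if (mv != 2L) split_a[[r]][ia] else "-"
    for (r in seq_along(out_b)) out_b[[r]][k] <-
        if (mv != 1L) split_b[[r]][ib] else "-"
  }
  c(vapply(out_a, paste, character(1), collapse = ""),
    vapply(out_b, paste, character(1), collapse = ""))
}

.as_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    stats::setNames(x$residues, x$id)
  } else {
    if (is.null(names(x))) names(x) <- "seq"
    x
  }
}

#' Optimal pairwise global alignment
#'
#' Needleman-Wunsch with affine gaps (Gotoh) under a [scoring
#' scheme][scheme_protein]. Traceback is deterministic with preference
#' diagonal > up (gap in `b`) > left (gap in `a`).
#'
#' @param a,b one-row sequence tibbles (see [seq_record()]) or named strings.
#' @param scheme a `scoring_scheme`; both sequences must match its alphabet.
#' @return A list with `alignment` (tibble with columns `id`, `gapped`) and
#'   `score`.
#' @examples
#' global_align(seq_record("a", "HPGG"), seq_record("b", "HPGG"),
#'              scheme_protein())$score
#' @export
global_align <- function(a, b, scheme = scheme_protein()) {
  ra <- .as_residues(a); rb <- .as_residues(b)
  if (is.data.frame(a) && is.data.frame(b) && a$alphabet != b$alphabet) {
    stop("alphabet mismatch between records")
  }
  chars <- colnames(scheme$matrix)
  la <- nchar(ra); lb <- nchar(rb)
  if (la == 0L || lb == 0L) {
    n <- max(la, lb)
    gap_cost <- if (scheme$end_gaps_free || n == 0L) 0 else
      -(scheme$gap_open + n * scheme$gap_extend)
    al <- tibble::tibble(
      id = c(names(ra), names(rb)),
      gapped = unname(c(if (la) ra else strrep("-", n),
                        if (lb) rb else strrep("-", n)))
    )
    return(list(alignment = al, score = gap_cost))
  }
  res <- .align_profiles_cpp(.seq_profile(ra, chars), .seq_profile(rb, chars),
                             scheme$matrix, scheme$gap_open,
                             scheme$gap_extend, scheme$end_gaps_free)
  rows <- unname(.apply_path(res$path, ra, rb))
  list(alignment = tibble::tibble(id = c(names(ra), names(rb)), gapped = rows),
       score = res$score)
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from neighbor joining on pairwise alignment distances
#' (1 - fraction identical columns), profiles merged in guide-tree order
#' (profile-profile affine alignment), followed by one optional round of
#' leave-one-out refinement kept only when it does not lower the sum-of-pairs
#' score. Ungapping any output row reproduces its input sequence.
#'
#' @param seqs sequence tibble with >= 2 rows, one alphabet.
#' @param scheme a `scoring_scheme`.
#' @param refine run the leave-one-out refinement round? (default TRUE)
#' @return An alignment tibble with columns `id`, `gapped` (input order).
#' @export
progressive_msa <- function(seqs, scheme = scheme_protein(), refine = TRUE) {
  stopifnot(is.data.frame(seqs))
  n <- nrow(seqs)
  if (n < 2L) stop("progressive_msa() needs at least 2 sequences")
  if (length(unique(seqs$alphabet)) != 1L) stop("mixed alphabets")
  if (anyDuplicated(seqs$id)) stop("duplicate sequence ids")
  if (n == 2L) {
    al <- global_align(seqs[1, ], seqs[2, ], scheme)$alignment
    return(al)
  }
  # pairwise guide distances
  D <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- global_align(seqs[i, ], seqs[j, ], scheme)$alignment
    x <- strsplit(al$gapped[1], "")[[1]]
    y <- strsplit(al$gapped[2], "")[[1]]
    D[i, j] <- D[j, i] <- 1 - sum(x == y & x != "-") / length(x)
  }
  guide <- if (n == 3L) .nj3(D) else ape::nj(stats::as.dist(D))
  guide$tip.label <- as.character(guide$tip.label)
  merged <- .merge_clade(guide, length(guide$tip.label) + 1L, seqs, scheme)
  al <- tibble::tibble(id = merged$ids, gapped = merged$rows)
  if (refine) al <- .refine_once(al, seqs, scheme)
  al[match(seqs$id, al$id), ]
}

.nj3 <- function(D) {
  # three-taxon tree: unique unrooted topology, three-point branch lengths
  lab <- rownames(D)
  bl <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
          (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
          (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  tr <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2, byrow = TRUE),
             edge.length = pmax(bl, 0), tip.label = lab, Nnode = 1L)
  class(tr) <- "phylo"
  tr
}

.merge_clade <- function(tree, node, seqs, scheme) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    id <- tree$tip.label[node]
    return(list(ids = id, rows = seqs$residues[seqs$id == id]))
  }
  children <- tree$edge[tree$edge[, 1] == node, 2]
  parts <- lapply(children, function(ch) .merge_clade(tree, ch, seqs, scheme))
  acc <- parts[[1]]
  for (k in 2:length(parts)) acc <- .merge_profiles(acc, parts[[k]], scheme)
  acc
}

.merge_profiles <- function(pa, pb, scheme) {
  chars <- colnames(scheme$matrix)
  res <- .align_profiles_cpp(.rows_profile(pa$rows, chars),
                             .rows_profile(pb$rows, chars),
                             scheme$matrix, scheme$gap_open,
                             scheme$gap_extend, scheme$end_gaps_free)
  rows <- .apply_path(res$path, pa$rows, pb$rows)
  list(ids = c(pa$ids, pb$ids), rows = rows)
}

.drop_allgap_cols <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- colSums(mat != "-") > 0
  apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
}

.sp_score <- function(rows, scheme) {
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  mat[mat == "*"] <- "X"
  chars <- colnames(scheme$matrix)
  total <- 0
  n <- nrow(mat)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- mat[i, ]; b <- mat[j, ]
    both <- a != "-" & b != "-"
    total <- total + sum(scheme$matrix[cbind(a[both], b[both])])
    total <- total - scheme$gap_extend * sum(xor(a == "-", b == "-"))
  }
  total
}

.refine_once <- function(al, seqs, scheme) {
  best_rows <- al$gapped
  best_sp <- .sp_score(best_rows, scheme)
  for (i in seq_len(nrow(al))) {
    others <- .drop_allgap_cols(best_rows[-i])
    chars <- colnames(scheme$matrix)
    seq_i <- gsub("-", "", best_rows[i], fixed = TRUE)
    res <- .align_profiles_cpp(.rows_profile(others, chars),
                               .seq_profile(seq_i, chars),
                               scheme$matrix, scheme$gap_open,
                               scheme$gap_extend, scheme$end_gaps_free)
    rows <- .apply_path(res$path, others, seq_i)
    cand <- append(rows[seq_along(others)], rows[length(rows)], after = i - 1L)
    sp <- .sp_score(cand, scheme)
    if (sp > best_sp) {
      best_rows <- cand
      best_sp <- sp
    }
  }
  tibble::tibble(id = al$id, gapped = best_rows)
}

#' Count fully conserved alignment columns
#'
#' A column is conserved when every row carries the identical residue.
#' Columns containing a gap are never conserved unless `include_gapped`, in
#' which case a gapped column counts if all its residues agree.
#'
#' @param al alignment tibble (`id`, `gapped`).
#' @param include_gapped logical (default FALSE).
#' @return integer count.
#' @export
conserved_columns <- function(al, include_gapped = FALSE) {
  mat <- do.call(rbind, strsplit(al$gapped, ""))
  stopifnot(length(unique(nchar(al$gapped))) == 1L)
  ok <- apply(mat, 2, function(col) {
    has_gap <- any(col == "-")
    res <- col[col != "-"]
    if (has_gap && !include_gapped) return(FALSE)
    length(res) > 0L && length(unique(res)) == 1L
  })
  sum(ok)
}

#' Map annotated reference positions onto a candidate protein
#'
#' Globally aligns the reference to the candidate and carries each annotated
#' reference position through the alignment columns to a candidate coordinate
#' (or `NA` where the candidate has a gap). If the reference residue at an
#' annotated position differs from the annotation's expectation, a warning is
#' issued and the mapping proceeds.
#'
#' @param reference,candidate one-row protein sequence tibbles.
#' @param ann annotation tibble from [parse_residue_annotation()].
#' @param scheme a protein `scoring_scheme`.
#' @return A tibble with columns `ref_pos`, `expected`, `cand_pos` (1-based or
#'   `NA`), `cand_residue` (`NA` when unaligned).
#' @export
map_reference_positions <- function(reference, candidate, ann,
                                    scheme = scheme_protein()) {
  if (nrow(ann) && max(ann$position) > nchar(reference$residues)) {
    stop("annotation position beyond reference length")
  }
  ref_chars <- strsplit(reference$residues, "")[[1]]
  mismatch <- ann$position[ref_chars[ann$position] != ann$expected]
  if (length(mismatch)) {
    warning("reference residues differ from annotation at position(s): ",
            paste(mismatch, collapse = ", "))
  }
  al <- global_align(reference, candidate, scheme)$alignment
  rrow <- strsplit(al$gapped[1], "")[[1]]
  crow <- strsplit(al$gapped[2], "")[[1]]
  ref_pos_at_col <- cumsum(rrow != "-")
  cand_pos_at_col <- cumsum(crow != "-")
  cols <- match(ann$position, ifelse(rrow != "-", ref_pos_at_col, NA))
  cand_res <- crow[cols]
  unaligned <- is.na(cand_res) | cand_res == "-"
  tibble::tibble(
    ref_pos = ann$position,
    expected = ann$expected,
    cand_pos = ifelse(unaligned, NA_integer_, cand_pos_at_col[cols]),
    cand_residue = ifelse(unaligned, NA_character_, cand_res)
  )
}
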