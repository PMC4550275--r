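#' Sequence records as tibbles
#'
#' Throughout the package a set of sequences is an ordinary tibble with columns
#' `id` (header token before the first whitespace), `description` (remainder of
#' the header, possibly empty), `alphabet` (`"nucleotide"` or `"protein"`) and
#' `residues` (upper-case sequence string). [seq_record()] builds such a tibble
#' from vectors and validates the alphabet.
#'
#' @param id character vector of record ids.
#' @param residues character vector of sequences (case-insensitive on input).
#' @param alphabet `"nucleotide"`, `"protein"`, or `"auto"` to guess from the
#'   residue content.
#' @param description optional character vector of descriptions.
#' @return A tibble with columns `id`, `description`, `alphabet`, `residues`.
#' @examples
#' seq_record("a", "acgt")
#' @export
seq_record <- function(id, residues, alphabet = "auto", description = "") {
  residues <- toupper(as.character(residues))
  if (any(!nzchar(residues))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  }
  alphabet <- .resolve_alphabet(residues, alphabet)
  for (i in seq_along(residues)) .check_alphabet(residues[i], alphabet[i], id[i])
  tibble::tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    alphabet = alphabet,
    residues = residues
  )
}

.NT_CHARS <- c("A", "C", "G", "T", "N")
.AA_CHARS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
  "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*"
)

.resolve_alphabet <- function(residues, alphabet) {
  alphabet <- match.arg(alphabet, c("auto", "nucleotide", "protein"))
  if (alphabet != "auto") return(rep_len(alphabet, length(residues)))
  vapply(residues, function(s) {
    chars <- unique(strsplit(s, "")[[1]])
    if (all(chars %in% .NT_CHARS)) "nucleotide" else "protein"
  }, character(1), USE.NAMES = FALSE)
}

.check_alphabet <- function(s, alphabet, id = "<sequence>") {
  allowed <- if (alphabet == "nucleotide") .NT_CHARS else .AA_CHARS
  bad <- setdiff(unique(strsplit(s, "")[[1]]), allowed)
  if (length(bad)) {
    stop("record '", id, "': characters not in the ", alphabet, " alphabet: ",
         paste(bad, collapse = ""))
  }
  invisible(TRUE)
}

#' Read and write FASTA files
#'
#' `read_fasta()` returns one row per record, in file order, with wrapped
#' sequence lines concatenated and case normalised to upper. `write_fasta()`
#' is its inverse (sequences wrapped at 70 columns), so the pair round-trips
#' `id`/`residues` exactly.
#'
#' @param path file path.
#' @param alphabet forwarded to [seq_record()]; default guesses per record.
#' @return `read_fasta()`: a sequence tibble (see [seq_record()]).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  if (any(!nzchar(trimws(headers)))) {
    stop("malformed header (empty) at record ",
         which(!nzchar(trimws(headers)))[1], " in ", path)
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  res <- as.character(set)
  if (any(!nzchar(res))) {
    stop("empty sequence for record '", ids[!nzchar(res)][1], "' in ", path)
  }
  seq_record(ids, res, alphabet = alphabet, description = desc)
}

#' @param seqs a sequence tibble with at least `id` and `residues`.
#' @param width line-wrap width for `write_fasta()`.
#' @rdname read_fasta
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  desc <- rep_len(desc, nrow(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    header <- if (nzchar(desc[i])) paste(seqs$id[i], desc[i]) else seqs$id[i]
    s <- seqs$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", header), substring(s, starts, starts + width - 1L)),
               con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Vectorised reverse complement of nucleotide strings; `N` maps to `N`, and
#' the operation is an involution.
#'
#' @param nt character vector of nucleotide sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("AAAC")
#' @export
revcomp <- function(nt) {
  vapply(as.character(nt), function(s) {
    if (!nzchar(s)) return("")
    .check_alphabet(toupper(s), "nucleotide")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
  }, character(1), USE.NAMES = FALSE)
}

.codon_table <- function() {
  if (is.null(.lcpufa_env$CODON)) {
    e <- new.env()
    .lcpufa_env$CODON <- Biostrings::GENETIC_CODE
  }
  .lcpufa_env$CODON
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code, from the given frame to the first in-frame stop
#' codon or the end of the sequence. The stop symbol is not included in the
#' output, a trailing partial codon is ignored, and any codon containing `N`
#' translates to `X`.
#'
#' @param nt nucleotide string.
#' @param frame 0, 1 or 2 (offset from the 5' end).
#' @return the translated protein string (possibly empty).
#' @examples
#' translate("ATGGAATAA")
#' @export
translate <- function(nt, frame = 0) {
  stopifnot(length(nt) == 1L, frame %in% 0:2)
  nt <- toupper(nt)
  if (!nzchar(nt)) return("")
  .check_alphabet(nt, "nucleotide")
  s <- substr(nt, frame + 1L, nchar(nt))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(.codon_table()[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}
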