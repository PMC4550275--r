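#' Compile a degenerate protein motif
#'
#' The pattern grammar has exactly three position types: a literal residue
#' (`H`), the wildcard `X` (any residue), and a binary alternatives group
#' written `A/B` (either residue). So `"HPGG"` has length 4, `"HXXXH"` length
#' 5, and the consensus `"HDF/YGH"` length 5 with alternatives \{F, Y\} at
#' position 3. Alternatives groups are limited to two residues; anything else
#' is rejected with the offending position.
#'
#' @param name pattern name carried into hits.
#' @param spec pattern string in the grammar above.
#' @return An object of class `motif_pattern`: list with `name`, `spec`,
#'   `length` and `positions` (list of allowed-residue character vectors;
#'   `NA` marks a wildcard).
#' @examples
#' compile_pattern("hbox1_consensus", "HDF/YGH")$length
#' @export
compile_pattern <- function(name, spec) {
  if (!nzchar(spec)) stop("empty pattern spec")
  chars <- strsplit(toupper(spec), "")[[1]]
  aa_ok <- setdiff(.AA_CHARS, c("X", "*"))
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    c1 <- chars[i]
    if (c1 == "/") stop("pattern '", spec, "': '/' with no left residue at position ", i)
    if (c1 == "X") {
      positions[[length(positions) + 1L]] <- NULL_POSITION
      i <- i + 1L
      next
    }
    if (!c1 %in% aa_ok) stop("pattern '", spec, "': illegal character '", c1,
                             "' at position ", i)
    if (i + 1L <= length(chars) && chars[i + 1L] == "/") {
      if (i + 2L > length(chars)) stop("pattern '", spec, "': dangling '/'")
      c2 <- chars[i + 2L]
      if (!c2 %in% aa_ok) stop("pattern '", spec, "': illegal alternative '",
                               c2, "' at position ", i + 2L)
      if (i + 3L <= length(chars) && chars[i + 3L] == "/") {
        stop("pattern '", spec, "': alternatives groups are limited to 2 residues")
      }
      positions[[length(positions) + 1L]] <- c(c1, c2)
      i <- i + 3L
    } else {
      positions[[length(positions) + 1L]] <- c1
      i <- i + 1L
    }
  }
  structure(list(name = name, spec = spec, length = length(positions),
                 positions = positions),
            class = "motif_pattern")
}

# sentinel so that list assignment keeps a slot for wildcards
NULL_POSITION <- NA_character_

#' Scan a protein for a compiled motif
#'
#' Reports every (possibly overlapping) window satisfying the pattern, in
#' ascending start order.
#'
#' @param protein protein string.
#' @param pattern a `motif_pattern` from [compile_pattern()].
#' @return A tibble with columns `pattern_name`, `start` (0-based), `matched`.
#' @examples
#' scan_motif("AAHDFGHAA", compile_pattern("hbox1", "HXXXH"))
#' @export
scan_motif <- function(protein, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"), length(protein) == 1L)
  protein <- toupper(protein)
  L <- nchar(protein)
  k <- pattern$length
  empty <- tibble::tibble(pattern_name = character(), start = integer(),
                          matched = character())
  if (L < k) return(empty)
  chars <- strsplit(protein, "")[[1]]
  ok <- rep(TRUE, L - k + 1L)
  for (j in seq_len(k)) {
    allowed <- pattern$positions[[j]]
    if (length(allowed) == 1L && is.na(allowed)) next   # wildcard
    ok <- ok & chars[seq_len(L - k + 1L) + j - 1L] %in% allowed
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  tibble::tibble(
    pattern_name = pattern$name,
    start = starts - 1L,
    matched = substring(protein, starts, starts + k - 1L)
  )
}

#' Parse a conserved-residue annotation string
#'
#' Annotation strings are comma-separated tokens, each an integer reference
#' position followed by one or more residue letters; a multi-letter run such
#' as `"131DT"` expands to consecutive positions (131 D, 132 T). This is the
#' reading under which the elongase checklist
#' `"125K, 128E, 131DT, 137L, 151HH, 178N, 182H, 185MY, 188YY, 208T, 250LF,
#' 254F"` totals 17 residues.
#'
#' @param text annotation string (may be empty).
#' @param source_ref_id id of the reference protein the positions refer to.
#' @return A tibble with columns `position` (1-based, strictly increasing) and
#'   `expected` (single residue), with attribute `source_ref_id`.
#' @export
parse_residue_annotation <- function(text, source_ref_id = "") {
  text <- trimws(text)
  if (!nzchar(text)) {
    out <- tibble::tibble(position = integer(), expected = character())
    attr(out, "source_ref_id") <- source_ref_id
    return(out)
  }
  tokens <- trimws(strsplit(text, ",")[[1]])
  rows <- purrr::map(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([0-9]+)([A-Za-z]+)$", tok))[[1]]
    if (length(m) != 3L) stop("bad annotation token: '", tok, "'")
    p0 <- as.integer(m[2])
    letters <- toupper(strsplit(m[3], "")[[1]])
    bad <- setdiff(letters, setdiff(.AA_CHARS, c("X", "*")))
    if (length(bad)) stop("bad residue letter(s) in token '", tok, "'")
    tibble::tibble(position = p0 + seq_along(letters) - 1L, expected = letters)
  })
  out <- dplyr::bind_rows(rows)
  if (any(diff(out$position) <= 0L)) {
    stop("annotation positions not strictly increasing after expansion")
  }
  attr(out, "source_ref_id") <- source_ref_id
  out
}

#' Serialise a residue annotation back to its text form
#'
#' Inverse of [parse_residue_annotation()]: consecutive positions are
#' re-collapsed into multi-letter runs.
#'
#' @param ann annotation tibble from [parse_residue_annotation()].
#' @return single annotation string.
#' @export
format_residue_annotation <- function(ann) {
  if (nrow(ann) == 0L) return("")
  run <- cumsum(c(1L, diff(ann$position) != 1L))
  parts <- vapply(split(seq_len(nrow(ann)), run), function(idx) {
    paste0(ann$position[idx[1]], paste(ann$expected[idx], collapse = ""))
  }, character(1))
  paste(parts, collapse = ", ")
}

#' Built-in motif profile and elongase residue checklist
#'
#' `builtin_motifs()` reads the motif profile shipped with the package: the
#' haeme-binding motif `HPGG`, the three desaturase histidine boxes (`HXXXH`,
#' `HXXHH`, `QXXHH`), the elongase diagnostic box (`HXXHH`), and the observed
#' consensus variants of each box (`HDF/YGH`, `HY/FQ/LHH`, `QI/VEHH`,
#' `HVF/YHH`). `builtin_elovl_annotation()` reads the shipped 17-residue
#' elongase checklist (positions on the Elovl5 reference coordinate system).
#'
#' @return `builtin_motifs()`: a named list of `motif_pattern` objects.
#' @export
builtin_motifs <- function() {
  path <- system.file("extdata", "motif_profiles.txt", package = "lcpufa")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  pats <- purrr::map(kv, ~ compile_pattern(trimws(.x[1]), trimws(.x[2])))
  stats::setNames(pats, vapply(pats, `[[`, character(1), "name"))
}

#' @rdname builtin_motifs
#' @return `builtin_elovl_annotation()`: an annotation tibble
#'   (see [parse_residue_annotation()]).
#' @export
builtin_elovl_annotation <- function() {
  path <- system.file("extdata", "elovl_annotation.txt", package = "lcpufa")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parse_residue_annotation(lines[1], source_ref_id = "Elovl5_reference")
}
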