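# conservative substitution groups accepted at checklist positions
CONSERVATIVE_GROUPS <- list(
  c("S", "T"), c("L", "V", "I", "A"), c("F", "Y"),
  c("K", "R"), c("D", "E"), c("N", "Q")
)

.is_conservative <- function(a, b) {
  any(vapply(CONSERVATIVE_GROUPS, function(g) a %in% g && b %in% g,
             logical(1)))
}

#' Screening configuration
#'
#' Bundles every tunable of the candidate screen: the contig length
#' pre-filter (200 nt), the per-family full-length protein windows (Fad
#' 380-480 aa, Elovl 230-340 aa, enclosing the 428-445 and 261-324 aa ranges
#' observed for curated family members), the transmembrane scanner
#' parameters, the N-terminal span in which the haeme motif must occur (80 aa,
#' proxying the cytochrome b5-like domain location), and the residue-checklist
#' tolerance (at most 1 non-conservative mismatch).
#'
#' @param min_contig_nt contig length pre-filter.
#' @param min_orf_aa minimum ORF length considered at all.
#' @param fad_len_window,elovl_len_window full-length aa windows.
#' @param tm list of [tm_segments()] parameters.
#' @param haeme_nterm_limit HPGG must start within this many N-terminal aa.
#' @param max_residue_mismatches checklist tolerance (non-conservative).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(min_contig_nt = 200, min_orf_aa = 100,
                          fad_len_window = c(380L, 480L),
                          elovl_len_window = c(230L, 340L),
                          tm = list(window = 19, threshold = 1.6,
                                    min_len = 19, min_gap = 5),
                          haeme_nterm_limit = 80,
                          max_residue_mismatches = 1) {
  stopifnot(min_contig_nt > 0, min_orf_aa >= 1,
            diff(fad_len_window) >= 0, diff(elovl_len_window) >= 0,
            haeme_nterm_limit > 0, max_residue_mismatches >= 0)
  structure(list(min_contig_nt = min_contig_nt, min_orf_aa = min_orf_aa,
                 fad_len_window = fad_len_window,
                 elovl_len_window = elovl_len_window, tm = tm,
                 haeme_nterm_limit = haeme_nterm_limit,
                 max_residue_mismatches = max_residue_mismatches),
            class = "screen_config")
}

#' Default references for screening
#'
#' The Elovl residue checklist needs an annotated reference protein; the
#' shipped default is the [synthetic Elovl5 scaffold][default_elovl_reference]
#' plus the built-in 17-residue annotation.
#'
#' @return list with `elovl_reference` (sequence tibble) and
#'   `elovl_annotation` (annotation tibble).
#' @export
default_refs <- function() {
  list(elovl_reference = default_elovl_reference(),
       elovl_annotation = builtin_elovl_annotation())
}

.tm_count <- function(protein, cfg) {
  nrow(tm_segments(protein, window = cfg$tm$window,
                   threshold = cfg$tm$threshold, min_len = cfg$tm$min_len,
                   min_gap = cfg$tm$min_gap))
}

#' Structural filter for Fad desaturase candidates
#'
#' Evaluates, on the translated protein: (1) the haeme-binding HPGG motif
#' within the N-terminal `haeme_nterm_limit` residues (proxy for the
#' cytochrome b5-like domain, which contains it); (2-4) presence of the three
#' histidine boxes HXXXH, HXXHH, QXXHH — HXXXH must have an occurrence
#' distinct from an HXXHH window, since every HXXHH also matches HXXXH; (5)
#' their starts strictly increasing in the order HPGG < HXXXH < HXXHH <
#' QXXHH (evaluated over the boxes that are present, so a single missing
#' motif flips exactly its own filter); (6) 3-4 transmembrane segments.
#'
#' @param protein protein string.
#' @param cfg a [screen_config()].
#' @return evidence tibble with columns `filter`, `pass`, `detail`.
#' @export
check_fad_structure <- function(protein, cfg = screen_config()) {
  motifs <- builtin_motifs()
  hpgg <- scan_motif(protein, motifs$haeme)
  b1 <- scan_motif(protein, motifs$fad_box1)
  b2 <- scan_motif(protein, motifs$fad_box2)
  b3 <- scan_motif(protein, motifs$fad_box3)
  # HXXXH windows that are not themselves HXXHH windows
  b1d <- b1[!b1$start %in% b2$start, , drop = FALSE]
  hpgg_ok <- hpgg[hpgg$start < cfg$haeme_nterm_limit, , drop = FALSE]
  first <- function(x) if (nrow(x)) x$start[1] else NA_integer_
  starts <- c(haeme = first(hpgg_ok), hbox1 = first(b1d), hbox2 = first(b2),
              hbox3 = first(b3))
  present <- starts[!is.na(starts)]
  order_ok <- length(present) <= 1L || all(diff(present) > 0)
  tmc <- .tm_count(protein, cfg)
  tibble::tibble(
    filter = c("haeme_hpgg", "hbox1_hxxxh", "hbox2_hxxhh", "hbox3_qxxhh",
               "box_order", "tm_count"),
    pass = c(nrow(hpgg_ok) > 0, nrow(b1d) > 0, nrow(b2) > 0, nrow(b3) > 0,
             order_ok, tm_count_ok(tmc, "Fad")),
    detail = c(
      if (nrow(hpgg_ok)) paste0("HPGG at ", hpgg_ok$start[1]) else
        "no HPGG in N-terminal region",
      if (nrow(b1d)) paste0(b1d$matched[1], " at ", b1d$start[1]) else
        "no distinct HXXXH",
      if (nrow(b2)) paste0(b2$matched[1], " at ", b2$start[1]) else "absent",
      if (nrow(b3)) paste0(b3$matched[1], " at ", b3$start[1]) else "absent",
      paste(names(present), present, collapse = " < "),
      paste0(tmc, " segments")
    )
  )
}

#' Structural filter for Elovl elongase candidates
#'
#' Evaluates: (1) the diagnostic HXXHH histidine box; (2) 5-7 transmembrane
#' segments; (3) the 17-residue conserved checklist transferred from the
#' annotated reference by global alignment — matches and conservative
#' substitutions (S/T, L/V/I/A, F/Y, K/R, D/E, N/Q) are accepted, and the
#' filter passes iff non-conservative mismatches (including unaligned
#' positions) do not exceed `max_residue_mismatches`.
#'
#' @param protein protein string.
#' @param reference annotated reference protein (one-row sequence tibble).
#' @param ann annotation tibble for the reference.
#' @param cfg a [screen_config()].
#' @return evidence tibble with columns `filter`, `pass`, `detail`.
#' @export
check_elovl_structure <- function(protein, reference = default_elovl_reference(),
                                  ann = builtin_elovl_annotation(),
                                  cfg = screen_config()) {
  motifs <- builtin_motifs()
  box <- scan_motif(protein, motifs$elovl_box)
  tmc <- .tm_count(protein, cfg)
  mapped <- map_reference_positions(reference,
                                    seq_record("candidate", protein,
                                               alphabet = "protein"),
                                    ann)
  cls <- dplyr::case_when(
    is.na(mapped$cand_residue) ~ "unaligned",
    mapped$cand_residue == mapped$expected ~ "match",
    vapply(seq_len(nrow(mapped)), function(i) {
      !is.na(mapped$cand_residue[i]) &&
        .is_conservative(mapped$expected[i], mapped$cand_residue[i])
    }, logical(1)) ~ "conservative",
    TRUE ~ "mismatch"
  )
  n_bad <- sum(cls %in% c("mismatch", "unaligned"))
  tibble::tibble(
    filter = c("elovl_box_hxxhh", "tm_count", "residue_checklist"),
    pass = c(nrow(box) > 0, tm_count_ok(tmc, "Elovl"),
             n_bad <= cfg$max_residue_mismatches),
    detail = c(
      if (nrow(box)) paste0(box$matched[1], " at ", box$start[1]) else "absent",
      paste0(tmc, " segments"),
      paste0(sum(cls == "match"), " match, ",
             sum(cls == "conservative"), " conservative, ",
             sum(cls == "mismatch"), " mismatch, ",
             sum(cls == "unaligned"), " unaligned")
    )
  )
}

#' Classify one contig
#'
#' Applies the full candidate screen to a single contig: the contig length
#' pre-filter, six-frame ORF extraction, per-family full-length windows, and
#' the family structure checks. A candidate whose full-length ORF passes
#' every family filter is `functional`; full-length but failing one or more
#' structural filters is `putative_pseudogene`; an incomplete ORF with the
#' family's diagnostic motif is `partial`; anything else is `rejected`. If
#' both family checks fully pass (pathological), the family with more
#' passing filters wins and an exact tie is rejected as ambiguous.
#'
#' @param contig one-row nucleotide sequence tibble.
#' @param cfg a [screen_config()].
#' @param refs references from [default_refs()].
#' @return one-row tibble: `record_id`, `family`, `status`, `aa_len`,
#'   `tm_count`, `n_pass`, `n_filters`, `reason`, plus list-columns
#'   `evidence` and `orf`.
#' @export
classify_candidate <- function(contig, cfg = screen_config(),
                               refs = default_refs()) {
  call_row <- function(family, status, reason, orf = NULL, evidence = NULL) {
    tibble::tibble(
      record_id = contig$id, family = family, status = status,
      aa_len = if (is.null(orf)) NA_integer_ else orf$aa_len,
      tm_count = if (is.null(orf)) NA_integer_ else
        .tm_count(orf$aa, cfg),
      n_pass = if (is.null(evidence)) NA_integer_ else sum(evidence$pass),
      n_filters = if (is.null(evidence)) NA_integer_ else nrow(evidence),
      reason = reason,
      evidence = list(evidence %||% tibble::tibble()),
      orf = list(orf)
    )
  }
  if (nchar(contig$residues) < cfg$min_contig_nt) {
    return(call_row("none", "rejected",
                    paste0("below ", cfg$min_contig_nt, " nt")))
  }
  orfs <- find_orfs(contig, min_aa = cfg$min_orf_aa)
  if (nrow(orfs) == 0L) {
    return(call_row("none", "rejected",
                    paste0("no ORF of >= ", cfg$min_orf_aa, " aa")))
  }
  windows <- list(Fad = cfg$fad_len_window, Elovl = cfg$elovl_len_window)
  assess <- purrr::map(names(windows), function(fam) {
    w <- windows[[fam]]
    full <- orfs[vapply(seq_len(nrow(orfs)), function(i) {
      is_full_length(orfs[i, ], w)
    }, logical(1)), , drop = FALSE]
    if (nrow(full) == 0L) return(NULL)
    orf <- full[1, ]    # longest full-length ORF in the family window
    ev <- if (fam == "Fad") check_fad_structure(orf$aa, cfg) else
      check_elovl_structure(orf$aa, refs$elovl_reference,
                            refs$elovl_annotation, cfg)
    list(family = fam, orf = orf, evidence = ev,
         frac_pass = sum(ev$pass) / nrow(ev), all_pass = all(ev$pass))
  })
  assess <- purrr::compact(assess)
  if (length(assess)) {
    passing <- purrr::keep(assess, "all_pass")
    if (length(passing) == 2L) {
      n_pass <- purrr::map_int(passing, ~ sum(.x$evidence$pass))
      if (n_pass[1] == n_pass[2]) {
        return(call_row("none", "rejected", "ambiguous family assignment"))
      }
      passing <- passing[which.max(n_pass)]
    }
    if (length(passing) == 1L) {
      a <- passing[[1]]
      return(call_row(a$family, "functional", "all filters passed",
                      a$orf, a$evidence))
    }
    # full-length somewhere but structurally broken: putative pseudogene
    best <- assess[order(-purrr::map_dbl(assess, "frac_pass"))][[1]]
    failed <- best$evidence$filter[!best$evidence$pass]
    return(call_row(best$family, "putative_pseudogene",
                    paste("failed:", paste(failed, collapse = ", ")),
                    best$orf, best$evidence))
  }
  # no full-length ORF in any window: partial if any ORF carries a family's
  # diagnostic motif (longest such ORF reported; haeme motif is the more
  # specific signature and wins when both occur)
  motifs <- builtin_motifs()
  fad_hits <- vapply(orfs$aa, function(a) {
    nrow(scan_motif(a, motifs$haeme)) > 0L
  }, logical(1))
  elovl_hits <- vapply(orfs$aa, function(a) {
    nrow(scan_motif(a, motifs$elovl_box)) > 0L
  }, logical(1))
  if (any(fad_hits)) {
    return(call_row("Fad", "partial", "incomplete ORF with haeme motif",
                    orfs[which(fad_hits)[1], ]))
  }
  if (any(elovl_hits)) {
    return(call_row("Elovl", "partial",
                    "incomplete ORF with diagnostic histidine box",
                    orfs[which(elovl_hits)[1], ]))
  }
  call_row("none", "rejected", "no family evidence")
}

#' Screen a whole transcriptome
#'
#' Maps [classify_candidate()] over every contig (exhaustive screening — no
#' similarity pre-filter) and tabulates calls per family and status. With
#' `out_dir`, writes `calls.tsv` and `summary.json`.
#'
#' @param x a sequence tibble or a FASTA path.
#' @param cfg a [screen_config()].
#' @param refs references from [default_refs()].
#' @param out_dir optional output directory.
#' @return An object of class `lcpufa_screen`: list with `calls` (tibble),
#'   `summary` (named counts) and `config`.
#' @export
screen_transcriptome <- function(x, cfg = screen_config(),
                                 refs = default_refs(), out_dir = NULL) {
  contigs <- if (is.character(x)) read_fasta(x, alphabet = "nucleotide") else x
  calls <- dplyr::bind_rows(purrr::map(seq_len(nrow(contigs)), function(i) {
    classify_candidate(contigs[i, ], cfg, refs)
  }))
  summary <- calls |>
    dplyr::count(.data$family, .data$status, name = "n") |>
    dplyr::arrange(.data$family, .data$status)
  res <- structure(list(calls = calls, summary = summary, config = cfg),
                   class = "lcpufa_screen")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(dplyr::select(calls, -"evidence", -"orf"),
                     file.path(out_dir, "calls.tsv"))
    jsonlite::write_json(
      list(counts = summary,
           config = unclass(cfg),
           note = "TM counts from a Kyte-Doolittle hydropathy scanner"),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
  }
  res
}

#' @export
print.lcpufa_screen <- function(x, ...) {
  cat("lcPUFA gene screen:", nrow(x$calls), "contigs\n")
  print(x$summary, n = Inf)
  invisible(x)
}
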