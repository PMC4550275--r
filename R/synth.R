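# Residue pools for scaffold construction. Linkers exclude H and Q (and P)
# so histidine boxes and the HPGG motif can only occur where planted, and are
# hydrophilic enough (mean Kyte-Doolittle about -2.9) that transmembrane
# stretches are detected exactly where planted.
.HYDRO_POOL <- c("L", "I", "V", "F", "A")
.LINKER_POOL <- c("E", "K", "R", "D", "N", "S", "G")

# fixed scaffold geometry (1-based protein positions)
.FAD_LAYOUT <- list(hpgg = 25L, box1 = 120L, box2 = 155L, box3 = 360L,
                    tm_starts = c(190L, 231L, 272L, 313L), tm_len = 21L)
.ELOVL_LAYOUT <- list(box = 148L, tm_starts = c(15L, 61L, 103L, 161L, 208L),
                      tm6_start = 258L, tm6_min_len = 283L, tm_len = 21L)

.sample1 <- function(x) x[sample.int(length(x), 1L)]

# draw one integer from [lo, hi] (safe when lo == hi)
.sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

.rand_chars <- function(pool, n) {
  paste(pool[sample.int(length(pool), n, replace = TRUE)], collapse = "")
}

# canonical per-family residue backdrop (deterministic), from which every
# generated gene diverges by a bounded fraction — family members are
# homologs, not independent random strings
.canonical_backdrop <- function(family) {
  key <- paste0("CANON_", family)
  if (is.null(.lcpufa_env[[key]])) {
    old <- .Random.seed_save()
    set.seed(if (family == "Fad") 2024L else 2025L)
    .lcpufa_env[[key]] <- list(
      linker = strsplit(.rand_chars(.LINKER_POOL, 600L), "")[[1]],
      hydro = strsplit(.rand_chars(.HYDRO_POOL, 600L), "")[[1]]
    )
    .Random.seed_restore(old)
  }
  .lcpufa_env[[key]]
}

# canonical residues for positions `idx`, each resampled from `pool` with
# probability `divergence`
.diverged <- function(canon_chars, idx, pool, divergence) {
  out <- canon_chars[idx]
  flip <- stats::runif(length(idx)) < divergence
  if (any(flip)) {
    out[flip] <- pool[sample.int(length(pool), sum(flip), replace = TRUE)]
  }
  out
}

.place <- function(chars, start, insert) {
  chars[start:(start + nchar(insert) - 1L)] <- strsplit(insert, "")[[1]]
  chars
}

#' Synthetic Fad / Elovl protein scaffolds
#'
#' Builds a protein with the family's diagnostic architecture at fixed
#' scaffold positions: for Fad, the haeme-binding HPGG in the N-terminal
#' region followed by the three histidine boxes (drawn from the observed
#' consensus variants) in order and 3-4 hydrophobic 21-mer membrane
#' stretches; for Elovl, the diagnostic HXXHH box (consensus `HVF/YHH`), the
#' 17-residue conserved checklist at its reference positions, and 5-6
#' membrane stretches. Everything else is hydrophilic linker. Uses the
#' current RNG state.
#'
#' @param len protein length in amino acids (Fad >= 400, Elovl >= 261).
#' @param divergence fraction of backdrop residues resampled per gene
#'   (default 0.15, giving roughly 85-90% identity between family members —
#'   they are homologs of a canonical per-family backdrop, not independent
#'   random strings).
#' @return A list with `aa` (protein string) and `truth` (named list of
#'   0-based motif start positions and the planted `tm_count`).
#' @export
make_fad_protein <- function(len, divergence = 0.15) {
  ly <- .FAD_LAYOUT
  if (len < ly$box3 + 5L + 35L) stop("Fad scaffold needs at least ",
                                     ly$box3 + 40L, " aa")
  canon <- .canonical_backdrop("Fad")
  n_tm <- .sample1(3:4)
  chars <- .diverged(canon$linker, seq_len(len), .LINKER_POOL, divergence)
  for (s in ly$tm_starts[seq_len(n_tm)]) {
    chars[s:(s + ly$tm_len - 1L)] <-
      .diverged(canon$hydro, s:(s + ly$tm_len - 1L), .HYDRO_POOL, divergence)
  }
  box1 <- .sample1(c("HDFGH", "HDYGH"))
  box2 <- paste0("H", .sample1(c("Y", "F")), .sample1(c("Q", "L")), "HH")
  box3 <- paste0("Q", .sample1(c("I", "V")), "EHH")
  chars <- .place(chars, ly$hpgg, "HPGG")
  chars <- .place(chars, ly$box1, box1)
  chars <- .place(chars, ly$box2, box2)
  chars <- .place(chars, ly$box3, box3)
  list(aa = paste(chars, collapse = ""),
       truth = list(hpgg_start = ly$hpgg - 1L, box1_start = ly$box1 - 1L,
                    box2_start = ly$box2 - 1L, box3_start = ly$box3 - 1L,
                    tm_count = n_tm))
}

#' @rdname make_fad_protein
#' @export
make_elovl_protein <- function(len, divergence = 0.15) {
  ly <- .ELOVL_LAYOUT
  ann <- builtin_elovl_annotation()
  if (len < max(ann$position) + 5L) stop("Elovl scaffold needs at least ",
                                         max(ann$position) + 5L, " aa")
  canon <- .canonical_backdrop("Elovl")
  chars <- .diverged(canon$linker, seq_len(len), .LINKER_POOL, divergence)
  n_tm <- 5L
  tm_starts <- ly$tm_starts
  if (len >= ly$tm6_min_len) {
    n_tm <- 6L
    tm_starts <- c(tm_starts, ly$tm6_start)
  }
  for (s in tm_starts) {
    chars[s:(s + ly$tm_len - 1L)] <-
      .diverged(canon$hydro, s:(s + ly$tm_len - 1L), .HYDRO_POOL, divergence)
  }
  box <- paste0("HV", .sample1(c("F", "Y")), "HH")
  chars <- .place(chars, ly$box, box)
  chars[ann$position] <- ann$expected   # checklist residues at reference coords
  list(aa = paste(chars, collapse = ""),
       truth = list(box_start = ly$box - 1L, tm_count = n_tm,
                    checklist_positions = ann$position))
}

.syn_codon_table <- function() {
  if (is.null(.lcpufa_env$SYN)) {
    gc <- .codon_table()
    .lcpufa_env$SYN <- split(names(gc), unname(gc))
  }
  .lcpufa_env$SYN
}

#' Back-translate a protein with uniform synonymous codon choice
#'
#' @param aa protein string (20 amino acids).
#' @return nucleotide coding string (no stop codon), `3 * nchar(aa)` long.
#' @export
back_translate <- function(aa) {
  syn <- .syn_codon_table()
  res <- strsplit(toupper(aa), "")[[1]]
  if (any(!res %in% names(syn) | res == "*")) stop("cannot back-translate: ",
                                                   paste(setdiff(res, names(syn)), collapse = ""))
  paste(vapply(res, function(a) .sample1(syn[[a]]), character(1)),
        collapse = "")
}

.rand_utr <- function(n) {
  if (n <= 0L) return("")
  .rand_chars(c("A", "C", "G", "T"), n)
}

# contig = 5'UTR (ending with an in-frame stop) + ATG + CDS + stop + 3'UTR
.assemble_contig <- function(aa_body, utr_range) {
  utr5 <- .sample_range(utr_range[1], utr_range[2])
  utr5 <- max(utr5, 3L) %/% 3L * 3L   # in-frame guard stop needs room
  utr3 <- .sample_range(utr_range[1], utr_range[2])
  cds <- paste0("ATG", back_translate(substr(aa_body, 2L, nchar(aa_body))),
                .sample1(c("TAA", "TAG", "TGA")))
  stopifnot(substr(aa_body, 1L, 1L) == "M")
  u5 <- paste0(.rand_utr(utr5 - 3L), "TAA")
  contig <- paste0(u5, cds, .rand_utr(utr3))
  list(contig = contig, orf_start = nchar(u5), orf_end = nchar(u5) + nchar(cds),
       aa_len = nchar(aa_body))
}

#' Synthetic Fad / Elovl gene records
#'
#' Generates one transcript contig (UTRs + ATG-initiated coding sequence +
#' stop) containing a scaffold protein from [make_fad_protein()] /
#' [make_elovl_protein()], optionally lesioned, and the matching truth entry.
#' Lesions: `"drop_hpgg"` (Fad only: haeme motif replaced by linker;
#' putative pseudogene), `"scramble_box"` (first histidine box / diagnostic
#' box destroyed; putative pseudogene), `"truncate"` (contig cut inside the
#' ORF; partial), `"frameshift"` (single-base deletion inside the ORF;
#' expected status derived from the realised ORF geometry). With
#' `strand = "-"` the contig is reverse-complemented and truth coordinates
#' flipped. Uses the current RNG state.
#'
#' @param id record id.
#' @param family `"Fad"` or `"Elovl"`.
#' @param len_range aa-length range to draw from (defaults: Fad 428-445,
#'   Elovl 261-324).
#' @param utr_range UTR length range in nt.
#' @param lesion `"none"`, `"drop_hpgg"`, `"scramble_box"`, `"truncate"`,
#'   `"frameshift"`.
#' @param lesion_frac ORF fraction at which truncation (default 0.6) or
#'   frameshift (default 0.3) is applied.
#' @param strand `"+"`, `"-"`, or `"random"`.
#' @return A list with `record` (one-row sequence tibble) and `truth`
#'   (one-row tibble).
#' @export
make_gene <- function(id, family = c("Fad", "Elovl"), len_range = NULL,
                      utr_range = c(60, 300), lesion = "none",
                      lesion_frac = NULL, strand = "random") {
  family <- match.arg(family)
  lesion <- match.arg(lesion, c("none", "drop_hpgg", "scramble_box",
                                "truncate", "frameshift"))
  if (is.null(len_range)) {
    len_range <- if (family == "Fad") c(428L, 445L) else c(261L, 324L)
  }
  len <- .sample_range(len_range[1], len_range[2])
  prot <- if (family == "Fad") make_fad_protein(len) else make_elovl_protein(len)
  chars <- strsplit(prot$aa, "")[[1]]
  chars[1] <- "M"
  expected <- "functional"
  if (lesion == "drop_hpgg") {
    if (family != "Fad") stop("drop_hpgg lesion applies to Fad only")
    chars <- .place(chars, .FAD_LAYOUT$hpgg, .rand_chars(.LINKER_POOL, 4L))
    prot$truth$hpgg_start <- NA_integer_
    expected <- "putative_pseudogene"
  } else if (lesion == "scramble_box") {
    if (family == "Fad") {
      chars <- .place(chars, .FAD_LAYOUT$box1, .rand_chars(.LINKER_POOL, 5L))
      prot$truth$box1_start <- NA_integer_
    } else {
      # destroy the box head, keep the 151/152 HH checklist residues
      chars[.ELOVL_LAYOUT$box] <- .sample1(.LINKER_POOL)
      chars[.ELOVL_LAYOUT$box + 2L] <- .sample1(setdiff(.LINKER_POOL, "H"))
      prot$truth$box_start <- NA_integer_
    }
    expected <- "putative_pseudogene"
  }
  aa_body <- paste(chars, collapse = "")
  asm <- .assemble_contig(aa_body, utr_range)
  contig <- asm$contig
  if (lesion == "truncate") {
    frac <- if (is.null(lesion_frac)) 0.6 else lesion_frac
    cut <- asm$orf_start + 3L * floor(frac * asm$aa_len)
    contig <- substr(contig, 1L, cut)
    expected <- "partial"
  } else if (lesion == "frameshift") {
    frac <- if (is.null(lesion_frac)) 0.3 else lesion_frac
    pos <- asm$orf_start + 3L * floor(frac * asm$aa_len)
    contig <- paste0(substr(contig, 1L, pos - 1L),
                     substr(contig, pos + 1L, nchar(contig)))
    expected <- NA_character_  # filled below from realised geometry
  }
  strand <- if (identical(strand, "random")) .sample1(c("+", "-")) else strand
  L <- nchar(contig)
  orf_start <- asm$orf_start; orf_end <- min(asm$orf_end, L)
  if (strand == "-") {
    contig <- revcomp(contig)
    tmp <- orf_start
    orf_start <- L - orf_end
    orf_end <- L - tmp
  }
  record <- seq_record(id, contig, alphabet = "nucleotide")
  if (lesion == "frameshift") {
    expected <- .expected_status_geometry(record, family)
  }
  truth <- tibble::tibble(
    record_id = id, family = family, expected_status = expected,
    lesion = lesion, strand = strand,
    orf_start = orf_start, orf_end = orf_end, aa_len = asm$aa_len,
    tm_planted = prot$truth$tm_count,
    hpgg_start = prot$truth$hpgg_start %||% NA_integer_,
    box1_start = prot$truth$box1_start %||% prot$truth$box_start %||% NA_integer_,
    box2_start = prot$truth$box2_start %||% NA_integer_,
    box3_start = prot$truth$box3_start %||% NA_integer_
  )
  list(record = record, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Status a lesioned record should receive, from realised ORF geometry alone:
# a stop-terminated ORF inside a family length window can only be a putative
# pseudogene (the lesion broke structure); otherwise the longest ORF's
# diagnostic-motif evidence decides partial vs rejected. Uses low-level
# primitives only (find_orfs/scan), never the screen itself.
.expected_status_geometry <- function(record, family,
                                      fad_window = c(380L, 480L),
                                      elovl_window = c(230L, 340L),
                                      min_aa = 100L) {
  orfs <- find_orfs(record, min_aa = min_aa)
  if (nrow(orfs) == 0L) return("rejected")
  in_window <- orfs$has_stop &
    ((orfs$aa_len >= fad_window[1] & orfs$aa_len <= fad_window[2]) |
       (orfs$aa_len >= elovl_window[1] & orfs$aa_len <= elovl_window[2]))
  if (any(in_window)) return("putative_pseudogene")
  motifs <- builtin_motifs()
  pat <- if (family == "Fad") motifs$haeme else motifs$elovl_box
  hit <- any(vapply(orfs$aa, function(a) nrow(scan_motif(a, pat)) > 0L,
                    logical(1)))
  if (hit) "partial" else "rejected"
}

#' Plant SNPs in a gene record to make a clone pair
#'
#' Plants exactly `n_snps` substitutions inside the ORF of a generated gene
#' record. With `synonymous_only = TRUE` each substitution is drawn from
#' third-position codon degeneracy so the translation is unchanged; otherwise
#' each substitution is forced nonsynonymous. The clone is trimmed or
#' extended at the UTRs at random (it always covers the ORF). Uses the
#' current RNG state.
#'
#' @param gene a list from [make_gene()] (lesion-free, plus strand).
#' @param n_snps number of substitutions to plant.
#' @param synonymous_only logical (default TRUE).
#' @return A list with `clone` (one-row sequence tibble), `snps` (tibble:
#'   `pos_in_orf` 1-based, `from`, `to`, `synonymous`) and `orf_nt` (the
#'   assembled coding sequence, stop codon excluded).
#' @export
make_clone_pair <- function(gene, n_snps, synonymous_only = TRUE) {
  tr <- gene$truth
  if (tr$strand != "+" || tr$lesion != "none") {
    stop("make_clone_pair() expects a lesion-free plus-strand gene record")
  }
  contig <- gene$record$residues
  cds <- substr(contig, tr$orf_start + 1L, tr$orf_end - 3L)  # stop excluded
  n_codon <- nchar(cds) %/% 3L
  syn <- .syn_codon_table()
  codon_at <- function(i) substr(cds, (i - 1L) * 3L + 1L, i * 3L)
  # third-position degeneracy: synonymous codons sharing the first two bases
  third_pos_alts <- function(codon) {
    alts <- setdiff(syn[[.codon_table()[[codon]]]], codon)
    alts[substr(alts, 1L, 2L) == substr(codon, 1L, 2L)]
  }
  if (synonymous_only) {
    degenerate <- which(vapply(seq_len(n_codon), function(i) {
      length(third_pos_alts(codon_at(i))) > 0L
    }, logical(1)))
    if (length(degenerate) < n_snps) {
      stop("only ", length(degenerate), " degenerate codons available for ",
           n_snps, " synonymous SNPs")
    }
    picks <- sort(sample(degenerate, n_snps))
  } else {
    picks <- sort(sample.int(n_codon, n_snps))
  }
  clone_cds <- cds
  snps <- purrr::map_dfr(picks, function(i) {
    old <- codon_at(i)
    if (synonymous_only) {
      new <- .sample1(third_pos_alts(old))
    } else {
      repeat {
        pos <- sample.int(3L, 1L)
        base <- .sample1(setdiff(c("A", "C", "G", "T"),
                                 substr(old, pos, pos)))
        new <- old
        substr(new, pos, pos) <- base
        if (.codon_table()[[new]] != .codon_table()[[old]] &&
            .codon_table()[[new]] != "*") break
      }
    }
    diff_at <- which(strsplit(old, "")[[1]] != strsplit(new, "")[[1]])
    substr(clone_cds, (i - 1L) * 3L + diff_at, (i - 1L) * 3L + diff_at) <<-
      substr(new, diff_at, diff_at)
    tibble::tibble(pos_in_orf = (i - 1L) * 3L + diff_at,
                   from = substr(old, diff_at, diff_at),
                   to = substr(new, diff_at, diff_at),
                   synonymous = synonymous_only)
  })
  u5_avail <- tr$orf_start
  u3_avail <- nchar(contig) - tr$orf_end
  u5 <- sample.int(u5_avail + 1L, 1L) - 1L
  u3 <- sample.int(u3_avail + 1L, 1L) - 1L
  clone <- paste0(substr(contig, tr$orf_start - u5 + 1L, tr$orf_start),
                  clone_cds,
                  substr(contig, tr$orf_end - 2L, tr$orf_end),  # stop codon
                  substr(contig, tr$orf_end + 1L, tr$orf_end + u3))
  list(clone = seq_record(paste0(tr$record_id, "_clone"), clone),
       snps = snps, orf_nt = cds)
}

#' Simulate a gap-free alignment on a tree
#'
#' Draws a root sequence from the model's stationary frequencies and evolves
#' it along the branches under the K2P/T92 transition probabilities, with the
#' invariant-sites / discrete-gamma rate mixture applied per site.
#'
#' @param tree `phylo` with branch lengths.
#' @param m [model_params()].
#' @param n_sites number of sites.
#' @param seed optional integer seed.
#' @param ncat gamma categories for the rate mixture.
#' @return An alignment tibble (`id`, `gapped`), one row per tip.
#' @export
simulate_alignment <- function(tree, m = model_params(), n_sites, seed = NULL,
                               ncat = 4) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ed <- .model_eigen(m)
  mix <- .rate_mixture(m, ncat)
  bases <- c("A", "C", "G", "T")
  cat_of_site <- sample.int(length(mix$rates), n_sites, replace = TRUE,
                            prob = mix$weights)
  rates <- mix$rates[cat_of_site]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample.int(4L, n_sites, replace = TRUE, prob = ed$pi)
  tree <- stats::reorder(tree, "cladewise")  # parent edges before child edges
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    out <- integer(n_sites)
    for (r in unique(rates)) {
      idx <- which(rates == r)
      if (r == 0 || b == 0) {
        out[idx] <- seqs[[parent]][idx]
      } else {
        P <- .pmat(ed, b * r)
        for (s in 1:4) {
          here <- idx[seqs[[parent]][idx] == s]
          if (length(here)) {
            out[here] <- sample.int(4L, length(here), replace = TRUE,
                                    prob = P[s, ])
          }
        }
      }
    }
    seqs[[child]] <- out
  }
  tibble::tibble(
    id = tree$tip.label,
    gapped = vapply(seq_len(ntip), function(i) {
      paste(bases[seqs[[i]]], collapse = "")
    }, character(1))
  )
}

#' Synthetic-transcriptome parameters
#'
#' @param n_fad,n_elovl numbers of lesion-free functional genes.
#' @param n_pseudo full-length pseudogenes (alternating drop-HPGG Fad /
#'   scrambled-box Elovl lesions).
#' @param n_partial truncated partial transcripts (alternating family).
#' @param n_decoys random non-coding contigs, lengths drawn from the planted
#'   records so length alone cannot separate classes.
#' @param fad_len,elovl_len aa-length ranges.
#' @param utr_len UTR length range (nt).
#' @param seed mandatory master seed.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(n_fad = 5, n_elovl = 5, n_pseudo = 3, n_partial = 3,
                         n_decoys = 100, fad_len = c(428L, 445L),
                         elovl_len = c(261L, 324L), utr_len = c(60L, 300L),
                         seed) {
  if (missing(seed)) stop("synth_params() requires an explicit seed")
  stopifnot(n_fad >= 0, n_elovl >= 0, n_pseudo >= 0, n_partial >= 0,
            n_decoys >= 0)
  structure(list(n_fad = n_fad, n_elovl = n_elovl, n_pseudo = n_pseudo,
                 n_partial = n_partial, n_decoys = n_decoys,
                 fad_len = fad_len, elovl_len = elovl_len, utr_len = utr_len,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a synthetic transcriptome with a planted-gene truth ledger
#'
#' Assembles lesion-free Fad and Elovl transcripts, pseudogenised and
#' truncated copies, and random decoy contigs into one contig set, together
#' with a truth table sufficient to decide every screening outcome. The
#' output is a deterministic function of the parameters (including the
#' seed).
#'
#' @param params a [synth_params()] object.
#' @param out_dir optional directory; when given, writes `contigs.fasta`,
#'   `truth.tsv` and `params.json` there.
#' @return A list with `contigs` (sequence tibble) and `truth` (tibble, one
#'   row per planted gene; decoys carry no truth rows).
#' @export
make_transcriptome <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  genes <- list()
  add <- function(g) genes[[length(genes) + 1L]] <<- g
  for (i in seq_len(params$n_fad)) {
    add(make_gene(sprintf("fad_%02d", i), "Fad", params$fad_len,
                  params$utr_len))
  }
  for (i in seq_len(params$n_elovl)) {
    add(make_gene(sprintf("elovl_%02d", i), "Elovl", params$elovl_len,
                  params$utr_len))
  }
  for (i in seq_len(params$n_pseudo)) {
    if (i %% 2L == 1L) {
      add(make_gene(sprintf("pseudo_%02d", i), "Fad", params$fad_len,
                    params$utr_len, lesion = "drop_hpgg"))
    } else {
      add(make_gene(sprintf("pseudo_%02d", i), "Elovl", params$elovl_len,
                    params$utr_len, lesion = "scramble_box"))
    }
  }
  for (i in seq_len(params$n_partial)) {
    fam <- if (i %% 2L == 1L) "Fad" else "Elovl"
    lr <- if (fam == "Fad") params$fad_len else params$elovl_len
    add(make_gene(sprintf("partial_%02d", i), fam, lr, params$utr_len,
                  lesion = "truncate"))
  }
  contigs <- dplyr::bind_rows(purrr::map(genes, ~ .x$record))
  truth <- dplyr::bind_rows(purrr::map(genes, ~ .x$truth))
  if (params$n_decoys > 0L) {
    lens <- if (nrow(contigs)) nchar(contigs$residues) else c(800L, 1500L)
    decoys <- purrr::map(seq_len(params$n_decoys), function(i) {
      seq_record(sprintf("decoy_%03d", i),
                 .rand_chars(c("A", "C", "G", "T"), .sample1(lens)))
    })
    contigs <- dplyr::bind_rows(contigs, dplyr::bind_rows(decoys))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(contigs, file.path(out_dir, "contigs.fasta"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
    jsonlite::write_json(unclass(params), file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(contigs = contigs, truth = truth)
}

#' Synthetic Elovl5 reference protein
#'
#' The conserved-residue checklist refers to positions on an Elovl5 reference
#' protein. The shipped reference is a synthetic scaffold (deterministic
#' seed, 294 aa — the length of the Elovl5 protein the checklist annotates)
#' carrying the 17 checklist residues at their reference positions; it is a
#' stand-in, not the database protein.
#'
#' @return one-row protein sequence tibble, id `Elovl5_synthetic_reference`.
#' @export
default_elovl_reference <- function() {
  if (is.null(.lcpufa_env$ELOVL_REF)) {
    old <- .Random.seed_save()
    set.seed(101L)
    prot <- make_elovl_protein(294L)
    .Random.seed_restore(old)
    .lcpufa_env$ELOVL_REF <- seq_record("Elovl5_synthetic_reference", prot$aa,
                                        alphabet = "protein")
  }
  .lcpufa_env$ELOVL_REF
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
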