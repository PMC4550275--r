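test_that("the generator is a deterministic function of params and seed", {
  p <- synth_params(n_fad = 2, n_elovl = 2, n_pseudo = 2, n_partial = 1,
                    n_decoys = 5, seed = 51)
  a <- make_transcriptome(p)
  b <- make_transcriptome(p)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth, b$truth)
  out <- withr::local_tempdir()
  make_transcriptome(p, out_dir = out)
  expect_true(file.exists(file.path(out, "contigs.fasta")))
  expect_true(file.exists(file.path(out, "truth.tsv")))
  expect_true(file.exists(file.path(out, "params.json")))
  expect_error(synth_params(n_fad = 1), "seed")
})

test_that("record and truth-row bookkeeping matches the requested counts", {
  p <- synth_params(n_fad = 5, n_elovl = 5, n_pseudo = 3, n_partial = 3,
                    n_decoys = 100, seed = 42)
  sim <- make_transcriptome(p)
  expect_equal(nrow(sim$contigs), 116L)
  expect_equal(nrow(sim$truth), 16L)
  expect_equal(anyDuplicated(sim$contigs$id), 0L)
  # decoy lengths are drawn from the planted-record length distribution
  planted_len <- nchar(sim$contigs$residues[1:16])
  decoy_len <- nchar(sim$contigs$residues[17:116])
  expect_true(all(decoy_len %in% planted_len))
})

test_that("planted motif positions coincide with scan hits", {
  set.seed(52)
  motifs <- builtin_motifs()
  for (i in 1:5) {
    g <- make_gene(paste0("f", i), "Fad", strand = "+")
    tr <- g$truth
    orf <- find_orfs(g$record, 100)[1, ]
    expect_equal(orf$start, tr$orf_start)
    expect_equal(orf$end, tr$orf_end)
    expect_true(tr$hpgg_start %in% scan_motif(orf$aa, motifs$haeme)$start)
    expect_true(tr$box1_start %in% scan_motif(orf$aa, motifs$fad_box1)$start)
    expect_true(tr$box2_start %in% scan_motif(orf$aa, motifs$fad_box2)$start)
    expect_true(tr$box3_start %in% scan_motif(orf$aa, motifs$fad_box3)$start)
    e <- make_gene(paste0("e", i), "Elovl", strand = "+")
    eorf <- find_orfs(e$record, 100)[1, ]
    expect_true(e$truth$box1_start %in%
                  scan_motif(eorf$aa, motifs$elovl_box)$start)
  }
})

test_that("generator lesions produce the promised screen outcomes", {
  set.seed(53)
  g1 <- make_gene("l1", "Fad", lesion = "drop_hpgg", strand = "+")
  expect_equal(g1$truth$expected_status, "putative_pseudogene")
  orf <- find_orfs(g1$record, 100)[1, ]
  ev <- check_fad_structure(orf$aa)
  expect_equal(ev$filter[!ev$pass], "haeme_hpgg")
  g2 <- make_gene("l2", "Elovl", lesion = "truncate", strand = "+")
  expect_equal(g2$truth$expected_status, "partial")
  expect_false(find_orfs(g2$record, 100)$has_stop[1])
  expect_error(make_gene("x", "Elovl", lesion = "drop_hpgg"), "Fad only")
})

test_that("frameshift truth matches the realised screen outcome", {
  set.seed(54)
  for (i in 1:5) {
    g <- make_gene(paste0("fs", i), "Fad", lesion = "frameshift")
    call <- classify_candidate(g$record)
    expect_equal(call$status, g$truth$expected_status)
  }
})

test_that("generator-screen consistency holds across seeds", {
  for (sd in 1:5) {
    p <- synth_params(n_fad = 3, n_elovl = 3, n_pseudo = 2, n_partial = 2,
                      n_decoys = 5, seed = sd)
    sim <- make_transcriptome(p)
    calls <- tidy(screen_transcriptome(sim$contigs))
    joined <- dplyr::inner_join(sim$truth, calls, by = "record_id",
                                suffix = c("_truth", "_call"))
    expect_equal(joined$status, joined$expected_status)
    expect_equal(joined$family_call, joined$family_truth)
    decoy <- calls[grepl("^decoy", calls$record_id), ]
    expect_equal(sum(decoy$status == "functional"), 0L)
  }
})

test_that("synonymous-SNP planting respects degeneracy limits", {
  set.seed(55)
  g <- make_gene("g", "Fad", strand = "+")
  expect_error(make_clone_pair(g, n_snps = 10000), "degenerate codons")
  pair <- make_clone_pair(g, n_snps = 4)
  expect_true(all(pair$snps$synonymous))
  # applying the ledger to the ORF leaves the protein unchanged
  mutated <- strsplit(pair$orf_nt, "")[[1]]
  mutated[pair$snps$pos_in_orf] <- pair$snps$to
  expect_equal(translate(paste(mutated, collapse = "")),
               translate(pair$orf_nt))
  expect_equal(length(unique((pair$snps$pos_in_orf - 1) %/% 3)), 4L)
})
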