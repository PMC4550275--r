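test_that("short contigs are rejected by the length pre-filter", {
  set.seed(45)
  call <- classify_candidate(seq_record("short", random_nt(180)))
  expect_equal(call$status, "rejected")
  expect_match(call$reason, "below 200 nt")
})

test_that("deleting one required motif flips exactly its own filter", {
  set.seed(46)
  clean <- make_fad_protein(435)$aa
  ev0 <- check_fad_structure(clean)
  expect_true(all(ev0$pass))
  # HPGG deleted
  no_hpgg <- paste0(substr(clean, 1, 24), "EKRD", substr(clean, 29, nchar(clean)))
  ev1 <- check_fad_structure(no_hpgg)
  expect_equal(ev1$filter[!ev1$pass], "haeme_hpgg")
  # first histidine box deleted
  no_b1 <- paste0(substr(clean, 1, 119), "EKRDN", substr(clean, 125, nchar(clean)))
  ev2 <- check_fad_structure(no_b1)
  expect_equal(ev2$filter[!ev2$pass], "hbox1_hxxxh")
  # second histidine box deleted
  no_b2 <- paste0(substr(clean, 1, 154), "EKRDN", substr(clean, 160, nchar(clean)))
  ev3 <- check_fad_structure(no_b2)
  expect_equal(ev3$filter[!ev3$pass], "hbox2_hxxhh")
  # third histidine box deleted
  no_b3 <- paste0(substr(clean, 1, 359), "EKRDN", substr(clean, 365, nchar(clean)))
  ev4 <- check_fad_structure(no_b3)
  expect_equal(ev4$filter[!ev4$pass], "hbox3_qxxhh")
})

test_that("out-of-order histidine boxes fail only the ordering constraint", {
  set.seed(47)
  # scrambled scaffold: QXXHH first, then HXXXH, HXXHH; HPGG in N-terminus
  chars <- strsplit(paste(sample(c("E", "K", "R", "D", "N", "S", "G"), 435,
                                 TRUE), collapse = ""), "")[[1]]
  place <- function(ch, at, s) { ch[at:(at + nchar(s) - 1)] <- strsplit(s, "")[[1]]; ch }
  chars <- place(chars, 25, "HPGG")
  chars <- place(chars, 120, "QIEHH")
  chars <- place(chars, 200, "HDFGH")
  chars <- place(chars, 300, "HYQHH")
  for (s in c(330, 380)) chars <- place(chars, s, strrep("L", 21))
  ev <- check_fad_structure(paste(chars, collapse = ""))
  expect_false(ev$pass[ev$filter == "box_order"])
  expect_true(all(ev$pass[ev$filter %in%
                            c("haeme_hpgg", "hbox1_hxxxh", "hbox2_hxxhh",
                              "hbox3_qxxhh")]))
})

test_that("the Elovl residue checklist tolerates conservative substitutions", {
  set.seed(48)
  clean <- make_elovl_protein(294)$aa
  ev0 <- check_elovl_structure(clean)
  expect_true(all(ev0$pass))
  expect_match(ev0$detail[ev0$filter == "residue_checklist"], "17 match")
  sub_at <- function(s, pos, r) paste0(substr(s, 1, pos - 1), r,
                                       substr(s, pos + 1, nchar(s)))
  # T -> S at checklist position 208: conservative, still passes
  ts <- sub_at(clean, 208, "S")
  ev1 <- check_elovl_structure(ts)
  expect_true(ev1$pass[ev1$filter == "residue_checklist"])
  expect_match(ev1$detail[ev1$filter == "residue_checklist"], "1 conservative")
  # one non-conservative mismatch: tolerated at the default threshold
  one <- sub_at(clean, 125, "G")
  ev2 <- check_elovl_structure(one)
  expect_true(ev2$pass[ev2$filter == "residue_checklist"])
  # three non-conservative mismatches: fails
  three <- sub_at(sub_at(sub_at(clean, 125, "G"), 128, "G"), 137, "G")
  ev3 <- check_elovl_structure(three)
  expect_false(ev3$pass[ev3$filter == "residue_checklist"])
  # destroyed diagnostic box flips exactly the box filter
  nobox <- sub_at(sub_at(clean, 148, "E"), 150, "K")
  ev4 <- check_elovl_structure(nobox)
  expect_equal(ev4$filter[!ev4$pass], "elovl_box_hxxhh")
})

test_that("classification recovers planted genes with the right calls", {
  p <- synth_params(n_fad = 5, n_elovl = 5, n_pseudo = 3, n_partial = 3,
                    n_decoys = 0, seed = 49)
  sim <- make_transcriptome(p)
  scr <- screen_transcriptome(sim$contigs)
  calls <- tidy(scr)
  joined <- dplyr::inner_join(sim$truth, calls, by = "record_id",
                              suffix = c("_truth", "_call"))
  expect_equal(nrow(joined), 16L)
  expect_equal(joined$status, joined$expected_status)
  expect_equal(joined$family_call, joined$family_truth)
  g <- glance(scr)
  expect_equal(g$n_functional, 10L)
  expect_equal(g$n_pseudogene, 3L)
  expect_equal(g$n_partial, 3L)
  # one call per record
  expect_equal(anyDuplicated(calls$record_id), 0L)
})

test_that("random non-coding contigs yield no functional calls", {
  set.seed(7)
  decoys <- seq_record(sprintf("d%03d", 1:100),
                       vapply(sample(800:1600, 100, TRUE), random_nt,
                              character(1)))
  scr <- screen_transcriptome(decoys)
  expect_equal(sum(tidy(scr)$status == "functional"), 0L)
})

test_that("screening is deterministic and writes its reports", {
  p <- synth_params(n_fad = 2, n_elovl = 2, n_pseudo = 1, n_partial = 1,
                    n_decoys = 5, seed = 50)
  sim <- make_transcriptome(p)
  out <- withr::local_tempdir()
  s1 <- screen_transcriptome(sim$contigs, out_dir = out)
  s2 <- screen_transcriptome(sim$contigs)
  expect_identical(tidy(s1), tidy(s2))
  expect_true(file.exists(file.path(out, "calls.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  # FASTA input path equals in-memory input
  fa <- file.path(out, "in.fasta")
  write_fasta(sim$contigs, fa)
  s3 <- screen_transcriptome(fa)
  expect_identical(tidy(s1), tidy(s3))
})
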