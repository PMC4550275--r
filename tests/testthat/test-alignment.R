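test_that("global_align handles identical and empty sequences", {
  s <- "MKWVTFISLL"
  ga <- global_align(seq_record("a", s), seq_record("b", s))
  expect_equal(ga$alignment$gapped, c(s, s), ignore_attr = TRUE)
  b62 <- scheme_protein()$matrix
  expect_equal(ga$score,
               sum(b62[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])]))
  ge <- global_align(seq_record("a", "ACGT"),
                     seq_record("b", "A"),   # nearly empty partner
                     scheme_clone_validation())
  expect_equal(nchar(ge$alignment$gapped[1]), nchar(ge$alignment$gapped[2]))
  # fully empty partner, free end gaps: all-gap row, score 0
  ge2 <- global_align("ACGT", stats::setNames("", "b"),
                      scheme_clone_validation())
  expect_equal(ge2$alignment$gapped[2], "----")
  expect_equal(ge2$score, 0)
})

test_that("global_align equals exhaustive alignment enumeration", {
  sp <- scheme_protein()
  sn <- scheme_nucleotide()
  set.seed(13)
  for (i in 1:20) {
    la <- sample(1:6, 1); lb <- sample(1:6, 1)
    a <- random_protein(la); b <- random_protein(lb)
    got <- global_align(stats::setNames(a, "a"), stats::setNames(b, "b"), sp)
    want <- enum_align_score(a, b, sp$matrix, sp$gap_open, sp$gap_extend)
    expect_equal(got$score, want)
    an <- random_nt(la); bn <- random_nt(lb)
    gotn <- global_align(stats::setNames(an, "a"), stats::setNames(bn, "b"), sn)
    expect_equal(gotn$score,
                 enum_align_score(an, bn, sn$matrix, sn$gap_open, sn$gap_extend))
  }
  # a couple of longer instances
  for (i in 1:2) {
    a <- random_protein(8); b <- random_protein(8)
    got <- global_align(stats::setNames(a, "a"), stats::setNames(b, "b"), sp)
    expect_equal(got$score,
                 enum_align_score(a, b, sp$matrix, sp$gap_open, sp$gap_extend))
  }
})

test_that("ungapping alignment rows reproduces the inputs", {
  set.seed(14)
  seqs <- seq_record(paste0("s", 1:5),
                     replicate(5, random_elovl_protein(294)),
                     alphabet = "protein")
  al <- progressive_msa(seqs)
  expect_equal(length(unique(nchar(al$gapped))), 1L)
  expect_equal(gsub("-", "", al$gapped), seqs$residues[match(al$id, seqs$id)])
})

test_that("progressive_msa reduces to global_align for two sequences and is
          gap-free for identical inputs", {
  s <- "MKWVTFISLLFLFSSAYS"
  al3 <- progressive_msa(seq_record(c("a", "b", "c"), rep(s, 3)))
  expect_equal(al3$gapped, rep(s, 3), ignore_attr = TRUE)
  set.seed(15)
  x <- random_protein(30); y <- random_protein(25)
  two <- seq_record(c("a", "b"), c(x, y), alphabet = "protein")
  expect_equal(progressive_msa(two)$gapped,
               global_align(two[1, ], two[2, ])$alignment$gapped)
  expect_error(progressive_msa(two[1, ]), "at least 2")
})

test_that("the 17 checklist columns align across synthetic Elovl homologs", {
  set.seed(16)
  seqs <- seq_record(paste0("e", 1:5),
                     replicate(5, random_elovl_protein(294)),
                     alphabet = "protein")
  ann <- builtin_elovl_annotation()
  ref <- default_elovl_reference()
  for (i in 1:5) {
    m <- map_reference_positions(ref, seqs[i, ], ann)
    expect_equal(sum(m$cand_residue == m$expected, na.rm = TRUE), 17L)
  }
})

test_that("conserved_columns matches a per-column scan and is monotone", {
  al <- tibble::tibble(id = c("a", "b"), gapped = c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(conserved_columns(al), 10L)
  al$gapped[2] <- "ACGTAAGTAC"   # one row differs at column 6
  expect_equal(conserved_columns(al), 9L)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:6, 1); L <- sample(10:40, 1)
    rows <- replicate(n, paste(sample(c("A", "C", "G", "-"), L, TRUE),
                               collapse = ""))
    al <- tibble::tibble(id = paste0("r", 1:n), gapped = rows)
    mat <- do.call(rbind, strsplit(rows, ""))
    oracle <- sum(apply(mat, 2, function(cl) {
      !any(cl == "-") && length(unique(cl)) == 1
    }))
    expect_equal(conserved_columns(al), oracle)
    # with gaps allowed, count can only grow
    expect_gte(conserved_columns(al, include_gapped = TRUE),
               conserved_columns(al))
  }
})

test_that("dropping the most divergent row never lowers the conserved count", {
  set.seed(18)
  base <- random_elovl_protein(294)
  near <- replicate(4, random_elovl_protein(294))
  outgroup <- random_protein(260)   # unrelated, plays the divergent outgroup
  with_og <- progressive_msa(seq_record(c(paste0("s", 1:5), "og"),
                                        c(base, near, outgroup),
                                        alphabet = "protein"))
  without <- progressive_msa(seq_record(paste0("s", 1:5), c(base, near),
                                        alphabet = "protein"))
  expect_gte(conserved_columns(without), conserved_columns(with_og))
  # adding a divergent row never increases the count on a fixed alignment
  sub <- with_og[with_og$id != "og", ]
  expect_gte(conserved_columns(sub, include_gapped = TRUE),
             conserved_columns(with_og, include_gapped = TRUE))
})

test_that("map_reference_positions tracks insertions and deletions", {
  set.seed(19)
  refseq <- random_elovl_protein(294)
  ref <- seq_record("ref", refseq, alphabet = "protein")
  ann <- builtin_elovl_annotation()
  # identity
  m0 <- map_reference_positions(ref, ref, ann)
  expect_equal(m0$cand_pos, m0$ref_pos)
  # 5 residues inserted before position 100 shift later positions by +5
  cand <- seq_record("ins", paste0(substr(refseq, 1, 99), "WWWWW",
                                   substr(refseq, 100, 294)),
                     alphabet = "protein")
  m1 <- map_reference_positions(ref, cand, ann)
  expect_equal(m1$cand_pos[m1$ref_pos >= 100], m1$ref_pos[m1$ref_pos >= 100] + 5L)
  expect_equal(m1$cand_pos[m1$ref_pos < 100], m1$ref_pos[m1$ref_pos < 100])
  # deletion spanning position 137 maps to unaligned
  del <- seq_record("del", paste0(substr(refseq, 1, 133),
                                  substr(refseq, 142, 294)),
                    alphabet = "protein")
  m2 <- map_reference_positions(ref, del, ann)
  expect_true(is.na(m2$cand_pos[m2$ref_pos == 137]))
  expect_error(
    map_reference_positions(seq_record("short", "MKWV", alphabet = "protein"),
                            ref, ann),
    "beyond reference length"
  )
  # annotation/reference disagreement warns but proceeds
  bad_ann <- parse_residue_annotation("2W")
  expect_warning(map_reference_positions(ref, ref, bad_ann), "differ")
})
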