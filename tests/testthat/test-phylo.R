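test_that("count_PQ classifies substitutions and skips gaps/N", {
  expect_equal(count_PQ("ACGT", "ACGT"), list(P = 0, Q = 0, n_sites = 4L))
  expect_equal(count_PQ("ACGT", "GCGT"), list(P = 0.25, Q = 0, n_sites = 4L))
  expect_equal(count_PQ("A-GT", "ANGT")$n_sites, 3L)
  expect_equal(count_PQ("--", "AC")$n_sites, 0L)
  set.seed(20)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    a <- paste(sample(c("A", "C", "G", "T", "-", "N"), n, TRUE,
                      prob = c(.22, .22, .22, .22, .06, .06)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-", "N"), n, TRUE,
                      prob = c(.22, .22, .22, .22, .06, .06)), collapse = "")
    expect_equal(count_PQ(a, b), oracle_PQ(a, b))
  }
})

test_that("K2P distance evaluates its closed form and flags saturation", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # 4000 sites with exactly 400 transitions and 200 transversions:
  # P = 0.1, Q = 0.05 -> d ~= 0.1702
  a <- strrep("A", 4000)
  b <- paste0(strrep("G", 400), strrep("C", 200), strrep("A", 3400))
  d <- k2p_distance(a, b)
  expect_equal(d, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_equal(round(d, 4), 0.1702)
  # cross-check against an independent implementation
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  rownames(m) <- c("a", "b")
  expect_equal(d, as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80")),
               tolerance = 1e-12)
  # Q = 0 reduces to the pure-transition form
  b2 <- paste0(strrep("G", 400), strrep("A", 3600))
  expect_equal(k2p_distance(a, b2), -0.5 * log(1 - 0.2) - 0.25 * log(1))
  # saturation
  expect_true(is.na(k2p_distance(strrep("A", 10), strrep("G", 10))))
})

test_that("Tamura-3 reduces to K2P at theta = 0.5 and matches ape's T92", {
  a <- paste0(strrep("A", 1500), strrep("G", 1500), strrep("C", 500),
              strrep("T", 500))
  set.seed(21)
  bchars <- strsplit(a, "")[[1]]
  idx <- sample(4000, 300)
  bchars[idx] <- vapply(bchars[idx], function(x) {
    switch(x, A = "G", G = "A", C = "T", T = "C")
  }, character(1))
  b <- paste(bchars, collapse = "")
  expect_equal(tamura3_distance(a, b, theta = 0.5), k2p_distance(a, b))
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  rownames(m) <- c("a", "b")
  expect_equal(tamura3_distance(a, b),
               as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "T92")),
               tolerance = 1e-12)
  expect_equal(tamura3_distance("ACGT", "ACGT"), 0)
  # formula value at P=0.1, Q=0.05, theta=0.3
  aa <- strrep("A", 4000)
  bb <- paste0(strrep("G", 400), strrep("C", 200), strrep("A", 3400))
  h <- 2 * 0.3 * 0.7
  expect_equal(tamura3_distance(aa, bb, theta = 0.3),
               -h * log(1 - 0.1 / h - 0.05) - 0.5 * (1 - h) * log(1 - 0.1))
})

test_that("distance ordering p <= K2P holds where finite", {
  set.seed(22)
  t2 <- ape::read.tree(text = "(a:0.15,b:0.15);")
  al <- simulate_alignment(t2, model_params("k2p", kappa = 3), 2000)
  p_dist <- mean(strsplit(al$gapped[1], "")[[1]] != strsplit(al$gapped[2], "")[[1]])
  expect_gte(k2p_distance(al$gapped[1], al$gapped[2]), p_dist)
})

test_that("neighbor joining recovers additive trees exactly", {
  # 3 taxa: three-point formulas
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$tip.label), c("a", "b", "c"))
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  set.seed(23)
  for (i in 1:5) {
    tr <- ape::rtree(6 + i)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.4)
    D <- stats::cophenetic(tr)
    nj_t <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(nj_t, ape::unroot(tr)), 0)
    # permutation invariance of the unrooted topology
    perm <- sample(nrow(D))
    nj_p <- neighbor_joining(D[perm, perm])
    expect_equal(phangorn::RF.dist(nj_t, nj_p), 0)
  }
  expect_error(neighbor_joining(D3[1:2, 1:2]), ">= 3")
  Dna <- D3; Dna["a", "b"] <- Dna["b", "a"] <- NA
  expect_warning(expect_error(neighbor_joining(Dna), ">= 3"), "dropping")
})

test_that("pruning likelihood equals brute-force state enumeration", {
  # 2 taxa, 1 site, equal bases, zero branch: log stationary frequency
  t2 <- ape::read.tree(text = "(a:0,b:0);")
  al2 <- tibble::tibble(id = c("a", "b"), gapped = c("A", "A"))
  expect_equal(tree_log_likelihood(t2, al2, model_params("k2p"), ncat = 1),
               log(0.25))
  set.seed(24)
  t4 <- ape::read.tree(text = "((a:0.1,b:0.25):0.07,(c:0.18,d:0.12):0.07);")
  for (kappa in c(1, 2, 4)) {
    al <- simulate_alignment(t4, model_params("k2p", kappa = kappa), 10)
    mine <- tree_log_likelihood(t4, al, model_params("k2p", kappa = kappa),
                                ncat = 1)
    expect_equal(mine, enum_log_likelihood(t4, al, kappa), tolerance = 1e-10)
  }
  # 5 taxa with missing data
  t5 <- ape::read.tree(
    text = "(((a:0.1,b:0.2):0.05,c:0.15):0.05,(d:0.1,e:0.3):0.05);")
  al5 <- simulate_alignment(t5, model_params("k2p", kappa = 2), 8)
  substr(al5$gapped[2], 3, 4) <- "NN"
  expect_equal(tree_log_likelihood(t5, al5, model_params("k2p", kappa = 2),
                                   ncat = 1),
               enum_log_likelihood(t5, al5, 2), tolerance = 1e-10)
  expect_error(tree_log_likelihood(t5, al5[1:4, ], model_params()), "leaf")
})

test_that("pruning likelihood matches phangorn and is rooting-invariant", {
  set.seed(25)
  t4 <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.05);")
  al <- simulate_alignment(t4, model_params("k2p", kappa = 2), 60)
  m <- model_params("k2p", kappa = 2, alpha = 0.7, p_inv = 0)
  mine <- tree_log_likelihood(t4, al, m, ncat = 4)
  mat <- do.call(rbind, strsplit(al$gapped, ""))
  rownames(mat) <- al$id
  fit <- phangorn::pml(t4, phangorn::phyDat(mat), model = "K80",
                       k = 4, shape = 0.7)
  fit <- update(fit, Q = c(1, 2, 1, 1, 2, 1))
  expect_equal(mine, fit$logLik, tolerance = 1e-8)
  # pulley principle: rerooting leaves the likelihood unchanged
  rerooted <- ape::root(ape::unroot(t4), "c", resolve.root = TRUE)
  expect_equal(tree_log_likelihood(rerooted, al, m, ncat = 4), mine,
               tolerance = 1e-10)
  # invariant + gamma mixture still a proper likelihood
  m2 <- model_params("t92", kappa = 2, theta = 0.4, alpha = 1, p_inv = 0.2)
  expect_lt(tree_log_likelihood(t4, al, m2, ncat = 4), 0)
})

test_that("NNI search is monotone and recovers a perturbed 6-taxon topology", {
  set.seed(26)
  true6 <- ape::read.tree(
    text = "(((a:0.1,b:0.1):0.08,c:0.18):0.04,((d:0.1,e:0.1):0.08,f:0.18):0.04);")
  m <- model_params("k2p", kappa = 2)
  al <- simulate_alignment(true6, m, 2000)
  # start at the NJ tree (equals truth under this signal): no move accepted
  start <- neighbor_joining(dist_matrix(al, "k2p"))
  expect_equal(phangorn::RF.dist(start, ape::unroot(true6)), 0)
  res0 <- nni_search(start, al, m, ncat = 1, max_rounds = 5)
  expect_equal(phangorn::RF.dist(res0$tree, ape::unroot(true6)), 0)
  expect_length(res0$trace, 1L)
  # start from a one-NNI perturbation: truth recovered, monotone trace
  pert <- phangorn::nni(start)[[1]]
  pert <- phangorn::nnls.tree(stats::as.dist(dist_matrix(al, "k2p")), pert,
                              method = "unrooted")
  res <- nni_search(pert, al, m, ncat = 1, max_rounds = 5)
  expect_equal(phangorn::RF.dist(res$tree, ape::unroot(true6)), 0)
  expect_true(all(diff(res$trace) >= 0))
})

test_that("bootstrap supports are reproducible and strong under strong signal", {
  set.seed(27)
  true6 <- ape::read.tree(
    text = "(((a:0.1,b:0.1):0.08,c:0.18):0.04,((d:0.1,e:0.1):0.08,f:0.18):0.04);")
  al <- simulate_alignment(true6, model_params("k2p", kappa = 2), 2000)
  bt <- bootstrap_support(al, B = 100, seed = 7)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  expect_true(all(sup[!is.na(sup)] >= 75))
  # same seed, same supports; near-degenerate columns give certainty
  bt2 <- bootstrap_support(al, B = 100, seed = 7)
  expect_identical(bt$node.label, bt2$node.label)
  # two seeds differ by at most Monte-Carlo error (binomial s.e. at B=100)
  bt3 <- bootstrap_support(al, B = 100, seed = 8)
  d <- abs(as.numeric(bt$node.label) - as.numeric(bt3$node.label))
  expect_true(all(d[!is.na(d)] <= 3 * 100 * sqrt(0.25 / 100) + 1))
  expect_equal(attr(bt, "B"), 100)
  # support suppression blanks weak values only
  bt$node.label <- c("60", "92", "88", "")
  expect_equal(suppress_weak_support(bt)$node.label, c("", "92", "88", ""))
})

test_that("newick write/read round-trips topology, lengths and supports", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  txt <- "((a:0.1,b:0.2)95:0.05,(c:0.15,d:0.1)88:0.05);"
  tr <- ape::read.tree(text = txt)
  write_newick(tr, tf)
  back <- read_newick(tf)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(back$edge.length, tr$edge.length)
  expect_equal(back$node.label, tr$node.label)
})

test_that("assign_clade follows support, label purity and the outgroup rule", {
  txt <- paste0("(((cand:0.1,d5ref:0.1)90:0.1,(e4ref:0.1,x:0.1)85:0.1)80:0.1,",
                "og:0.5);")
  tr <- ape::read.tree(text = txt)
  refs <- c(d5ref = "delta-5", e4ref = "elovl4")
  got <- assign_clade(tr, "cand", refs, min_support = 75, outgroup = "og")
  expect_equal(got$clade, "delta-5")
  # low support withholds assignment
  low <- assign_clade(tr, "cand", refs, min_support = 95, outgroup = "og")
  expect_true(is.na(low$clade))
  # candidate sister to the outgroup: smallest ref clade spans the outgroup
  txt2 <- "(((d5ref:0.1,e4ref:0.1)90:0.1,x:0.1)85:0.1,(cand:0.1,og:0.1)99:0.1);"
  tr2 <- ape::read.tree(text = txt2)
  got2 <- assign_clade(tr2, "cand", refs, outgroup = "og")
  expect_true(is.na(got2$clade))
  # mixed labels in the smallest clade
  txt3 <- "((cand:0.1,(d5ref:0.1,e4ref:0.1)90:0.1)95:0.1,og:0.5);"
  got3 <- assign_clade(ape::read.tree(text = txt3), "cand", refs,
                       outgroup = "og")
  expect_true(is.na(got3$clade))
  expect_match(got3$reason, "mixed")
  expect_error(assign_clade(tr, "absent", refs), "not in tree")
})

test_that("simulated alignments recover model parameters", {
  # zero-length branches: all leaves identical
  t3 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  al0 <- simulate_alignment(t3, model_params("k2p"), 50, seed = 28)
  expect_equal(al0$gapped[1], al0$gapped[2])
  expect_equal(al0$gapped[1], al0$gapped[3])
  # two-taxon K2P estimator consistency at d = 0.2, n = 10000
  t2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  al <- simulate_alignment(t2, model_params("k2p", kappa = 4), 10000, seed = 3)
  d_hat <- k2p_distance(al$gapped[1], al$gapped[2])
  se <- 0.2 / sqrt(10000)   # order-of-magnitude s.e. for the estimator
  expect_lt(abs(d_hat - 0.2), 3 * 0.02)
  # transition:transversion counts at kappa = 4 within binomial tolerance
  pq <- count_PQ(al$gapped[1], al$gapped[2])
  P_exp <- k2p_pmat_closed(0.2, 4)["A", "G"]
  Q_exp <- 2 * k2p_pmat_closed(0.2, 4)["A", "C"]
  expect_lt(abs(pq$P - P_exp), 3 * sqrt(P_exp * (1 - P_exp) / 10000))
  expect_lt(abs(pq$Q - Q_exp), 3 * sqrt(Q_exp * (1 - Q_exp) / 10000))
})
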