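# Independent oracles and small generators used across the suite.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
NT4 <- c("A", "C", "G", "T")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_nt <- function(n) paste(sample(NT4, n, replace = TRUE), collapse = "")

# exhaustive enumeration of all affine-gap global alignments (no DP): the
# oracle for global_align() on short sequences
enum_align_score <- function(a, b, submat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, "M", acc + submat[A[i], B[j]])
    }
    if (i <= length(A)) {
      rec(i + 1L, j, "X",
          acc - (if (identical(last, "X")) 0 else gap_open) - gap_extend)
    }
    if (j <= length(B)) {
      rec(i, j + 1L, "Y",
          acc - (if (identical(last, "Y")) 0 else gap_open) - gap_extend)
    }
  }
  rec(1L, 1L, "M", 0)
  best
}

# window-by-window motif checker: the oracle for scan_motif()
oracle_scan <- function(protein, pattern) {
  chars <- strsplit(protein, "")[[1]]
  k <- pattern$length
  hits <- integer()
  if (length(chars) >= k) {
    for (s in 1:(length(chars) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        allowed <- pattern$positions[[j]]
        if (length(allowed) == 1L && is.na(allowed)) next
        if (!chars[s + j - 1L] %in% allowed) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s - 1L)
    }
  }
  hits
}

# per-column transition/transversion classifier: the oracle for count_PQ()
oracle_PQ <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(x)) {
    if (!x[i] %in% NT4 || !y[i] %in% NT4) next
    n <- n + 1L
    if (x[i] == y[i]) next
    pair <- sort(c(x[i], y[i]))
    if (identical(pair, c("A", "G")) || identical(pair, c("C", "T"))) {
      ts <- ts + 1L
    } else {
      tv <- tv + 1L
    }
  }
  list(P = if (n) ts / n else NA_real_, Q = if (n) tv / n else NA_real_,
       n_sites = n)
}

# closed-form K2P transition probabilities (independent of the package's
# eigendecomposition machinery); rate matrix normalised to mean rate 1
k2p_pmat_closed <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  trans <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv <- 0.25 - 0.25 * e1
  bases <- c("A", "C", "G", "T")
  P <- matrix(tv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- same
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- trans
  P
}

# brute-force likelihood by summation over all internal-state assignments
# (K2P, single rate class); the oracle for tree_log_likelihood()
enum_log_likelihood <- function(tree, al, kappa) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  rows <- al$gapped[match(tree$tip.label, al$id)]
  mat <- do.call(rbind, strsplit(rows, ""))
  bases <- c("A", "C", "G", "T")
  P_edge <- lapply(tree$edge.length, k2p_pmat_closed, kappa = kappa)
  n_sites <- ncol(mat)
  total <- 0
  states <- as.matrix(expand.grid(rep(list(1:4), nint)))
  for (site in seq_len(n_sites)) {
    lik <- 0
    obs <- match(mat[, site], bases)   # NA = missing
    for (r in seq_len(nrow(states))) {
      node_state <- c(obs, states[r, ])
      prod_p <- 0.25   # stationary frequency at the root
      ok <- TRUE
      for (e in seq_len(nrow(tree$edge))) {
        ps <- node_state[tree$edge[e, 1]]
        cs <- node_state[tree$edge[e, 2]]
        if (is.na(cs)) next   # missing tip: marginalise by skipping? no --
        prod_p <- prod_p * P_edge[[e]][ps, cs]
        if (prod_p == 0) { ok <- FALSE; break }
      }
      if (ok) lik <- lik + prod_p
    }
    total <- total + log(lik)
  }
  total
}

# one lesion-free synthetic Elovl protein (current RNG state)
random_elovl_protein <- function(len = 294L) make_elovl_protein(len)$aa
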