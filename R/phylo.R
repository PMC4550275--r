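#' Count transition and transversion proportions between two aligned rows
#'
#' Columns with a gap or `N` in either row are skipped. Transitions are
#' A<->G and C<->T; everything else that differs is a transversion.
#'
#' @param a,b equal-length gapped nucleotide strings.
#' @return A list with `P` (transition proportion), `Q` (transversion
#'   proportion) and `n_sites` (compared columns). `n_sites = 0` signals an
#'   undefined distance.
#' @examples
#' count_PQ("ACGT", "GCGT")
#' @export
count_PQ <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y)) stop("rows differ in length")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) return(list(P = NA_real_, Q = NA_real_, n_sites = 0L))
  diff <- x != y
  purine <- c("A", "G")
  ts <- diff & (x %in% purine) == (y %in% purine)
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n_sites = n)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P`/`Q` the observed
#' transition/transversion proportions. Saturated pairs (logarithm argument
#' <= 0) yield `NA` rather than an error.
#'
#' @inheritParams count_PQ
#' @return numeric distance, or `NA` on saturation / zero comparable columns.
#' @export
k2p_distance <- function(a, b) {
  pq <- count_PQ(a, b)
  if (pq$n_sites == 0L) return(NA_real_)
  w1 <- 1 - 2 * pq$P - pq$Q
  w2 <- 1 - 2 * pq$Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Tamura 3-parameter distance
#'
#' Extends the Kimura 2-parameter distance with a G+C-content correction
#' `h = 2 * theta * (1 - theta)`:
#' `d = -h * log(1 - P/h - Q) - 1/2 * (1 - h) * log(1 - 2Q)`.
#' `theta` defaults to the mean G+C content of the pair over the compared
#' columns; at `theta = 0.5` the distance reduces exactly to
#' [k2p_distance()].
#'
#' @inheritParams count_PQ
#' @param theta G+C content in (0, 1); `NULL` (default) estimates it from the
#'   pair.
#' @return numeric distance, or `NA` on saturation.
#' @export
tamura3_distance <- function(a, b, theta = NULL) {
  pq <- count_PQ(a, b)
  if (pq$n_sites == 0L) return(NA_real_)
  if (is.null(theta)) {
    x <- strsplit(toupper(paste0(a, b)), "")[[1]]
    x <- x[x %in% c("A", "C", "G", "T")]
    theta <- mean(x %in% c("G", "C"))
  }
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  h <- 2 * theta * (1 - theta)
  w1 <- 1 - pq$P / h - pq$Q
  w2 <- 1 - 2 * pq$Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -h * log(w1) - 0.5 * (1 - h) * log(w2)
}

#' Model distance matrix from an alignment
#'
#' @param al alignment tibble (`id`, `gapped`), nucleotide.
#' @param model `"k2p"` or `"t92"`.
#' @return A labelled symmetric matrix with zero diagonal; saturated pairs
#'   are `NA`.
#' @export
dist_matrix <- function(al, model = c("k2p", "t92")) {
  model <- match.arg(model)
  fn <- if (model == "k2p") k2p_distance else tamura3_distance
  n <- nrow(al)
  D <- matrix(0, n, n, dimnames = list(al$id, al$id))
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- fn(al$gapped[i], al$gapped[j])
  }
  D
}

#' Neighbor joining
#'
#' Standard NJ agglomeration on a labelled distance matrix (exact on additive
#' matrices). Pairs with undefined (saturated) distances cannot enter NJ:
#' labels are dropped greedily (most-NA first, ties by label order) with a
#' warning until the matrix is finite.
#'
#' @param D labelled symmetric distance matrix.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  while (anyNA(D)) {
    na_count <- rowSums(is.na(D))
    drop <- rownames(D)[order(-na_count, rownames(D))][1]
    warning("dropping '", drop, "' from NJ: undefined (saturated) distances")
    keep <- rownames(D) != drop
    D <- D[keep, keep, drop = FALSE]
  }
  if (nrow(D) < 3L) stop("neighbor_joining() needs >= 3 labels with finite distances")
  if (nrow(D) == 3L) return(.nj3(D))
  ape::nj(stats::as.dist(D))
}

#' Substitution-model parameters for the likelihood engine
#'
#' @param model `"k2p"` (equal base frequencies) or `"t92"` (frequencies set
#'   by G+C content `theta`).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param theta G+C content for `"t92"`.
#' @param alpha discrete-gamma shape (> 0); `Inf` disables rate variation.
#' @param p_inv proportion of invariant sites in [0, 1).
#' @return A list of class `model_params`.
#' @export
model_params <- function(model = c("k2p", "t92"), kappa = 2, theta = 0.5,
                         alpha = Inf, p_inv = 0) {
  model <- match.arg(model)
  stopifnot(kappa > 0, theta > 0, theta < 1, alpha > 0,
            p_inv >= 0, p_inv < 1)
  structure(list(model = model, kappa = kappa, theta = theta,
                 alpha = alpha, p_inv = p_inv),
            class = "model_params")
}

# stationary frequencies in A, C, G, T order
.model_freqs <- function(m) {
  if (m$model == "k2p") rep(0.25, 4)
  else c((1 - m$theta) / 2, m$theta / 2, m$theta / 2, (1 - m$theta) / 2)
}

# reversible rate matrix (rows A,C,G,T), normalised to mean rate 1,
# eigen-decomposed for fast P(t)
.model_eigen <- function(m) {
  pi <- .model_freqs(m)
  bases <- c("A", "C", "G", "T")
  is_ts <- function(i, j) (bases[i] %in% c("A", "G")) == (bases[j] %in% c("A", "G"))
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    Q[i, j] <- (if (is_ts(i, j)) m$kappa else 1) * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(pi = pi, values = e$values,
       right = diag(1 / s) %*% e$vectors,
       left = t(e$vectors) %*% diag(s))
}

.pmat <- function(ed, t) {
  # P(t) = right %*% diag(exp(lambda t)) %*% left; rows sum to 1
  P <- ed$right %*% (exp(ed$values * t) * ed$left)
  P[P < 0] <- 0
  P
}

# discrete-gamma category rates (mean 1), equal-probability bins
.gamma_rates <- function(alpha, ncat) {
  if (!is.finite(alpha)) return(rep(1, ncat))
  qb <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha,
                      rate = alpha)
  ncat * (stats::pgamma(qb[-1], shape = alpha + 1, rate = alpha) -
            stats::pgamma(qb[-(ncat + 1)], shape = alpha + 1, rate = alpha))
}

# rate mixture: invariant class + mean-normalised gamma categories
.rate_mixture <- function(m, ncat) {
  rates <- .gamma_rates(m$alpha, ncat)
  if (m$p_inv > 0) {
    list(rates = c(0, rates / (1 - m$p_inv)),
         weights = c(m$p_inv, rep((1 - m$p_inv) / ncat, ncat)))
  } else {
    list(rates = rates, weights = rep(1 / ncat, ncat))
  }
}

.alignment_patterns <- function(al, labels) {
  rows <- al$gapped[match(labels, al$id)]
  if (anyNA(rows)) stop("leaf without alignment row: ",
                        paste(labels[is.na(rows)], collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  key <- apply(mat, 2, paste, collapse = "")
  uniq <- !duplicated(key)
  list(mat = mat[, uniq, drop = FALSE],
       weights = as.vector(table(key)[key[uniq]]))
}

#' Log-likelihood of a tree by Felsenstein pruning
#'
#' Pruning over alignment sites under a K2P- or T92-style reversible rate
#' matrix with an invariant-sites class and `ncat` discrete-gamma rate
#' categories (mixture mean-normalised to 1). Gaps and `N` are treated as
#' missing data. For a reversible model the value is invariant to the rooting
#' of an unrooted tree.
#'
#' @param tree a `phylo` tree with branch lengths; its tips must be a subset
#'   of the alignment rows.
#' @param al alignment tibble (`id`, `gapped`), nucleotide.
#' @param m a [model_params()] object.
#' @param ncat number of gamma categories (>= 1).
#' @return log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(tree, al, m = model_params(), ncat = 4) {
  stopifnot(inherits(tree, "phylo"), ncat >= 1)
  pat <- .alignment_patterns(al, tree$tip.label)
  ed <- .model_eigen(m)
  mix <- .rate_mixture(m, ncat)
  npat <- ncol(pat$mat)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  bases <- c("A", "C", "G", "T")
  # tip conditionals: 4 x npat, missing = all ones
  tipcond <- lapply(seq_len(ntip), function(i) {
    obs <- pat$mat[i, ]
    cond <- matrix(1, 4, npat)
    known <- obs %in% bases
    cond[, known] <- 0
    cond[cbind(match(obs[known], bases), which(known))] <- 1
    cond
  })
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  site_lik <- rep(0, npat)  # mixture-accumulated site likelihoods
  for (c_i in seq_along(mix$rates)) {
    rate <- mix$rates[c_i]
    scale_log <- rep(0, npat)
    pmats <- lapply(tree$edge.length, function(b) .pmat(ed, b * rate))
    down <- function(node) {
      if (node <= ntip) return(tipcond[[node]])
      cond <- matrix(1, 4, npat)
      for (e in children[[as.character(node)]]) {
        child_cond <- down(tree$edge[e, 2])
        cond <- cond * (pmats[[e]] %*% child_cond)
      }
      mx <- apply(cond, 2, max)
      mx[mx == 0] <- 1
      scale_log <<- scale_log + log(mx)
      sweep(cond, 2, mx, "/")
    }
    root_cond <- down(root)
    site_lik <- site_lik +
      mix$weights[c_i] * colSums(ed$pi * root_cond) * exp(scale_log)
  }
  sum(pat$weights * log(site_lik))
}

#' NNI hill climbing on the pruning likelihood
#'
#' Starting from a tree (typically NJ), repeatedly evaluates all
#' nearest-neighbour-interchange rearrangements, assigns each candidate
#' branch lengths by non-negative least squares against the model distance
#' matrix, and accepts the best strictly improving move until no move
#' improves or `max_rounds` is reached. The accepted-move likelihood trace is
#' non-decreasing by construction.
#'
#' @param tree starting `phylo` tree (>= 4 tips, with branch lengths).
#' @param al alignment tibble.
#' @param m [model_params()].
#' @param ncat gamma categories.
#' @param max_rounds maximum accepted moves (default 20).
#' @return A list with `tree` (the final tree), `log_likelihood`, and `trace`
#'   (likelihoods after each accepted move, starting value first).
#' @export
nni_search <- function(tree, al, m = model_params(), ncat = 4,
                       max_rounds = 20) {
  stopifnot(inherits(tree, "phylo"))
  D <- dist_matrix(al[al$id %in% tree$tip.label, ],
                   model = if (m$model == "t92") "t92" else "k2p")
  fit_bl <- function(tr) phangorn::nnls.tree(stats::as.dist(D), tr,
                                             method = "unrooted")
  cur <- fit_bl(tree)
  cur_ll <- tree_log_likelihood(cur, al, m, ncat)
  trace <- cur_ll
  for (round in seq_len(max_rounds)) {
    cands <- phangorn::nni(cur)
    lls <- vapply(cands, function(tr) {
      tree_log_likelihood(fit_bl(tr), al, m, ncat)
    }, numeric(1))
    if (max(lls) <= cur_ll + 1e-9) break
    cur <- fit_bl(cands[[which.max(lls)]])
    cur_ll <- max(lls)
    trace <- c(trace, cur_ll)
  }
  list(tree = cur, log_likelihood = cur_ll, trace = trace)
}

#' Bootstrap clade support
#'
#' Resamples alignment columns with replacement `B` times, rebuilds a tree
#' with `builder` for each replicate, and annotates each internal edge of the
#' point-estimate tree with the percentage of replicates containing the same
#' bipartition (stored in `node.label`).
#'
#' @param al alignment tibble.
#' @param B number of replicates (>= 1).
#' @param seed integer seed for the column resampling.
#' @param builder function(alignment tibble) -> `phylo`; default NJ on K2P
#'   distances.
#' @return An object of class `lcpufa_tree`/`phylo`: the point-estimate tree
#'   with percentage supports in `node.label` and attribute `B`.
#' @export
bootstrap_support <- function(al, B = 1000, seed = 1,
                              builder = function(a) neighbor_joining(dist_matrix(a, "k2p"))) {
  stopifnot(B >= 1)
  point <- builder(al)
  ncolumns <- nchar(al$gapped[1])
  mat <- do.call(rbind, strsplit(al$gapped, ""))
  set.seed(as.integer(seed))
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncolumns, ncolumns, replace = TRUE)
    rep_al <- tibble::tibble(
      id = al$id,
      gapped = apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    )
    reps[[b]] <- builder(rep_al)
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- as.character(round(100 * counts / B))
  attr(point, "B") <- B
  class(point) <- c("lcpufa_tree", "phylo")
  point
}

#' Suppress weak bootstrap supports
#'
#' Blanks internal-node support labels below `min_support` (reporting
#' convention: values under 75% not shown).
#'
#' @param tree a `phylo` with numeric `node.label` supports.
#' @param min_support threshold in percent (default 75).
#' @return the tree with weak labels replaced by `""`.
#' @export
suppress_weak_support <- function(tree, min_support = 75) {
  if (is.null(tree$node.label)) return(tree)
  v <- suppressWarnings(as.numeric(tree$node.label))
  tree$node.label[!is.na(v) & v < min_support] <- ""
  tree
}

#' Assign a candidate leaf to a reference-anchored clade
#'
#' After rooting (explicit outgroup leaf if given, else midpoint), finds the
#' smallest clade containing the candidate and at least one labelled
#' reference. The clade's label is returned iff all labelled references
#' inside agree, the clade does not span the outgroup, and the subtending
#' edge's bootstrap support is at least `min_support` (edges without a
#' numeric support annotation are not used to withhold assignment).
#'
#' @param tree a `phylo` tree (supports in `node.label` if available).
#' @param candidate candidate leaf label (must be in the tree).
#' @param ref_labels named character vector: leaf label -> clade name.
#' @param min_support support threshold in percent (default 75).
#' @param outgroup optional outgroup leaf label used for rooting.
#' @return A list with `clade` (clade name or `NA`) and `reason`.
#' @export
assign_clade <- function(tree, candidate, ref_labels, min_support = 75,
                         outgroup = NULL) {
  if (!candidate %in% tree$tip.label) stop("candidate not in tree: ", candidate)
  refs <- intersect(names(ref_labels), tree$tip.label)
  if (!length(refs)) stop("no labelled reference present in tree")
  rooted <- if (!is.null(outgroup) && outgroup %in% tree$tip.label) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
  ntip <- length(rooted$tip.label)
  tip <- match(candidate, rooted$tip.label)
  anc <- phangorn::Ancestors(rooted, tip, "all")
  for (node in anc) {
    tips <- rooted$tip.label[unlist(phangorn::Descendants(rooted, node, "tips"))]
    inside <- intersect(tips, refs)
    if (!length(inside)) next
    labels_inside <- unique(unname(ref_labels[inside]))
    if (!is.null(outgroup) && outgroup %in% tips) {
      return(list(clade = NA_character_, reason = "smallest reference clade spans the outgroup"))
    }
    if (length(labels_inside) > 1L) {
      return(list(clade = NA_character_,
                  reason = paste("mixed reference labels:",
                                 paste(labels_inside, collapse = ", "))))
    }
    lab <- rooted$node.label[node - ntip]
    support <- suppressWarnings(as.numeric(lab))
    if (!is.na(support) && support < min_support) {
      return(list(clade = NA_character_,
                  reason = paste0("support ", support, " below ", min_support)))
    }
    return(list(clade = labels_inside, reason = "ok"))
  }
  list(clade = NA_character_, reason = "no reference-containing clade")
}

#' Read and write Newick trees
#'
#' Thin wrappers (bootstrap supports travel as internal-node labels).
#'
#' @param tree a `phylo`.
#' @param path file path.
#' @return `read_newick()`: a `phylo`; `write_newick()`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  class(tree) <- "phylo"
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
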