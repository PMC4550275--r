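#' Tidy a screening result
#'
#' One row per contig call, without the nested evidence/ORF columns.
#'
#' @param x an `lcpufa_screen` object.
#' @param ... unused.
#' @return tibble.
#' @exportS3Method generics::tidy
tidy.lcpufa_screen <- function(x, ...) {
  dplyr::select(x$calls, -"evidence", -"orf")
}

#' @rdname tidy.lcpufa_screen
#' @exportS3Method generics::glance
glance.lcpufa_screen <- function(x, ...) {
  calls <- x$calls
  tibble::tibble(
    n_contigs = nrow(calls),
    n_functional = sum(calls$status == "functional"),
    n_fad_functional = sum(calls$status == "functional" & calls$family == "Fad"),
    n_elovl_functional = sum(calls$status == "functional" & calls$family == "Elovl"),
    n_pseudogene = sum(calls$status == "putative_pseudogene"),
    n_partial = sum(calls$status == "partial"),
    n_rejected = sum(calls$status == "rejected")
  )
}

#' Plot a screening result
#'
#' Bar chart of call counts per family and status.
#'
#' @param object an `lcpufa_screen` object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lcpufa_screen <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$status != "rejected" |
                        .data$family != "none")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, fill = .data$family)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = NULL, y = "contigs", fill = "family",
                  title = "Candidate calls by family and status") +
    ggplot2::theme_minimal()
}

#' Tidy a bootstrap-annotated tree
#'
#' One row per edge with child label (for tip edges) and bootstrap support of
#' the subtended clade (for internal edges).
#'
#' @param x an `lcpufa_tree` (from [bootstrap_support()]) or plain `phylo`.
#' @param ... unused.
#' @return tibble with `parent`, `node`, `branch_length`, `is_tip`, `label`,
#'   `support`.
#' @exportS3Method generics::tidy
tidy.lcpufa_tree <- function(x, ...) {
  ntip <- length(x$tip.label)
  node <- x$edge[, 2]
  support <- rep(NA_real_, length(node))
  if (!is.null(x$node.label)) {
    internal <- node > ntip
    support[internal] <-
      suppressWarnings(as.numeric(x$node.label[node[internal] - ntip]))
  }
  tibble::tibble(
    parent = x$edge[, 1], node = node,
    branch_length = x$edge.length %||% rep(NA_real_, length(node)),
    is_tip = node <= ntip,
    label = ifelse(node <= ntip, x$tip.label[pmin(node, ntip)], NA_character_),
    support = support
  )
}

#' @rdname tidy.lcpufa_tree
#' @exportS3Method generics::glance
glance.lcpufa_tree <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_tips = sum(td$is_tip),
    n_internal_edges = sum(!td$is_tip),
    bootstrap_B = attr(x, "B") %||% NA_integer_,
    min_support = suppressWarnings(min(td$support, na.rm = TRUE)),
    median_support = stats::median(td$support, na.rm = TRUE)
  )
}

#' Plot a bootstrap-annotated tree
#'
#' Rectangular phylogram with tip labels and internal-edge bootstrap
#' supports; supports below `min_support` are not drawn.
#'
#' @param object an `lcpufa_tree` or `phylo`.
#' @param min_support suppress support labels below this value (default 75).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lcpufa_tree <- function(object, min_support = 75, ...) {
  tr <- object
  class(tr) <- "phylo"
  if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
  ntip <- length(tr$tip.label)
  xx <- ape::node.depth.edgelength(tr)
  yy <- ape::node.height(tr)
  seg <- tibble::tibble(
    x = xx[tr$edge[, 1]], xend = xx[tr$edge[, 2]],
    y = yy[tr$edge[, 2]], yend = yy[tr$edge[, 2]]
  )
  vseg <- tibble::tibble(
    x = xx[tr$edge[, 1]], xend = xx[tr$edge[, 1]],
    y = yy[tr$edge[, 1]], yend = yy[tr$edge[, 2]]
  )
  tips <- tibble::tibble(x = xx[1:ntip], y = yy[1:ntip], label = tr$tip.label)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_segment(data = vseg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.25))) +
    ggplot2::labs(x = "substitutions per site", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    nodes <- (ntip + 1):(ntip + tr$Nnode)
    lab <- tibble::tibble(x = xx[nodes], y = yy[nodes], support = sup)
    lab <- lab[!is.na(lab$support) & lab$support >= min_support, ]
    if (nrow(lab)) {
      p <- p + ggplot2::geom_text(
        data = lab, ggplot2::aes(x = .data$x, y = .data$y,
                                 label = .data$support),
        hjust = 1.1, vjust = -0.4, size = 2.8
      )
    }
  }
  p
}

#' Hydropathy plot with called transmembrane segments
#'
#' @param protein protein string.
#' @inheritParams tm_segments
#' @return a ggplot of the sliding-window profile with the threshold line and
#'   called segments shaded.
#' @export
plot_hydropathy <- function(protein, window = 19, threshold = 1.6,
                            min_len = 19, min_gap = 5) {
  prof <- hydropathy_profile(protein, window)
  segs <- tm_segments(protein, window, threshold, min_len, min_gap)
  offset <- (window - 1) / 2
  df <- tibble::tibble(position = seq_along(prof) + offset, hydropathy = prof)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$hydropathy)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "grey40")
  if (nrow(segs)) {
    p <- p + ggplot2::geom_rect(
      data = segs,
      ggplot2::aes(xmin = .data$start + 1, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "mean hydropathy (Kyte-Doolittle)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
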