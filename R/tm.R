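#' Kyte-Doolittle hydropathy scale
#'
#' Named per-residue hydropathy values (Kyte & Doolittle 1982); `X` and `*`
#' score 0.
#' @format named numeric vector of length 22.
#' @export
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0, `*` = 0
)

#' Sliding-window hydropathy profile
#'
#' Centred moving average of a per-residue hydropathy scale (Kyte-Doolittle by
#' default). The output has one value per window, length
#' `nchar(protein) - window + 1`; value `i` is the mean over residues
#' `i .. i + window - 1`.
#'
#' @param protein protein string.
#' @param window odd window width, at most the protein length (default 19,
#'   roughly one membrane-crossing helix).
#' @param scale named per-residue hydropathy vector; defaults to the
#'   Kyte-Doolittle scale shipped as `KD_SCALE`.
#' @return numeric vector of window means.
#' @examples
#' hydropathy_profile(strrep("I", 19), window = 19)
#' @export
hydropathy_profile <- function(protein, window = 19, scale = KD_SCALE) {
  protein <- toupper(protein)
  L <- nchar(protein)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > L) stop("window larger than protein (", L, " aa)")
  vals <- unname(scale[strsplit(protein, "")[[1]]])
  if (anyNA(vals)) stop("residue(s) missing from the hydropathy scale")
  as.numeric(stats::filter(vals, rep(1 / window, window), sides = 2))[
    seq((window + 1) %/% 2, L - (window - 1) %/% 2)
  ]
}

#' Call transmembrane segments from a hydropathy profile
#'
#' A deterministic hydropathy stand-in for an HMM-based transmembrane
#' predictor: maximal runs of window centres whose profile is at or above
#' `threshold` are extended to their full window extents, merged when
#' separated by fewer than `min_gap` residues, and discarded when shorter than
#' `min_len`. Only the segment count enters the downstream screen, so this
#' scanner deliberately does not model topology.
#'
#' @inheritParams hydropathy_profile
#' @param threshold minimum window-mean hydropathy (default 1.6).
#' @param min_len minimum segment length in residues (default 19).
#' @param min_gap segments closer than this are merged (default 5).
#' @return A tibble with columns `start`, `end` (0-based half-open protein
#'   coordinates) and `mean_hydropathy`; non-overlapping and sorted.
#' @export
tm_segments <- function(protein, window = 19, threshold = 1.6, min_len = 19,
                        min_gap = 5, scale = KD_SCALE) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          mean_hydropathy = numeric())
  if (nchar(protein) < window) return(empty)
  prof <- hydropathy_profile(protein, window, scale)
  hot <- prof >= threshold
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # window-start index i covers residues i .. i + window - 1 (1-based)
  seg <- tibble::tibble(start = starts[runs], end = ends[runs] + window - 1L)
  # merge segments separated by < min_gap residues
  merged <- list(seg[1, ])
  if (nrow(seg) > 1L) {
    for (i in 2:nrow(seg)) {
      last <- merged[[length(merged)]]
      if (seg$start[i] - last$end - 1L < min_gap) {
        merged[[length(merged)]]$end <- max(last$end, seg$end[i])
      } else {
        merged[[length(merged) + 1L]] <- seg[i, ]
      }
    }
  }
  seg <- dplyr::bind_rows(merged)
  seg <- seg[seg$end - seg$start + 1L >= min_len, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty)
  vals <- unname(scale[strsplit(toupper(protein), "")[[1]]])
  tibble::tibble(
    start = seg$start - 1L,
    end = seg$end,
    mean_hydropathy = vapply(seq_len(nrow(seg)), function(i) {
      mean(vals[seg$start[i]:seg$end[i]])
    }, numeric(1))
  )
}

#' Is a transmembrane-segment count consistent with a family?
#'
#' Fad desaturases are expected to carry 3-4 membrane-crossing segments,
#' Elovl elongases 5-7.
#'
#' @param count non-negative integer segment count.
#' @param family `"Fad"` or `"Elovl"`.
#' @return logical.
#' @examples
#' tm_count_ok(3, "Fad")
#' tm_count_ok(7, "Elovl")
#' @export
tm_count_ok <- function(count, family = c("Fad", "Elovl")) {
  family <- match.arg(family)
  stopifnot(count >= 0)
  if (family == "Fad") count >= 3 && count <= 4 else count >= 5 && count <= 7
}
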