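#' Position-specific scoring matrix (PSSM)
#'
#' A motif is stored as a `w x 4` matrix of per-position base probabilities
#' over (A, C, G, T), together with its provenance inside a bicluster
#' ensemble and the pseudocount used when the matrix is turned into
#' log-odds scores.
#'
#' @param prob Numeric matrix with 4 columns (A, C, G, T); each row must sum
#'   to 1 (within 1e-9) and contain no negative entries.
#' @param run_id,bicluster_id Provenance of the motif within an ensemble
#'   (optional).
#' @param motif_index Index of the motif within its bicluster (optional).
#' @param pseudocount Pseudocount mixed into the probabilities when scoring
#'   (default 0.001).
#' @return An object of class `pssm`.
#' @examples
#' m <- pssm(matrix(c(1, 0, 0, 0,
#'                    0, 0, 0, 1), nrow = 2, byrow = TRUE))
#' pssm_width(m)
#' @export
pssm <- function(prob, run_id = NA_character_, bicluster_id = NA_character_,
                 motif_index = NA_integer_, pseudocount = 0.001) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) stopf("a PSSM needs 4 columns (A, C, G, T), got %d", ncol(prob))
  if (nrow(prob) < 1) stopf("a PSSM needs at least one position")
  if (any(prob < 0)) stopf("PSSM probabilities must be non-negative")
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > 1e-9)) {
    stopf("PSSM row %d does not sum to 1 (sum = %.12f)", which.max(abs(rs - 1)), rs[which.max(abs(rs - 1))])
  }
  colnames(prob) <- DNA_BASES
  rownames(prob) <- NULL
  structure(
    list(prob = prob,
         provenance = list(run_id = run_id, bicluster_id = bicluster_id,
                           motif_index = motif_index),
         pseudocount = pseudocount),
    class = "pssm")
}

#' @exportS3Method base::print
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> width %d, provenance %s/%s[%s]\n",
              pssm_width(x),
              x$provenance$run_id, x$provenance$bicluster_id,
              x$provenance$motif_index))
  print(round(x$prob, 3))
  invisible(x)
}

#' Width (number of positions) of a PSSM
#' @param x A [pssm].
#' @export
pssm_width <- function(x) nrow(x$prob)

#' Reverse complement of a PSSM
#'
#' Reverses the column (position) order and swaps A with T and C with G.
#' @param x A [pssm].
#' @return A [pssm] of the same width.
#' @export
pssm_revcomp <- function(x) {
  p <- x$prob[rev(seq_len(nrow(x$prob))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(p) <- DNA_BASES
  out <- x
  out$prob <- p
  out
}

#' Consensus sequence of a PSSM
#' @param x A [pssm].
#' @return A character scalar over ACGT.
#' @export
pssm_consensus <- function(x) {
  paste(DNA_BASES[max.col(x$prob, ties.method = "first")], collapse = "")
}

#' Per-position information content of a PSSM
#'
#' @param x A [pssm].
#' @return Numeric vector, bits per position (2 minus the Shannon entropy of
#'   the base distribution).
#' @export
pssm_information <- function(x) {
  apply(x$prob, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Sample a sequence from a PSSM
#' @param x A [pssm].
#' @return A character scalar of length `pssm_width(x)`.
#' @noRd
pssm_sample <- function(x) {
  paste(apply(x$prob, 1, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}

# Column-shuffled copy (row/position order permuted); used for the motif
# similarity null model.
pssm_shuffle <- function(x) {
  out <- x
  out$prob <- x$prob[sample.int(nrow(x$prob)), , drop = FALSE]
  out
}

#' Align two PSSMs and compute their distance
#'
#' Slides one matrix across the other in both orientations (the reverse
#' complement reverses position order and swaps A/T and C/G) and, over all
#' relative offsets with at least `min_overlap` aligned positions, returns
#' the minimum of the mean per-position Euclidean distance between the
#' aligned probability rows.
#'
#' @param a,b [pssm] objects.
#' @param min_overlap Minimum number of aligned positions (default 6 nt).
#' @return A list with `distance`, `offset` (position of `b`'s first column
#'   relative to `a`'s first column, after any reverse complementation of
#'   `b`) and `orientation` (`"same"` or `"revcomp"`).
#' @examples
#' a <- pssm(matrix(rep(c(1, 0, 0, 0), 6), ncol = 4, byrow = TRUE))
#' pssm_distance(a, a)$distance
#' @export
pssm_distance <- function(a, b, min_overlap = 6) {
  wa <- pssm_width(a); wb <- pssm_width(b)
  if (max(wa, wb) < min_overlap) stopf("no admissible alignment: both widths < min_overlap (%d)", min_overlap)
  if (min(wa, wb) < min_overlap) stopf("no admissible alignment: motif of width %d shorter than min_overlap (%d)", min(wa, wb), min_overlap)
  best <- list(distance = Inf, offset = 0L, orientation = "same", overlap = 0L)
  for (orient in c("same", "revcomp")) {
    bm <- if (orient == "same") b$prob else pssm_revcomp(b)$prob
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      ia <- max(0L, off); ib <- max(0L, -off)
      len <- min(wa - ia, wb - ib)
      if (len < min_overlap) next
      d <- a$prob[ia + seq_len(len), , drop = FALSE] - bm[ib + seq_len(len), , drop = FALSE]
      dist <- mean(sqrt(rowSums(d * d)))
      if (dist < best$distance - 1e-15 ||
          (dist < best$distance + 1e-15 && len > best$overlap)) {
        best <- list(distance = dist, offset = as.integer(off),
                     orientation = orient, overlap = as.integer(len))
      }
    }
  }
  best
}

# Best distance per minimum-overlap class: element L - min_overlap + 1 is
# the minimum mean column distance over alignments with overlap >= L.
# Inf where no alignment of that overlap exists.
pssm_distance_by_overlap <- function(a, b, min_overlap = 6, max_overlap = NULL) {
  wa <- pssm_width(a); wb <- pssm_width(b)
  lmax <- max_overlap %||% min(wa, wb)
  best <- rep(Inf, lmax - min_overlap + 1)
  for (orient in 1:2) {
    bm <- if (orient == 1) b$prob else pssm_revcomp(b)$prob
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      ia <- max(0L, off); ib <- max(0L, -off)
      len <- min(wa - ia, wb - ib)
      if (len < min_overlap) next
      d <- a$prob[ia + seq_len(len), , drop = FALSE] - bm[ib + seq_len(len), , drop = FALSE]
      dist <- mean(sqrt(rowSums(d * d)))
      hi <- min(len, lmax) - min_overlap + 1
      upd <- seq_len(hi)
      best[upd] <- pmin(best[upd], dist)
    }
  }
  best
}
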