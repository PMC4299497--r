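#' Motif similarity network over an ensemble's PSSMs
#'
#' Computes all-vs-all [pssm_distance()] between motifs, assigns each pair
#' an empirical p-value against a null of column-shuffled PSSM pairs
#' matched on the observed width distribution, corrects across all pairs by
#' Benjamini-Hochberg, and keeps edges with q at or below `fdr`.
#'
#' The pair p-value is the fraction of null distances at or below the
#' observed distance (no +1 correction: a distance smaller than every null
#' draw is genuinely off the null's scale and gets p = 0).
#'
#' @param motifs List of [pssm] objects (e.g. [ensemble_motifs()]).
#' @param fdr Edge FDR threshold (default 0.01).
#' @param min_overlap Minimum alignment overlap in nt (default 6).
#' @param n_null Number of null (column-shuffled) pairs (default 1000;
#'   fewer than 100 is refused as unstable).
#' @param seed Seed for the null draws.
#' @return Tibble with one row per retained edge: `a`, `b` (motif indices),
#'   `distance`, `offset`, `orientation`, `p_value`, `q_value`; the full
#'   set of candidate pairs is attached as attribute `all_pairs`, and the
#'   null distances as attribute `null_distances`.
#' @export
motif_similarity_network <- function(motifs, fdr = 0.01, min_overlap = 6,
                                     n_null = 1000, seed = 1L) {
  if (length(motifs) < 2) {
    out <- tibble(a = integer(), b = integer(), distance = numeric(),
                  offset = integer(), orientation = character(),
                  p_value = numeric(), q_value = numeric())
    attr(out, "all_pairs") <- out
    return(out)
  }
  if (n_null < 100) stopf("n_null < 100 gives an unstable null")
  pairs <- combn(length(motifs), 2)
  all_pairs <- tibble(a = pairs[1, ], b = pairs[2, ])
  det <- map(seq_len(ncol(pairs)), function(k) {
    pssm_distance(motifs[[pairs[1, k]]], motifs[[pairs[2, k]]], min_overlap)
  })
  all_pairs$distance <- map_dbl(det, "distance")
  all_pairs$offset <- map_int(det, "offset")
  all_pairs$orientation <- map_chr(det, "orientation")
  all_pairs$overlap <- map_int(det, "overlap")

  # Empirical null, with two refinements over a naive shuffle null:
  # (1) null source pairs exclude near-duplicate pairs (distance below half
  #     the median) -- an ensemble contains many near-duplicate motifs
  #     (that is the signal), and letting duplicates seed the null would
  #     contaminate its left tail; the cutoff must stay below the unrelated
  #     pairs' bulk, or the null would be biased toward badly matching
  #     compositions and lose its own left tail;
  # (2) the null is conditioned on the observed alignment's overlap length:
  #     short overlaps are far easier to match by chance, so a pair whose
  #     best alignment spans L positions is compared against the null's
  #     best distance over alignments of at least L positions (the standard
  #     alignment-length correction in motif comparison).
  eligible <- which(all_pairs$distance > 0.5 * stats::median(all_pairs$distance))
  if (length(eligible) < 10) eligible <- seq_len(nrow(all_pairs))
  lmax <- max(all_pairs$overlap)
  null_mat <- with_seed(stage_seed(seed, "motif_null"), {
    picks <- eligible[sample.int(length(eligible), n_null, replace = TRUE)]
    t(vapply(picks, function(k) {
      pssm_distance_by_overlap(pssm_shuffle(motifs[[all_pairs$a[k]]]),
                               pssm_shuffle(motifs[[all_pairs$b[k]]]),
                               min_overlap, max_overlap = lmax)
    }, numeric(lmax - min_overlap + 1)))
  })
  # p = fraction of null draws whose overlap-conditioned best distance is
  # strictly below the observed one; a distance no null draw undercuts is
  # off the null's scale and gets p = 0
  null_sorted <- apply(null_mat, 2, sort)
  if (is.null(dim(null_sorted))) null_sorted <- matrix(null_sorted, ncol = 1)
  all_pairs$p_value <- vapply(seq_len(nrow(all_pairs)), function(k) {
    col <- all_pairs$overlap[k] - min_overlap + 1
    findInterval(all_pairs$distance[k] - 1e-12, null_sorted[, col]) / n_null
  }, numeric(1))
  null_d <- null_mat[, 1]
  all_pairs$q_value <- p.adjust(all_pairs$p_value, method = "BH")
  edges <- filter(all_pairs, .data$q_value <= fdr)
  attr(edges, "all_pairs") <- all_pairs
  attr(edges, "null_distances") <- null_d
  edges
}

#' Markov clustering (MCL) of a motif similarity network
#'
#' Runs the Markov Cluster algorithm on the weighted undirected graph:
#' self-loops added, columns normalised to a stochastic matrix, then
#' alternated expansion (matrix squaring) and inflation (elementwise power
#' `inflation` followed by renormalisation) until the matrix changes by
#' less than `tol`, with clusters read off as the connected components of
#' the converged matrix's support. Every node lands in exactly one cluster.
#'
#' @param edges Tibble with columns `a`, `b` and optionally `weight`
#'   (default weight 1).
#' @param nodes Vector of node ids (defaults to nodes present in `edges`;
#'   pass explicitly to include isolated nodes as singleton clusters).
#' @param inflation Inflation exponent (default 2.0).
#' @param max_iter,tol Convergence controls (default 200 iterations, 1e-6).
#' @return List of integer/character vectors, one per cluster, using the
#'   ids in `nodes`.
#' @export
mcl_cluster <- function(edges, nodes = NULL, inflation = 2.0,
                        max_iter = 200, tol = 1e-6) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  if (n == 0) return(list())
  M <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
    M[cbind(ia, ib)] <- w
    M[cbind(ib, ia)] <- w
  }
  diag(M) <- pmax(apply(M, 2, max), 1e-12)  # self-loops
  normalize <- function(X) sweep(X, 2, pmax(colSums(X), .Machine$double.xmin), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                 # expansion
    M2 <- normalize(M2^inflation) # inflation
    M2[M2 < 1e-12] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged) warnf("MCL did not converge in %d iterations; interpreting current matrix", max_iter)
  support <- (M > 1e-9) | (t(M) > 1e-9)
  comp <- connected_components(support)
  unname(lapply(split(seq_len(n), comp), function(i) nodes[i]))
}

# Connected components of a logical adjacency matrix (BFS).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Build gene regulatory elements (GREs) from motif clusters
#'
#' Clusters with at least `min_size` members become GREs. Members are
#' aligned to the cluster medoid (the member minimising its summed distance
#' to the others) and the combined PSSM is the per-position unweighted mean
#' over the members covering that position, truncated to positions covered
#' by at least half the members and renormalised.
#'
#' @param clusters List of motif-index vectors (from [mcl_cluster()]).
#' @param motifs The motif list the indices refer to.
#' @param min_size Minimum cluster size to qualify as a GRE (default 10).
#' @param min_overlap Alignment overlap passed to [pssm_distance()].
#' @param coverage Minimum fraction of members covering a retained combined
#'   position (default 0.5).
#' @return List of class `gre_set`: each element has `gre_id`, `members`
#'   (motif indices), `offsets`, `orientations`, `combined` (a [pssm]).
#' @export
build_gres <- function(clusters, motifs, min_size = 10, min_overlap = 6,
                       coverage = 0.5) {
  keep <- clusters[lengths(clusters) >= min_size]
  gres <- list()
  for (cl in keep) {
    cl <- as.integer(cl)
    k <- length(cl)
    dmat <- matrix(0, k, k)
    align <- vector("list", k)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d <- pssm_distance(motifs[[cl[i]]], motifs[[cl[j]]], min_overlap)
        dmat[i, j] <- dmat[j, i] <- d$distance
      }
    }
    medoid <- which.min(rowSums(dmat))
    offsets <- integer(k); orients <- character(k)
    aligned <- vector("list", k)
    for (i in seq_len(k)) {
      if (i == medoid) {
        offsets[i] <- 0L; orients[i] <- "same"
        aligned[[i]] <- motifs[[cl[i]]]$prob
      } else {
        d <- pssm_distance(motifs[[cl[medoid]]], motifs[[cl[i]]], min_overlap)
        offsets[i] <- d$offset; orients[i] <- d$orientation
        aligned[[i]] <- if (d$orientation == "same") motifs[[cl[i]]]$prob else
          pssm_revcomp(motifs[[cl[i]]])$prob
      }
    }
    lo <- min(offsets)
    hi <- max(offsets + vapply(aligned, nrow, integer(1)))
    width <- hi - lo
    sums <- matrix(0, width, 4); cover <- integer(width)
    for (i in seq_len(k)) {
      rows <- offsets[i] - lo + seq_len(nrow(aligned[[i]]))
      sums[rows, ] <- sums[rows, ] + aligned[[i]]
      cover[rows] <- cover[rows] + 1L
    }
    keep_pos <- which(cover >= coverage * k)
    if (length(keep_pos) == 0) keep_pos <- which.max(cover)
    keep_pos <- seq(min(keep_pos), max(keep_pos))  # contiguous support
    prob <- sums[keep_pos, , drop = FALSE] / cover[keep_pos]
    prob <- prob / rowSums(prob)
    gres[[length(gres) + 1]] <- list(
      gre_id = length(gres) + 1L,
      members = cl, offsets = offsets, orientations = orients,
      medoid = cl[medoid], support_start = lo + min(keep_pos) - 1L,
      combined = pssm(prob, pseudocount = motifs[[cl[1]]]$pseudocount))
  }
  structure(gres, class = "gre_set")
}

#' @exportS3Method base::print
print.gre_set <- function(x, ...) {
  cat(sprintf("<gre_set> %d GRE(s); sizes: %s\n", length(x),
              paste(vapply(x, function(g) length(g$members), integer(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Cluster ensemble motifs into GREs
#'
#' Convenience wrapper chaining [motif_similarity_network()],
#' [mcl_cluster()] (on similarity weights `1 - distance/d_max`, `d_max`
#' being the largest retained distance) and [build_gres()].
#'
#' @inheritParams motif_similarity_network
#' @inheritParams build_gres
#' @param inflation MCL inflation (default 2.0).
#' @return A `gre_set` (see [build_gres()]); the similarity edges are
#'   attached as attribute `edges`.
#' @export
discover_gres <- function(motifs, fdr = 0.01, min_overlap = 6, n_null = 1000,
                          inflation = 2.0, min_size = 10, seed = 1L) {
  edges <- motif_similarity_network(motifs, fdr = fdr, min_overlap = min_overlap,
                                    n_null = n_null, seed = seed)
  d_max <- if (nrow(edges) > 0) max(edges$distance) else 1
  d_max <- max(d_max, 1e-9)
  wedges <- mutate(edges, weight = pmax(0, 1 - .data$distance / d_max))
  clusters <- mcl_cluster(wedges, nodes = seq_along(motifs), inflation = inflation)
  gres <- build_gres(clusters, motifs, min_size = min_size, min_overlap = min_overlap)
  attr(gres, "edges") <- edges
  gres
}
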