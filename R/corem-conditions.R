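#' Relative standard deviation of a gene set in one condition
#'
#' RSD = |sigma / mu| over the corem genes' expression values in the
#' condition, with sigma the sample (n-1) standard deviation. Undefined
#' (returned as `NA` with a reason attribute) when fewer than 2 values are
#' available or the mean magnitude is below 1e-12 — on log-ratio data a
#' near-zero mean is common and uninformative.
#'
#' @param genes Character vector of gene ids.
#' @param expression Genes x conditions matrix.
#' @param condition Condition id.
#' @return RSD (numeric scalar), or `NA` with attribute `reason`.
#' @export
corem_rsd <- function(genes, expression, condition) {
  v <- expression[intersect(genes, rownames(expression)), condition]
  v <- v[!is.na(v)]
  if (length(v) < 2) return(structure(NA_real_, reason = "insufficient data"))
  mu <- mean(v)
  if (abs(mu) < 1e-12) return(structure(NA_real_, reason = "zero mean"))
  abs(sd(v) / mu)
}

# RSD of every column for a set of row-index draws, vectorised through
# sparse indicator multiplication; undefined entries become +Inf.
rsd_matrix <- function(expression, idx_matrix) {
  G <- nrow(expression)
  P <- nrow(idx_matrix); k <- ncol(idx_matrix)
  Z0 <- expression; Z0[is.na(Z0)] <- 0
  W <- !is.na(expression)
  S <- Matrix::sparseMatrix(i = rep(seq_len(P), k), j = as.vector(idx_matrix),
                            x = 1, dims = c(P, G))
  counts <- as.matrix(S %*% W)
  sums <- as.matrix(S %*% Z0)
  sums2 <- as.matrix(S %*% (Z0^2))
  mu <- sums / counts
  v <- (sums2 - counts * mu^2) / (counts - 1)
  v[v < 0] <- 0
  out <- abs(sqrt(v) / mu)
  out[counts < 2 | abs(mu) < 1e-12 | !is.finite(out)] <- Inf
  out
}

#' Permutation test for conditional co-regulation of a corem
#'
#' Per condition, the observed RSD of the corem genes is compared with a
#' null of `n_perm` equally sized gene sets drawn without replacement from
#' all matrix genes: p = (1 + #\{null RSD <= observed\}) / (1 + n_perm).
#' Conditions with undefined RSD get p = 1. Benjamini-Hochberg q-values
#' across conditions are reported alongside; the co-regulated set follows
#' the raw p at `p_cut` (set `use_q = TRUE` to gate on q instead).
#'
#' @param genes Corem gene ids (all must exist in the matrix).
#' @param expression Genes x conditions matrix.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the draws.
#' @param p_cut Threshold defining the co-regulated condition set (0.05).
#' @param use_q Gate the co-regulated set on the BH q-value instead of the
#'   raw p (default FALSE).
#' @return Tibble (`condition_id`, `rsd`, `defined`, `p_value`, `q_value`,
#'   `coregulated`), one row per condition in matrix order.
#' @export
rsd_permutation_test <- function(genes, expression, n_perm = 1000, seed = 1L,
                                 p_cut = 0.05, use_q = FALSE) {
  genes <- unique(genes)
  missing <- setdiff(genes, rownames(expression))
  if (length(missing) > 0) stopf("corem gene(s) not in expression matrix: %s", missing[1])
  k <- length(genes)
  G <- nrow(expression)
  if (k > G) stopf("corem larger than the gene universe")
  obs <- rsd_matrix(expression, matrix(match(genes, rownames(expression)), nrow = 1))[1, ]
  null <- with_seed(stage_seed(seed, "activity"), {
    idx <- t(vapply(seq_len(n_perm), function(i) sample.int(G, k), integer(k)))
    rsd_matrix(expression, idx)
  })
  n_le <- colSums(null <= matrix(obs, nrow = n_perm, ncol = length(obs), byrow = TRUE))
  p <- (1 + n_le) / (1 + n_perm)
  defined <- is.finite(obs)
  p[!defined] <- 1
  q <- p.adjust(p, method = "BH")
  crit <- if (use_q) q else p
  tibble(condition_id = colnames(expression),
         rsd = unname(ifelse(defined, obs, NA_real_)),
         defined = unname(defined),
         p_value = unname(p), q_value = unname(q),
         coregulated = unname(defined & crit <= p_cut))
}

#' Aggregate co-regulated conditions into contiguous blocks
#'
#' Helper over [rsd_permutation_test()] output: maximal runs of
#' consecutive co-regulated conditions (in matrix column order) of length
#' at least `min_len`. Pruning short runs suppresses the isolated
#' false positives a per-condition test at nominal level necessarily
#' admits.
#'
#' @param activity Tibble from [rsd_permutation_test()].
#' @param min_len Minimum run length (default 3).
#' @return Tibble (`block`, `condition_id`).
#' @export
coregulated_blocks <- function(activity, min_len = 3) {
  r <- rle(activity$coregulated)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_len)
  if (length(keep) == 0) return(tibble(block = integer(), condition_id = character()))
  bind_rows(lapply(seq_along(keep), function(b) {
    i <- keep[b]
    tibble(block = b, condition_id = activity$condition_id[starts[i]:ends[i]])
  }))
}

# Does any hit interval overlap any promoter-window interval of any of the
# given genes?
hits_in_promoters <- function(hits, genes, genome, upstream = 875, downstream = 125) {
  if (nrow(hits) == 0) return(rep(FALSE, 0))
  ok <- rep(FALSE, nrow(hits))
  for (g in genes) {
    gi <- match(g, genome$genes$gene_id)
    if (is.na(gi)) next
    win <- promoter_window(genome$genes[gi, ], genome, upstream, downstream)
    L <- replicon_row(genome, genome$genes$replicon_id[gi])$length
    circ <- replicon_row(genome, genome$genes$replicon_id[gi])$topology == "circular"
    for (w in seq_len(nrow(win))) {
      h_start <- hits$position
      h_end <- hits$position + hits$width
      same <- hits$replicon_id == win$replicon_id[w]
      direct <- same & h_start < win$end[w] & h_end > win$start[w]
      ok <- ok | direct
      if (circ) {
        # hits wrapping past the origin also cover positions < h_end - L
        wrap <- same & h_end > L & (h_end - L) > win$start[w] & win$end[w] > 0
        ok <- ok | wrap
      }
    }
  }
  ok
}

#' Associate GREs with a corem
#'
#' A GRE is implicated in a corem's regulation iff (1) it has at least one
#' significant match inside the promoter window (default -875 to +125 nt
#' around the start codon) of at least one corem gene, and (2) at least
#' one of its member PSSMs originates from a bicluster in the top
#' `top_fraction` of biclusters ranked by the number of corem genes they
#' contain (boundary ties all included; a supporting bicluster must share
#' at least one gene with the corem). The composition weight is the GRE's
#' supporting-bicluster count normalised over all associated GREs.
#'
#' @param corem_genes Character vector of corem gene ids.
#' @param gres A `gre_set` (see [build_gres()]).
#' @param hits [scan_genome()] output for the `gre_set`.
#' @param motifs Motif list the GRE member indices refer to.
#' @param ens The [ensemble()] the motifs came from.
#' @param genome A [genome_annotation()].
#' @param top_fraction Fraction of top-ranked biclusters (default 0.10).
#' @param upstream,downstream Promoter window extent.
#' @return Tibble (`gre_id`, `has_promoter_hit`, `in_top_biclusters`,
#'   `n_supporting`, `associated`, `weight`).
#' @export
associate_gres_to_corem <- function(corem_genes, gres, hits, motifs, ens, genome,
                                    top_fraction = 0.10,
                                    upstream = 875, downstream = 125) {
  overlaps <- map_int(ens$biclusters$genes, ~ length(intersect(.x, corem_genes)))
  n_top <- max(1L, ceiling(top_fraction * nrow(ens$biclusters)))
  boundary <- sort(overlaps, decreasing = TRUE)[min(n_top, length(overlaps))]
  top_ids <- ens$biclusters$bicluster_id[overlaps >= max(boundary, 1L)]

  if (length(gres) == 0) {
    return(tibble(gre_id = integer(), has_promoter_hit = logical(),
                  in_top_biclusters = logical(), n_supporting = integer(),
                  associated = logical(), weight = numeric()))
  }
  rows <- map(gres, function(g) {
    gh <- hits[!is.na(hits$gre_id) & hits$gre_id == g$gre_id, ]
    has_hit <- nrow(gh) > 0 && any(hits_in_promoters(gh, corem_genes, genome,
                                                     upstream, downstream))
    member_bcs <- unique(map_chr(g$members, function(i) motifs[[i]]$provenance$bicluster_id))
    support <- intersect(member_bcs, top_ids)
    tibble(gre_id = g$gre_id,
           has_promoter_hit = has_hit,
           in_top_biclusters = length(support) > 0,
           n_supporting = length(support))
  })
  out <- bind_rows(rows)
  out$associated <- out$has_promoter_hit & out$in_top_biclusters
  tot <- sum(out$n_supporting[out$associated])
  out$weight <- ifelse(out$associated & tot > 0, out$n_supporting / tot, 0)
  arrange(out, desc(.data$weight), .data$gre_id)
}

#' Normalised GRE composition of a corem
#'
#' The associated GREs' weights, renormalised to sum to 1 and ordered by
#' decreasing weight then GRE id; an empty result means the corem's
#' co-regulation is unexplained by any GRE. This supporting-bicluster
#' composition is a declared stand-in for a model-based influence score.
#'
#' @param associations Output of [associate_gres_to_corem()].
#' @return Tibble (`gre_id`, `weight`) with weights summing to 1, or zero
#'   rows.
#' @export
corem_gre_composition <- function(associations) {
  a <- filter(associations, .data$associated)
  if (nrow(a) == 0) return(tibble(gre_id = integer(), weight = numeric()))
  a$weight <- a$n_supporting / sum(a$n_supporting)
  select(arrange(a, desc(.data$weight), .data$gre_id), "gre_id", "weight")
}

#' Condition-group enrichment of a co-regulated condition set
#'
#' Hypergeometric upper-tail test of the overlap between the co-regulated
#' conditions and each annotated condition group, with the full condition
#' universe as background and Benjamini-Hochberg correction across groups.
#'
#' @param coregulated Character vector of co-regulated condition ids.
#' @param annotation Tibble (`condition_id`, `group`).
#' @param universe All condition ids (e.g. `colnames(expression)`).
#' @return Tibble (`group`, `n_group`, `n_coregulated`, `overlap`,
#'   `p_value`, `fdr`), groups not intersecting the universe skipped.
#' @export
condition_enrichment <- function(coregulated, annotation, universe) {
  coregulated <- intersect(coregulated, universe)
  N <- length(universe); n <- length(coregulated)
  rows <- map(split(annotation$condition_id, annotation$group), function(conds) {
    K <- length(intersect(conds, universe))
    if (K == 0) return(NULL)
    ov <- length(intersect(conds, coregulated))
    tibble(n_group = K, n_coregulated = n, overlap = ov,
           p_value = phyper(ov - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble(group = character(), n_group = integer(),
                  n_coregulated = integer(), overlap = integer(),
                  p_value = numeric(), fdr = numeric()))
  }
  out <- bind_rows(rows, .id = "group")
  out$fdr <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value)
}

#' Detect operons split across corems
#'
#' For each operon, collects the distinct non-empty intersection patterns
#' between the operon's genes and each corem; an operon with two or more
#' distinct patterns is flagged as predicting condition-specific transcript
#' isoforms (sub-segments of the operon are separately co-regulated).
#'
#' @param operons Tibble (`operon_id`, `gene_id`), genes in operon order.
#' @param corems Tibble with a `genes` list-column, e.g.
#'   [extract_corems()].
#' @return Tibble (`operon_id`, `n_genes`, `n_patterns`, `patterns`
#'   list-column, `status`) with status one of
#'   `"conditional isoforms predicted"`, `"single isoform"`,
#'   `"no co-regulation evidence"`.
#' @export
detect_operon_splits <- function(operons, corems) {
  rows <- map(split(operons$gene_id, operons$operon_id), function(genes) {
    pats <- unique(keep(map(corems$genes, ~ intersect(genes, .x)), ~ length(.x) > 0))
    status <- if (length(pats) >= 2) "conditional isoforms predicted"
              else if (length(pats) == 1) "single isoform"
              else "no co-regulation evidence"
    tibble(n_genes = length(genes), n_patterns = length(pats),
           patterns = list(pats), status = status)
  })
  out <- bind_rows(rows, .id = "operon_id")
  arrange(out, .data$operon_id)
}
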