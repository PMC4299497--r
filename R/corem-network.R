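#' Gene-gene co-occurrence network from a bicluster ensemble
#'
#' Edge weight w_ij is the number of biclusters whose gene set contains
#' both genes; genes never co-clustered share no edge.
#'
#' @param ens An [ensemble()].
#' @param normalize Optional `"runs"`: divide each weight by the number of
#'   distinct runs containing both genes (default `"none"`, raw counts).
#' @return Tibble (`gene_a`, `gene_b`, `weight`) with `gene_a < gene_b`.
#' @export
count_cooccurrence <- function(ens, normalize = c("none", "runs")) {
  normalize <- match.arg(normalize)
  pair_rows <- lapply(seq_len(nrow(ens$biclusters)), function(i) {
    g <- sort(unique(ens$biclusters$genes[[i]]))
    if (length(g) < 2) return(NULL)
    p <- combn(g, 2)
    tibble(gene_a = p[1, ], gene_b = p[2, ], run_id = ens$biclusters$run_id[i])
  })
  pairs <- bind_rows(pair_rows)
  if (nrow(pairs) == 0) return(tibble(gene_a = character(), gene_b = character(), weight = numeric()))
  net <- summarise(group_by(pairs, .data$gene_a, .data$gene_b),
                   weight = dplyr::n(), n_runs = dplyr::n_distinct(.data$run_id),
                   .groups = "drop")
  if (normalize == "runs") net$weight <- net$weight / net$n_runs
  arrange(select(net, "gene_a", "gene_b", "weight"), .data$gene_a, .data$gene_b)
}

#' Disparity-filter backbone of a weighted network
#'
#' For each edge at an endpoint i with degree k_i >= 2, the normalised
#' weight is p_ij = w_ij / s_i (s_i the node strength) and the disparity
#' p-value is alpha_ij = (1 - p_ij)^(k_i - 1), the probability that a
#' uniformly split strength would give this edge at least its observed
#' share. An edge is retained iff alpha < `alpha` at either endpoint;
#' endpoints of degree 1 are uninformative and contribute alpha = 1.
#'
#' @param network Tibble (`gene_a`, `gene_b`, `weight`) from
#'   [count_cooccurrence()].
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @return The network tibble with columns `alpha_a`, `alpha_b`,
#'   `retained` added; filter on `retained` for the backbone (see
#'   [backbone()]).
#' @export
disparity_filter <- function(network, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0, 1)")
  if (any(network$weight <= 0)) stopf("disparity filter needs positive weights")
  long <- bind_rows(
    tibble(node = network$gene_a, other = network$gene_b, weight = network$weight, edge = seq_len(nrow(network))),
    tibble(node = network$gene_b, other = network$gene_a, weight = network$weight, edge = seq_len(nrow(network))))
  stats_by_node <- summarise(group_by(long, .data$node),
                             strength = sum(.data$weight), degree = dplyr::n(),
                             .groups = "drop")
  long <- left_join(long, stats_by_node, by = "node")
  long$alpha_val <- ifelse(long$degree < 2, 1,
                           (1 - long$weight / long$strength)^(long$degree - 1))
  a_end <- long[seq_len(nrow(network)), ]
  b_end <- long[nrow(network) + seq_len(nrow(network)), ]
  out <- network
  out$alpha_a <- a_end$alpha_val
  out$alpha_b <- b_end$alpha_val
  out$retained <- out$alpha_a < alpha | out$alpha_b < alpha
  out
}

#' Backbone edges of a disparity-filtered network
#' @param network Output of [disparity_filter()].
#' @return The retained edges, original weights kept.
#' @export
backbone <- function(network) {
  filter(network, .data$retained)
}

#' Similarity between two links sharing a node
#'
#' For links e_ik and e_jk sharing node k, the similarity is the Jaccard
#' index of the inclusive neighbourhoods n+(i) and n+(j) (a node together
#' with its neighbours) on the backbone. Identical links have similarity 1;
#' non-adjacent links 0.
#'
#' @param backbone_edges Tibble (`gene_a`, `gene_b`).
#' @param edge_a,edge_b Length-2 character vectors naming the link
#'   endpoints.
#' @return Similarity in `[0, 1]`.
#' @export
link_similarity <- function(backbone_edges, edge_a, edge_b) {
  ea <- sort(as.character(edge_a)); eb <- sort(as.character(edge_b))
  if (identical(ea, eb)) return(1)
  shared <- intersect(ea, eb)
  if (length(shared) != 1) return(0)
  i <- setdiff(ea, shared); j <- setdiff(eb, shared)
  nb <- function(x) {
    unique(c(x, backbone_edges$gene_b[backbone_edges$gene_a == x],
             backbone_edges$gene_a[backbone_edges$gene_b == x]))
  }
  ni <- nb(i); nj <- nb(j)
  length(intersect(ni, nj)) / length(union(ni, nj))
}

# All pairwise link similarities as a dist object (1 - similarity), with
# non-adjacent links at distance 1.
link_distance_matrix <- function(edges) {
  m <- nrow(edges)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ia <- match(edges$gene_a, nodes); ib <- match(edges$gene_b, nodes)
  adj[cbind(ia, ib)] <- TRUE; adj[cbind(ib, ia)] <- TRUE
  diag(adj) <- TRUE  # inclusive neighbourhoods
  D <- matrix(1, m, m)
  diag(D) <- 0
  # links are adjacent when they share exactly one node
  for (x in seq_along(nodes)) {
    inc <- which(ia == x | ib == x)
    if (length(inc) < 2) next
    for (u in seq_len(length(inc) - 1)) {
      for (v in seq(u + 1, length(inc))) {
        e1 <- inc[u]; e2 <- inc[v]
        i <- if (ia[e1] == x) ib[e1] else ia[e1]
        j <- if (ia[e2] == x) ib[e2] else ia[e2]
        ni <- adj[i, ]; nj <- adj[j, ]
        s <- sum(ni & nj) / sum(ni | nj)
        if (1 - s < D[e1, e2]) { D[e1, e2] <- D[e2, e1] <- 1 - s }
      }
    }
  }
  as.dist(D)
}

#' Partition density of a link partition
#'
#' For a community c with m_c links over n_c induced nodes, the community
#' density is D_c = (m_c - (n_c - 1)) / (n_c (n_c - 1) / 2 - (n_c - 1)),
#' i.e. the link surplus over a spanning tree, normalised by a clique's;
#' D_c is defined as 0 for n_c <= 2. The partition density is the
#' link-weighted mean D = (2 / M) * sum_c m_c (m_c - (n_c - 1)) /
#' ((n_c - 2)(n_c - 1)).
#'
#' @param edges Tibble (`gene_a`, `gene_b`).
#' @param membership Integer community label per edge.
#' @return List with `D` and a tibble `communities` (`community`, `m`, `n`,
#'   `density`).
#' @export
partition_density <- function(edges, membership) {
  M <- nrow(edges)
  comm <- map(split(seq_len(M), membership), function(i) {
    m_c <- length(i)
    n_c <- length(unique(c(edges$gene_a[i], edges$gene_b[i])))
    d_c <- if (n_c <= 2) 0 else (m_c - (n_c - 1)) / (n_c * (n_c - 1) / 2 - (n_c - 1))
    tibble(m = m_c, n = n_c, density = d_c)
  })
  tab <- bind_rows(comm, .id = "community")
  list(D = sum(tab$m * tab$density) / M, communities = tab)
}

#' Link communities by single-linkage clustering under partition density
#'
#' Clusters the backbone's links agglomeratively (single linkage) under the
#' inclusive-neighbourhood Jaccard similarity, evaluates the partition
#' density at every dendrogram height (including the all-singletons cut),
#' and keeps the cut maximising it, breaking ties toward the larger height
#' (coarser communities).
#'
#' @param backbone_edges Tibble (`gene_a`, `gene_b`, ...) of retained
#'   edges, e.g. [backbone()] output.
#' @return Object of class `link_communities`: list with `edges` (input
#'   edges plus `community`), `D`, `cut_height`, `communities` (per-
#'   community m, n, density), `heights` (all evaluated cuts).
#' @export
link_communities <- function(backbone_edges) {
  edges <- as_tibble(backbone_edges)
  if (nrow(edges) == 0) stopf("no links to cluster")
  if (nrow(edges) == 1) {
    pd <- partition_density(edges, 1L)
    edges$community <- 1L
    return(structure(list(edges = edges, D = pd$D, cut_height = 0,
                          communities = pd$communities,
                          heights = tibble(height = 0, D = pd$D)),
                     class = "link_communities"))
  }
  D <- link_distance_matrix(edges)
  hc <- hclust(D, method = "single")
  cuts <- sort(unique(c(0, hc$height)))
  evals <- map(cuts, function(h) {
    mem <- cutree(hc, h = h)
    pd <- partition_density(edges, mem)
    list(h = h, D = pd$D, mem = mem, communities = pd$communities)
  })
  dvals <- map_dbl(evals, "D")
  hvals <- map_dbl(evals, "h")
  best <- which(dvals >= max(dvals) - 1e-12)
  best <- best[which.max(hvals[best])]  # ties -> coarser cut
  chosen <- evals[[best]]
  edges$community <- as.integer(chosen$mem)
  structure(list(edges = edges, D = chosen$D, cut_height = chosen$h,
                 communities = chosen$communities,
                 heights = tibble(height = hvals, D = dvals)),
            class = "link_communities")
}

#' @exportS3Method base::print
print.link_communities <- function(x, ...) {
  cat(sprintf("<link_communities> %d links, %d communities, D = %.4f at height %.4f\n",
              nrow(x$edges), length(unique(x$edges$community)), x$D, x$cut_height))
  invisible(x)
}

#' Extract corems from link communities
#'
#' Each community's induced gene set with at least `min_genes` genes
#' becomes a corem. Because corems are defined over links, a gene can
#' belong to several corems. Corem ids are stable: communities are ordered
#' by decreasing size then lexicographic gene list.
#'
#' @param lc A [link_communities()] result.
#' @param min_genes Minimum corem size (default 3; community density is
#'   only meaningful from 3 nodes up).
#' @return Tibble (`corem_id`, `genes` list-column, `n_genes`, `n_links`,
#'   `community`).
#' @export
extract_corems <- function(lc, min_genes = 3) {
  rows <- map(split(seq_len(nrow(lc$edges)), lc$edges$community), function(i) {
    gene_set <- sort(unique(c(lc$edges$gene_a[i], lc$edges$gene_b[i])))
    tibble(genes = list(gene_set), n_genes = length(gene_set), n_links = length(i))
  })
  tab <- bind_rows(rows, .id = "community")
  tab <- filter(tab, .data$n_genes >= min_genes)
  tab <- tab[order(-tab$n_genes, map_chr(tab$genes, paste, collapse = ",")), ]
  tab$corem_id <- seq_len(nrow(tab))
  select(tab, "corem_id", "genes", "n_genes", "n_links", "community")
}
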