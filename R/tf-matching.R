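#' @name tf_matching
#' @title GRE-to-TF matching and regulatory network evaluation
NULL

# Bin index set covered by [start, end) intervals on a binned genome.
# Bins are fixed windows of bin_size nt per replicon; circular intervals
# wrap. Returns global bin ids unique across replicons.
interval_bins <- function(replicon_id, start, end, genome, bin_size) {
  offsets <- c(0, cumsum(ceiling(genome$replicons$length / bin_size)))
  names(offsets) <- c(genome$replicons$replicon_id, ".end")
  out <- integer(0)
  for (i in seq_along(start)) {
    ri <- match(replicon_id[i], genome$replicons$replicon_id)
    L <- genome$replicons$length[ri]
    pos <- seq(start[i], end[i] - 1L) %% L
    out <- c(out, offsets[ri] + unique(pos %/% bin_size))
  }
  unique(out)
}

total_bins <- function(genome, bin_size) {
  sum(ceiling(genome$replicons$length / bin_size))
}

#' Overlap test between PSSM hits and a TF's binding sites
#'
#' The genome is partitioned into fixed bins (default 50 nt); the p-value
#' is the hypergeometric upper tail of the number of hit-bins that are
#' also TF-site bins, drawing the hit-bins from all genome bins with the
#' TF-site bins marked.
#'
#' @param hits Tibble of one PSSM's hits (`replicon_id`, `position`,
#'   `width`).
#' @param sites Tibble of one TF's sites (`replicon_id`, `start`, `end`).
#' @param genome A [genome_annotation()].
#' @param bin_size Bin width in nt (default 50; must be at least the motif
#'   width).
#' @return Upper-tail p-value; 1 when the PSSM has no hits.
#' @export
pssm_site_overlap_test <- function(hits, sites, genome, bin_size = 50) {
  if (nrow(hits) > 0 && bin_size < max(hits$width)) {
    stopf("bin_size (%d) smaller than motif width (%d)", bin_size, max(hits$width))
  }
  if (nrow(hits) == 0) return(1)
  hb <- interval_bins(hits$replicon_id, hits$position, hits$position + hits$width,
                      genome, bin_size)
  sb <- interval_bins(sites$replicon_id, sites$start, sites$end, genome, bin_size)
  N <- total_bins(genome, bin_size)
  ov <- length(intersect(hb, sb))
  phyper(ov - 1, length(sb), N - length(sb), length(hb), lower.tail = FALSE)
}

#' Match GREs to transcription factors by binding-site overlap
#'
#' A member PSSM is significant for a TF when its genomic hit locations
#' overlap the TF's sites at `p_site` or better
#' ([pssm_site_overlap_test()]). The GRE-level p-value asks whether a
#' significant fraction of members is significant: a binomial upper tail
#' of the significant count at rate `p_site`. Benjamini-Hochberg across
#' all (GRE, TF) pairs gives q; matches are kept at `fdr`, and per GRE
#' only the most significant TF is flagged `best` (one TF may be best for
#' several GREs).
#'
#' @param gres A `gre_set` ([build_gres()]).
#' @param hits [scan_genome()] output for the `gre_set` (member-tagged).
#' @param tf_sites Tibble from [read_tf_sites()].
#' @param genome A [genome_annotation()].
#' @param bin_size Overlap-test bin width (default 50 nt).
#' @param p_site Per-PSSM overlap significance threshold (default 0.01).
#' @param fdr GRE-level match FDR (default 0.05).
#' @return Tibble (`gre_id`, `tf_id`, `n_significant`, `n_pssms`,
#'   `p_value`, `q_value`, `retained`, `best`).
#' @export
match_gre_to_tf <- function(gres, hits, tf_sites, genome, bin_size = 50,
                            p_site = 0.01, fdr = 0.05) {
  tfs <- split(tf_sites, tf_sites$tf_id)
  rows <- list()
  for (g in gres) {
    gh <- hits[!is.na(hits$gre_id) & hits$gre_id == g$gre_id, ]
    n_pssms <- length(g$members)
    member_p <- map(seq_len(n_pssms), function(k) {
      mh <- gh[gh$member == k, ]
      map_dbl(tfs, ~ pssm_site_overlap_test(mh, .x, genome, bin_size))
    })
    for (tf in names(tfs)) {
      nsig <- sum(map_dbl(member_p, ~ .x[[tf]]) <= p_site)
      rows[[length(rows) + 1]] <- tibble(
        gre_id = g$gre_id, tf_id = tf,
        n_significant = nsig, n_pssms = n_pssms,
        p_value = pbinom(nsig - 1, n_pssms, p_site, lower.tail = FALSE))
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(gre_id = integer(), tf_id = character(), n_significant = integer(),
                  n_pssms = integer(), p_value = numeric(), q_value = numeric(),
                  retained = logical(), best = logical()))
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$retained <- out$q_value <= fdr
  out$best <- FALSE
  for (gid in unique(out$gre_id)) {
    cand <- which(out$gre_id == gid & out$retained)
    if (length(cand) == 0) next
    ord <- cand[order(out$q_value[cand], out$p_value[cand], out$tf_id[cand])]
    out$best[ord[1]] <- TRUE
  }
  arrange(out, .data$gre_id, .data$q_value, .data$tf_id)
}

#' Derive a GRE-based gene regulatory network
#'
#' For every best GRE-TF match, an edge TF -> gene is drawn whenever the
#' GRE has a significant match inside the gene's promoter window.
#' Confidence is (1 - best promoter-hit q) * (1 - match q); duplicate
#' (TF, gene) edges keep the maximum confidence.
#'
#' @param matches [match_gre_to_tf()] output.
#' @param hits [scan_genome()] output for the `gre_set`.
#' @param genome A [genome_annotation()].
#' @param upstream,downstream Promoter window extent (defaults 875/125 nt).
#' @return Tibble (`tf_id`, `gene_id`, `confidence`, `gre_id`,
#'   `best_hit_q`), ordered by decreasing confidence.
#' @export
gre_based_grn <- function(matches, hits, genome, upstream = 875, downstream = 125) {
  best <- filter(matches, .data$best)
  rows <- list()
  for (i in seq_len(nrow(best))) {
    gid <- best$gre_id[i]
    gh <- hits[!is.na(hits$gre_id) & hits$gre_id == gid, ]
    if (nrow(gh) == 0) next
    for (j in seq_len(nrow(genome$genes))) {
      gene <- genome$genes[j, ]
      inside <- hits_in_promoters(gh, gene$gene_id, genome, upstream, downstream)
      if (!any(inside)) next
      bq <- min(gh$q_value[inside])
      rows[[length(rows) + 1]] <- tibble(
        tf_id = best$tf_id[i], gene_id = gene$gene_id,
        confidence = (1 - bq) * (1 - best$q_value[i]),
        gre_id = gid, best_hit_q = bq)
    }
  }
  if (length(rows) == 0) {
    return(tibble(tf_id = character(), gene_id = character(), confidence = numeric(),
                  gre_id = integer(), best_hit_q = numeric()))
  }
  out <- bind_rows(rows)
  out <- summarise(group_by(out, .data$tf_id, .data$gene_id),
                   confidence = max(.data$confidence),
                   gre_id = .data$gre_id[which.max(.data$confidence)],
                   best_hit_q = min(.data$best_hit_q), .groups = "drop")
  arrange(out, desc(.data$confidence), .data$tf_id, .data$gene_id)
}

#' Precision-recall evaluation of a predicted network
#'
#' Predictions are restricted to the gold standard's TF and gene universe,
#' ranked by decreasing confidence (ties broken lexicographically so the
#' ranking is total), and evaluated at every prefix. AUPR is the trapezoid
#' over recall, anchored at (recall 0, precision of the first prediction).
#' Also reported: the number of correct predictions in the largest prefix
#' whose precision still meets each cutoff.
#'
#' @param predicted Tibble (`tf_id`, `gene_id`, `confidence`).
#' @param gold Tibble (`tf_id`, `gene_id`) of true interactions.
#' @param cutoffs Precision cutoffs (default 0.10, 0.25, 0.50).
#' @return Object of class `pr_eval`: list with `curve` (tibble `rank`,
#'   `tf_id`, `gene_id`, `tp`, `precision`, `recall`), `aupr`, `hits_at`
#'   (named integer), `n_gold`, `n_predictions`.
#' @export
precision_recall_aupr <- function(predicted, gold, cutoffs = c(0.10, 0.25, 0.50)) {
  if (nrow(gold) == 0) stopf("empty gold standard")
  gold_key <- paste(gold$tf_id, gold$gene_id, sep = "\r")
  pred <- filter(predicted, .data$tf_id %in% unique(gold$tf_id),
                 .data$gene_id %in% unique(gold$gene_id))
  pred <- arrange(pred, desc(.data$confidence), .data$tf_id, .data$gene_id)
  is_tp <- paste(pred$tf_id, pred$gene_id, sep = "\r") %in% gold_key
  tp <- cumsum(is_tp)
  k <- seq_len(nrow(pred))
  curve <- tibble(rank = k, tf_id = pred$tf_id, gene_id = pred$gene_id,
                  tp = tp, precision = tp / k, recall = tp / nrow(gold))
  aupr <- if (nrow(curve) == 0) 0 else {
    r <- c(0, curve$recall); p <- c(curve$precision[1], curve$precision)
    sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  }
  hits_at <- vapply(cutoffs, function(cut) {
    ok <- which(curve$precision >= cut)
    if (length(ok) == 0) 0L else curve$tp[max(ok)]
  }, integer(1))
  names(hits_at) <- sprintf("%g", cutoffs)
  structure(list(curve = curve, aupr = aupr, hits_at = hits_at,
                 n_gold = nrow(gold), n_predictions = nrow(curve)),
            class = "pr_eval")
}

#' @exportS3Method base::print
print.pr_eval <- function(x, ...) {
  cat(sprintf("<pr_eval> AUPR = %.4f over %d predictions vs %d gold edges\n",
              x$aupr, x$n_predictions, x$n_gold))
  cat("correct predictions at precision cutoffs:\n")
  print(x$hits_at)
  invisible(x)
}

#' Fitness coherence of gene groupings (one-tailed KS)
#'
#' For each grouping (e.g. corems), distribution A holds the pairwise
#' Pearson correlations of fitness vectors for within-group gene pairs and
#' distribution B the correlations of all gene pairs in the universe; the
#' one-sided two-sample KS test asks whether A is stochastically greater
#' than B (its D statistic is the maximum excess of B's empirical CDF over
#' A's). Counts of within-group pairs above fixed correlation thresholds
#' are reported alongside.
#'
#' @param groupings Named list of gene-set collections; each collection is
#'   a list of character vectors (sets with fewer than 2 profiled genes
#'   contribute no pairs).
#' @param fitness Genes x conditions fitness matrix.
#' @param universe Gene universe for the background pairs (default: all
#'   rows of `fitness`).
#' @param thresholds Correlation thresholds for the capture counts.
#' @return Tibble (`method`, `n_pairs`, `D`, `p_value`, plus one
#'   `captured_at_<t>` column per threshold).
#' @export
fitness_coherence_ks <- function(groupings, fitness, universe = rownames(fitness),
                                 thresholds = c(0.75, 0.9)) {
  universe <- intersect(universe, rownames(fitness))
  cors <- cor(t(fitness[universe, , drop = FALSE]))
  background <- cors[upper.tri(cors)]
  rows <- map(groupings, function(sets) {
    within <- unlist(map(sets, function(g) {
      g <- intersect(unique(g), universe)
      if (length(g) < 2) return(numeric())
      cc <- cors[g, g, drop = FALSE]
      cc[upper.tri(cc)]
    }))
    if (length(within) == 0) {
      row <- tibble(n_pairs = 0L, D = NA_real_, p_value = NA_real_)
    } else {
      ks <- suppressWarnings(ks.test(within, background, alternative = "less"))
      row <- tibble(n_pairs = length(within), D = unname(ks$statistic),
                    p_value = ks$p.value)
    }
    for (t in thresholds) {
      row[[sprintf("captured_at_%g", t)]] <- sum(within >= t)
    }
    row
  })
  bind_rows(rows, .id = "method")
}
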