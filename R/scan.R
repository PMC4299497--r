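#' @name scanning
#' @title Genome scanning with exact match p-values
#' @description
#' A PSSM is scored against every genomic position on both strands as a
#' log2 odds ratio versus a 0-order background. Per-position p-values are
#' exact: per-position score distributions are discretised to `bin` log2
#' units and convolved by dynamic programming, giving the full null score
#' distribution under the background, from which upper-tail probabilities
#' are read off. Benjamini-Hochberg q-values are computed per PSSM across
#' all scanned positions (both strands); hits are reported at q <= `qmax`.
NULL

# Integer (binned) log2-odds score table for a PSSM: w x 4 matrix of
# round(log2(p'/bg)/bin) with pseudocount-mixed probabilities.
score_table <- function(m, background, bin = 1e-3) {
  pc <- m$pseudocount
  prob <- (m$prob + pc) / (1 + 4 * pc)
  if (any(background <= 0 & apply(prob, 2, max) > 0)) {
    stopf("background frequency 0 for a base with positive motif probability (infinite score)")
  }
  s <- log2(sweep(prob, 2, background, "/"))
  matrix(as.integer(round(s / bin)), nrow = nrow(s))
}

# Exact distribution of the integer score sum under the background:
# dynamic-programming convolution of the per-position score distributions.
# Returns list(min = smallest achievable sum, tail = P(S >= min + i - 1)).
score_null_tail <- function(stab, background) {
  lo <- sum(apply(stab, 1, min)); hi <- sum(apply(stab, 1, max))
  d <- numeric(hi - lo + 1)
  cur_lo <- 0L
  d[1] <- 1
  cur_len <- 1L
  for (j in seq_len(nrow(stab))) {
    mj <- min(stab[j, ]); Mj <- max(stab[j, ])
    new_len <- cur_len + (Mj - mj)
    nd <- numeric(new_len)
    for (b in 1:4) {
      sh <- stab[j, b] - mj
      idx <- seq_len(cur_len) + sh
      nd[idx] <- nd[idx] + d[seq_len(cur_len)] * background[b]
    }
    d[seq_len(new_len)] <- nd
    cur_len <- new_len
    cur_lo <- cur_lo + mj
  }
  tail <- rev(cumsum(rev(d[seq_len(cur_len)])))
  list(min = cur_lo, tail = pmin(tail, 1))
}

# P(S >= t) lookup for integer scores t against a score_null_tail().
tail_p <- function(t, null) {
  i <- t - null$min + 1L
  p <- rep(1, length(t))
  p[i > length(null$tail)] <- 0
  ok <- i >= 1 & i <= length(null$tail)
  p[ok] <- null$tail[i[ok]]
  p[is.na(t)] <- 1
  p
}

# Benjamini-Hochberg on a vector with few distinct values, via the grouped
# form; identical to p.adjust(p, "BH") but O(u log u) in distinct values.
fast_bh <- function(p, m = length(p)) {
  u <- sort(unique(p))
  cum <- findInterval(u, sort(p))
  raw <- pmin(m * u / cum, 1)
  q_u <- rev(cummin(rev(raw)))
  q_u[match(p, u)]
}

encode_seq <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
  x  # N and other ambiguity codes become NA
}

# Integer score at every start position for one strand of one replicon.
position_scores <- function(codes, stab, circular) {
  L <- length(codes); w <- nrow(stab)
  if (circular) {
    codes <- c(codes, codes[seq_len(w - 1L)])
    npos <- L
  } else {
    npos <- L - w + 1L
    if (npos < 1) return(integer())
  }
  total <- numeric(npos)
  for (j in seq_len(w)) {
    total <- total + stab[j, ][codes[j:(j + npos - 1L)]]
  }
  as.integer(round(total))
}

#' Scan a genome with a PSSM or a GRE
#'
#' Scores every position on both strands of every replicon (wrapping on
#' circular replicons), computes exact p-values by dynamic-programming
#' convolution of the discretised per-position score distributions, applies
#' Benjamini-Hochberg per PSSM across all scanned positions, and returns
#' hits with q at or below `qmax`. Reverse-strand matches are reported at
#' forward-strand coordinates with `strand = "-"`. For a GRE (see
#' [build_gres()]), hits of all member PSSMs are pooled, tagged by member.
#'
#' @param x A [pssm], a single GRE element of a `gre_set`, or a `gre_set`.
#' @param genome A [genome_annotation()].
#' @param background 0-order base frequencies over (A, C, G, T); default
#'   uniform.
#' @param qmax q-value threshold for reported hits (default 0.01).
#' @param bin Score discretisation in log2 units (default 1e-3).
#' @param motifs For a `gre_set`/GRE built from motif indices: the motif
#'   list the indices refer to.
#' @return Tibble: `gre_id` (NA for a bare PSSM), `member`, `replicon_id`,
#'   `position` (0-based forward-strand start), `width`, `strand`, `score`
#'   (log2 units), `p_value`, `q_value`.
#' @export
scan_genome <- function(x, genome, background = rep(0.25, 4), qmax = 0.01,
                        bin = 1e-3, motifs = NULL) {
  background <- background / sum(background)
  if (inherits(x, "gre_set")) {
    return(bind_rows(lapply(x, scan_genome, genome = genome,
                            background = background, qmax = qmax, bin = bin,
                            motifs = motifs)))
  }
  if (inherits(x, "pssm")) {
    members <- list(x); gre_id <- NA_integer_
  } else {  # one GRE
    members <- lapply(x$members, function(i) motifs[[i]])
    gre_id <- x$gre_id
  }
  codes_list <- lapply(genome$replicons$sequence, encode_seq)
  out <- list()
  for (k in seq_along(members)) {
    m <- members[[k]]
    stab_f <- score_table(m, background, bin)
    stab_r <- score_table(pssm_revcomp(m), background, bin)
    null_f <- score_null_tail(stab_f, background)
    null_r <- score_null_tail(stab_r, background)
    pos_rows <- list()
    for (ri in seq_len(nrow(genome$replicons))) {
      circ <- genome$replicons$topology[ri] == "circular"
      for (strand in c("+", "-")) {
        stab <- if (strand == "+") stab_f else stab_r
        nullt <- if (strand == "+") null_f else null_r
        sc <- position_scores(codes_list[[ri]], stab, circ)
        if (length(sc) == 0) next
        pv <- tail_p(sc, nullt)
        pos_rows[[length(pos_rows) + 1]] <- list(
          replicon = genome$replicons$replicon_id[ri], strand = strand,
          scores = sc, p = pv)
      }
    }
    p_all <- unlist(lapply(pos_rows, `[[`, "p"))
    q_all <- fast_bh(p_all)
    offset <- 0L
    for (pr in pos_rows) {
      np <- length(pr$p)
      q <- q_all[offset + seq_len(np)]
      offset <- offset + np
      hit <- which(q <= qmax)
      if (length(hit) > 0) {
        out[[length(out) + 1]] <- tibble(
          gre_id = gre_id, member = k, replicon_id = pr$replicon,
          position = hit - 1L, width = pssm_width(m), strand = pr$strand,
          score = pr$scores[hit] * bin, p_value = pr$p[hit], q_value = q[hit])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(gre_id = integer(), member = integer(), replicon_id = character(),
                  position = integer(), width = integer(), strand = character(),
                  score = numeric(), p_value = numeric(), q_value = numeric()))
  }
  arrange(bind_rows(out), .data$replicon_id, .data$position, .data$strand, .data$member)
}

#' Promoter-aligned GRE match profile
#'
#' Aggregates significant GRE matches onto a strand-relative coordinate
#' axis anchored at the start codon: for each position from `-upstream` to
#' `downstream - 1`, the count of significant member-PSSM matches covering
#' that position, summed over the given genes. With `dedupe = TRUE`,
#' overlapping member matches at one locus count once.
#'
#' @param hits Tibble from [scan_genome()] (already filtered at the scan's
#'   q threshold).
#' @param genome A [genome_annotation()].
#' @param genes Gene ids to aggregate over (default: all genes).
#' @param upstream,downstream Profile extent along the gene's strand.
#' @param dedupe Collapse overlapping member matches at a locus (default
#'   FALSE: matches are summed).
#' @return Tibble (`gre_id`, `position`, `count`), position being the
#'   start-codon-relative coordinate.
#' @export
gre_scan_profile <- function(hits, genome, genes = NULL,
                             upstream = 875, downstream = 125, dedupe = FALSE) {
  if (is.null(genes)) genes <- genome$genes$gene_id
  rel <- seq(-upstream, downstream - 1L)
  out <- list()
  for (gid in unique(hits$gre_id)) {
    sel <- if (is.na(gid)) is.na(hits$gre_id) else !is.na(hits$gre_id) & hits$gre_id == gid
    h <- hits[sel, ]
    cov <- list()
    for (ri in seq_len(nrow(genome$replicons))) {
      rid <- genome$replicons$replicon_id[ri]
      L <- genome$replicons$length[ri]
      v <- numeric(L)
      hr <- h[h$replicon_id == rid, ]
      if (nrow(hr) > 0) {
        if (dedupe) hr <- distinct(hr, .data$position, .data$width, .data$strand)
        for (i in seq_len(nrow(hr))) {
          posns <- (hr$position[i] + seq_len(hr$width[i]) - 1L) %% L
          v[posns + 1L] <- v[posns + 1L] + 1
        }
      }
      cov[[rid]] <- v
    }
    counts <- numeric(length(rel))
    for (g in genes) {
      gi <- match(g, genome$genes$gene_id)
      if (is.na(gi)) next
      grow <- genome$genes[gi, ]
      L <- replicon_row(genome, grow$replicon_id)$length
      gpos <- if (grow$strand == "+") (grow$start_codon_pos + rel) %% L
              else (grow$start_codon_pos - rel) %% L
      counts <- counts + cov[[grow$replicon_id]][gpos + 1L]
    }
    out[[length(out) + 1]] <- tibble(gre_id = gid, position = rel,
                                     count = as.integer(counts))
  }
  bind_rows(out)
}
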