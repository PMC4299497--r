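toy_genome <- function(L = 5000, id = "chr") {
  genome_annotation(
    tibble::tibble(replicon_id = id, length = L, topology = "linear",
                   sequence = strrep("A", L)),
    tibble::tibble(gene_id = "g1", replicon_id = id, start = 10L, end = 100L,
                   strand = "+"))
}

test_that("binned overlap test reproduces the direct hypergeometric tail", {
  g <- toy_genome(5000)  # 100 bins of 50 nt
  # TF marks bins 0..9; hits occupy 5 distinct bins, all inside the TF's
  sites <- tibble::tibble(replicon_id = "chr", start = seq(0, 450, 50), end = seq(10, 460, 50))
  hits <- tibble::tibble(replicon_id = "chr", position = seq(0, 200, 50), width = 10L)
  p <- pssm_site_overlap_test(hits, sites, g)
  # all 5 drawn bins marked: P(X >= 5) = C(10,5) C(90,0) / C(100,5)
  expect_equal(p, choose(10, 5) / choose(100, 5), tolerance = 1e-12)
  expect_equal(p, phyper(4, 10, 90, 5, lower.tail = FALSE), tolerance = 1e-15)

  # zero hits give p = 1; monotone in the overlap
  expect_equal(pssm_site_overlap_test(hits[0, ], sites, g), 1)
  hits_out <- dplyr::mutate(hits, position = position + 2500L)
  expect_gt(pssm_site_overlap_test(hits_out, sites, g), p)

  expect_error(pssm_site_overlap_test(dplyr::mutate(hits, width = 60L), sites, g),
               "bin_size")
})

test_that("random hit locations give roughly uniform, conservative p-values", {
  set.seed(77)
  g <- toy_genome(50000)  # 1000 bins
  sites <- tibble::tibble(replicon_id = "chr",
                          start = seq(0, 50 * 49, 50)[1:50], end = seq(10, 50 * 49 + 10, 50)[1:50])
  ps <- replicate(400, {
    pos <- sample(seq(0, 49950, 10), 20)
    pssm_site_overlap_test(tibble::tibble(replicon_id = "chr", position = pos,
                                          width = 10L), sites, g)
  })
  # discrete upper-tail p-values are super-uniform: P(p <= t) <= t
  for (t in c(0.05, 0.2, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 400))
  }
  expect_gt(mean(ps <= 0.8), 0.4)
})

test_that("GRE-TF matching keeps only the most significant TF as best", {
  g <- toy_genome(5000)
  base <- onehot_pssm("ACGTACGTAC")
  fake_gre <- structure(list(list(gre_id = 1L, members = 1:10,
                                  offsets = rep(0L, 10),
                                  orientations = rep("same", 10),
                                  medoid = 1L, combined = base)),
                        class = "gre_set")
  # all 10 member PSSMs hit the same 5 loci
  hits <- dplyr::bind_rows(lapply(1:10, function(k) {
    tibble::tibble(gre_id = 1L, member = k, replicon_id = "chr",
                   position = c(100L, 600L, 1100L, 1600L, 2100L), width = 10L,
                   strand = "+", score = 20, p_value = 1e-8, q_value = 1e-4)
  }))
  sites <- dplyr::bind_rows(
    tibble::tibble(tf_id = "TF_x", replicon_id = "chr",
                   start = c(100L, 600L, 1100L, 1600L), end = c(115L, 615L, 1115L, 1615L),
                   strand = NA_character_),
    tibble::tibble(tf_id = "TF_y", replicon_id = "chr",
                   start = c(3000L, 3500L, 4000L), end = c(3015L, 3515L, 4015L),
                   strand = NA_character_))
  m <- match_gre_to_tf(fake_gre, hits, sites, g)
  expect_equal(m$n_significant[m$tf_id == "TF_x"], 10L)
  expect_equal(m$n_significant[m$tf_id == "TF_y"], 0L)
  expect_true(m$best[m$tf_id == "TF_x"])
  expect_false(m$best[m$tf_id == "TF_y"])
  expect_equal(sum(m$best), 1L)  # at most one best per GRE
})

test_that("perfect predictions give AUPR 1 and an empty gold standard errors", {
  gold <- tibble::tibble(tf_id = c("t1", "t1"), gene_id = c("ga", "gb"))
  perfect <- dplyr::mutate(gold, confidence = c(0.9, 0.8))
  pr <- precision_recall_aupr(perfect, gold)
  expect_equal(pr$aupr, 1)
  expect_true(all(pr$curve$precision == 1))
  expect_equal(unname(pr$hits_at["0.5"]), 2L)
  expect_error(precision_recall_aupr(perfect, gold[0, ]), "empty gold")
})

test_that("AUPR of a hand-ranked 4-prediction curve equals the hand-summed trapezoid", {
  # predictions rank [TP, FP, TP, FP] against a 4-edge gold standard whose
  # universe keeps all four genes in play
  gold <- tibble::tibble(tf_id = c("t1", "t1", "t3", "t3"),
                         gene_id = c("ga", "gb", "gx", "gy"))
  preds <- tibble::tibble(tf_id = "t1", gene_id = c("ga", "gx", "gb", "gy"),
                          confidence = c(0.9, 0.8, 0.7, 0.6))
  pr <- precision_recall_aupr(preds, gold)
  expect_equal(pr$curve$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(pr$curve$recall, c(1 / 4, 1 / 4, 2 / 4, 2 / 4))
  # trapezoid anchored at (0, 1):
  #   0.25 * 1 + 0 + 0.25 * (1/2 + 2/3)/2 + 0
  expect_equal(pr$aupr, 0.25 + 0.25 * (1 / 2 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(unname(pr$hits_at), c(2L, 2L, 2L))

  # predictions outside the gold universe are dropped before ranking
  outside <- dplyr::mutate(preds, gene_id = c("ga", "zz1", "gb", "zz2"))
  pr2 <- precision_recall_aupr(outside, gold)
  expect_equal(pr2$n_predictions, 2L)
  expect_equal(pr2$curve$precision, c(1, 1))
})

test_that("random rankings give AUPR near the gold prevalence", {
  set.seed(55)
  tfs <- sprintf("t%d", 1:20); genes <- sprintf("g%03d", 1:100)
  all_edges <- tidyr::expand_grid(tf_id = tfs, gene_id = genes)
  gold <- all_edges[sample(nrow(all_edges), 100), ]
  prevalence <- 100 / nrow(all_edges)
  auprs <- replicate(10, {
    preds <- dplyr::mutate(all_edges, confidence = runif(dplyr::n()))
    precision_recall_aupr(preds, gold)$aupr
  })
  # a small positive bias over the prevalence is expected at finite size
  expect_lt(abs(mean(auprs) - prevalence), 0.05)
  expect_lt(mean(auprs), 0.25)  # far below any informative ranking
})

test_that("fitness coherence KS matches a direct empirical-CDF sweep", {
  set.seed(66)
  fit <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("f%d", 1:12)))
  # a tightly correlated group: copies of one vector plus tiny noise
  for (g in sprintf("g%02d", 1:5)) fit[g, ] <- fit["g01", ] + rnorm(12, sd = 0.01)
  res <- fitness_coherence_ks(list(grp = list(sprintf("g%02d", 1:5))), fit)
  expect_equal(res$n_pairs, 10L)
  expect_equal(res$captured_at_0.9, 10L)

  # oracle: direct sweep over the pooled sample points
  cors <- cor(t(fit))
  A <- cors[sprintf("g%02d", 1:5), sprintf("g%02d", 1:5)]
  A <- A[upper.tri(A)]
  B <- cors[upper.tri(cors)]
  xs <- sort(unique(c(A, B)))
  D_oracle <- max(sapply(xs, function(x) mean(B <= x) - mean(A <= x)))
  expect_equal(res$D, D_oracle, tolerance = 1e-12)

  # identical samples give D = 0 and sets with < 2 genes contribute nothing
  res0 <- fitness_coherence_ks(list(all = list(rownames(fit)),
                                    tiny = list("g01")), fit)
  expect_equal(res0$D[res0$method == "all"], 0, tolerance = 1e-12)
  expect_equal(res0$n_pairs[res0$method == "tiny"], 0L)
})
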