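make_genome <- function(seq, topology = "linear", id = "chr") {
  genome_annotation(
    tibble::tibble(replicon_id = id, length = nchar(seq), topology = topology,
                   sequence = seq),
    tibble::tibble(gene_id = "g1", replicon_id = id, start = 10L,
                   end = min(40L, nchar(seq)), strand = "+"))
}

test_that("a planted consensus word is the top hit, on the correct strand", {
  set.seed(5)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  word <- "ACGTACGGTA"
  m <- onehot_pssm(word)
  seq <- paste0(substr(bg, 1, 1000), word, substr(bg, 1011, 3000))
  hits <- scan_genome(m, make_genome(seq), qmax = 0.05)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$position, 1000L)
  expect_equal(top$strand, "+")

  # reverse complement of the word is reported at forward coordinates, "-"
  rcword <- "TACCGTACGT"
  seq2 <- paste0(substr(bg, 1, 2000), rcword, substr(bg, 2011, 3000))
  hits2 <- scan_genome(m, make_genome(seq2), qmax = 0.05)
  top2 <- hits2[hits2$strand == "-", ][1, ]
  expect_equal(top2$position, 2000L)
  expect_equal(top2$strand, "-")
})

test_that("dynamic-programming tail probabilities equal brute-force word enumeration", {
  for (w in c(4, 6)) {
    m <- random_pssm(w, seed = 20 + w)
    for (bg in list(rep(0.25, 4), c(0.4, 0.1, 0.1, 0.4))) {
      stab <- egrin2:::score_table(m, bg)
      null <- egrin2:::score_null_tail(stab, bg)
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      wscore <- rowSums(matrix(stab[cbind(rep(seq_len(w), each = nrow(words)),
                                          as.vector(words))], ncol = w))
      wprob <- apply(words, 1, function(x) prod(bg[x]))
      for (s in sample(unique(wscore), 25)) {
        expect_equal(egrin2:::tail_p(s, null), sum(wprob[wscore >= s]),
                     tolerance = 1e-12)
      }
      # tails are monotone and bounded
      expect_true(all(diff(null$tail) <= 1e-15))
      expect_equal(egrin2:::tail_p(null$min, null), 1, tolerance = 1e-12)
    }
  }
})

test_that("grouped Benjamini-Hochberg equals p.adjust", {
  set.seed(8)
  p <- sample(round(runif(50), 2), 5000, replace = TRUE)
  expect_equal(egrin2:::fast_bh(p), p.adjust(p, "BH"))
})

test_that("circular scanning wraps across the origin", {
  set.seed(9)
  bg <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  word <- strsplit("ACGTAACCGG", "")[[1]]
  # plant across the origin: last 5 bases + first 5 bases
  bg[1996:2000] <- word[1:5]; bg[1:5] <- word[6:10]
  g <- make_genome(paste(bg, collapse = ""), topology = "circular")
  hits <- scan_genome(onehot_pssm("ACGTAACCGG"), g, qmax = 0.1)
  expect_true(any(hits$position == 1995L & hits$strand == "+"))
})

test_that("promoter profiles sum member matches at start-codon-relative positions", {
  seq <- strrep("A", 2000)
  g <- genome_annotation(
    tibble::tibble(replicon_id = "chr", length = 2000L, topology = "linear",
                   sequence = seq),
    tibble::tibble(gene_id = c("gp", "gm"), replicon_id = "chr",
                   start = c(1000L, 200L), end = c(1300L, 500L),
                   strand = c("+", "-")))
  # one hit of width 6 starting 30 nt upstream of gp's start codon
  hits <- tibble::tibble(gre_id = 1L, member = 1L, replicon_id = "chr",
                         position = 970L, width = 6L, strand = "+",
                         score = 10, p_value = 1e-6, q_value = 1e-4)
  prof <- gre_scan_profile(hits, g, genes = "gp")
  expect_equal(prof$count[prof$position %in% -30:-25], rep(1L, 6))
  expect_equal(sum(prof$count), 6L)

  # two members at the same locus count twice; dedupe collapses them
  hits2 <- dplyr::bind_rows(hits, dplyr::mutate(hits, member = 2L))
  prof2 <- gre_scan_profile(hits2, g, genes = "gp")
  expect_equal(prof2$count[prof2$position == -28], 2L)
  prof2d <- gre_scan_profile(hits2, g, genes = "gp", dedupe = TRUE)
  expect_equal(prof2d$count[prof2d$position == -28], 1L)

  # a minus-strand gene counts positions along its own strand: a hit at
  # forward positions 505..510 lies 6..11 nt upstream of gm's start codon 499
  hits3 <- dplyr::mutate(hits, position = 505L)
  prof3 <- gre_scan_profile(hits3, g, genes = "gm")
  expect_equal(prof3$count[prof3$position %in% -11:-6], rep(1L, 6))
})

test_that("planted motifs are recovered at the planted promoter offset", {
  fx <- small_fixture()
  motifs <- ensemble_motifs(fx$ensemble)
  gres <- discover_gres(motifs, seed = 3)
  expect_equal(length(gres), 3L)
  hits <- scan_genome(gres, fx$genome, motifs = motifs)
  prof <- gre_scan_profile(hits, fx$genome)
  agg <- dplyr::summarise(dplyr::group_by(prof, position),
                          count = sum(count), .groups = "drop")
  # instances are planted starting 100 nt upstream of each start codon; the
  # planted offset carries the maximal aggregated count (windows also see
  # neighbouring genes' instances at shifted offsets, tying the mode)
  expect_equal(agg$count[agg$position == -100], max(agg$count))
  expect_gt(agg$count[agg$position == -100], 0)
})
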