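test_that("fixture generation is fully deterministic under a seed", {
  cfg <- noiseless_config(seed = 9, n_genes = 40, n_conditions = 20,
                          n_modules = 2, module_size_range = c(4, 6),
                          n_runs = 4, promoter_length = 200)
  f1 <- generate_fixture(cfg)
  f2 <- generate_fixture(cfg)
  expect_identical(f1$genome$replicons$sequence, f2$genome$replicons$sequence)
  expect_identical(f1$expression, f2$expression)
  expect_identical(f1$ensemble$biclusters$genes, f2$ensemble$biclusters$genes)
  expect_identical(f1$fitness, f2$fitness)
  expect_identical(f1$tf_sites, f2$tf_sites)
  # and byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(f1, d1); write_fixture(f2, d2)
  files <- list.files(d1, recursive = TRUE)
  h <- function(d) unname(tools::md5sum(file.path(d, files)))
  expect_identical(h(d1), h(d2))
})

test_that("config invariants are enforced", {
  expect_error(fixture_config(gene_dropout_rate = 1.5), "rates")
  expect_error(fixture_config(module_size_range = c(2, 5)), ">= 3")
  expect_error(fixture_config(n_runs = 0), "n_runs")
  expect_error(fixture_config(promoter_length = 10, planted_motif_width = 14),
               "promoter_length")
})

test_that("information content 2 plants one-hot PSSMs whose instances equal the consensus", {
  fx <- small_fixture()  # IC defaults to 2 bits/column
  gt <- fx$ground_truth
  for (m in seq_along(gt$pssms)) {
    expect_true(all(gt$pssms[[m]]$prob %in% c(0, 1)))
  }
  seqs <- strsplit(fx$genome$replicons$sequence, "")[[1]]
  for (r in seq_len(nrow(gt$instances))) {
    inst <- gt$instances[r, ]
    word <- paste(seqs[(inst$start + 1):inst$end], collapse = "")
    expect_equal(word, pssm_consensus(gt$pssms[[inst$module_id]]))
  }
  # every planted instance lies inside its gene's promoter window
  for (r in seq_len(nrow(gt$instances))) {
    inst <- gt$instances[r, ]
    win <- promoter_window(inst$gene_id, fx$genome)
    inside <- any(inst$start >= win$start & inst$end <= win$end)
    expect_true(inside)
  }
})

test_that("zero emission rate plants no instances", {
  cfg <- fixture_config(seed = 9, n_genes = 30, n_conditions = 10,
                        n_modules = 2, module_size_range = c(3, 4),
                        motif_emission_rate = 0, promoter_length = 200)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$ground_truth$instances), 0L)
})

test_that("noiseless expression collapses module genes to a common value in active blocks", {
  fx <- small_fixture()
  gt <- fx$ground_truth
  for (m in 1:2) {
    sub <- fx$expression[gt$modules$genes[[m]], gt$modules$active_conditions[[m]]]
    expect_equal(apply(sub, 2, stats::sd), setNames(rep(0, ncol(sub)), colnames(sub)))
    expect_true(all(abs(colMeans(sub)) >= 1))
  }
})

test_that("module genes in non-active conditions correlate like background genes", {
  cfg <- fixture_config(seed = 17, n_genes = 80, n_conditions = 60,
                        n_modules = 2, module_size_range = c(8, 10),
                        condition_block_length = 10, promoter_length = 200)
  g <- generate_genome(cfg)
  expr <- generate_expression(cfg, g$ground_truth)
  gt <- g$ground_truth
  inactive <- setdiff(colnames(expr),
                      unique(unlist(gt$modules$active_conditions)))
  mod <- gt$modules$genes[[1]]
  cors_mod <- cor(t(expr[mod, inactive]))
  cors_mod <- cors_mod[upper.tri(cors_mod)]
  bg_genes <- setdiff(rownames(expr), unlist(gt$modules$genes))[1:20]
  cors_bg <- cor(t(expr[bg_genes, inactive]))
  cors_bg <- cors_bg[upper.tri(cors_bg)]
  expect_gt(suppressWarnings(ks.test(cors_mod, cors_bg)$p.value), 0.001)
})

test_that("bicluster emission frequency matches the closed-form block-overlap probability", {
  cfg <- fixture_config(seed = 23, n_genes = 40, n_conditions = 50,
                        n_modules = 1, module_size_range = c(5, 5),
                        condition_block_length = 2,
                        conditions_per_run_fraction = 0.3,
                        n_runs = 100, promoter_length = 200)
  g <- generate_genome(cfg)
  expr <- generate_expression(cfg, g$ground_truth)
  ens <- generate_ensemble(cfg, g$ground_truth, expr)
  mod <- g$ground_truth$modules$genes[[1]]
  n_emitted <- sum(purrr::map_lgl(ens$biclusters$genes,
                                  ~ length(intersect(.x, mod)) >= 3))
  # P(block of 2 intersects a 15-condition sample of 50) = 1 - C(48,15)/C(50,15)
  p_hit <- 1 - choose(48, 15) / choose(50, 15)
  expect_lt(abs(n_emitted - 100 * p_hit), 4 * sqrt(100 * p_hit * (1 - p_hit)) + 1)
})

test_that("noiseless biclusters reproduce planted modules exactly, with decoys alongside", {
  fx <- small_fixture()
  gt <- fx$ground_truth
  mods <- lapply(gt$modules$genes, sort)
  exact <- purrr::map_lgl(fx$ensemble$biclusters$genes, function(g) {
    any(purrr::map_lgl(mods, ~ identical(sort(g), .x)))
  })
  # half the biclusters are decoys by construction
  expect_equal(sum(exact), nrow(fx$ensemble$biclusters) / 2)
})

test_that("auxiliary fixtures honour their construction contracts", {
  fx <- small_fixture()
  # one synthetic TF per planted motif, >= 3 unique sites at emission 1
  counts <- dplyr::count(fx$tf_sites, tf_id)
  expect_equal(nrow(counts), 3L)
  expect_true(all(counts$n >= 3))
  # gold standard covers exactly the planted instances
  expect_setequal(unique(fx$gold_edges$tf_id), sprintf("TF_m%d", 1:3))
  # condition groups include each planted active block
  gt <- fx$ground_truth
  for (m in 1:3) {
    grp <- fx$condition_annotation$condition_id[
      fx$condition_annotation$group == sprintf("block_m%d", m)]
    expect_setequal(grp, gt$modules$active_conditions[[m]])
  }
  # operons are consecutive runs of at least 2 genes
  sizes <- dplyr::count(fx$operons, operon_id)
  expect_true(all(sizes$n >= 2))
})

test_that("a fitness correlation target of 1 makes within-module vectors identical copies", {
  cfg <- noiseless_config(seed = 12, n_genes = 30, n_conditions = 10,
                          n_modules = 2, module_size_range = c(4, 4),
                          promoter_length = 200,
                          fitness_within_correlation = 1)
  g <- generate_genome(cfg)
  aux <- generate_auxiliary(cfg, g$ground_truth)
  for (m in 1:2) {
    sub <- aux$fitness[g$ground_truth$modules$genes[[m]], ]
    cors <- cor(t(sub))
    expect_equal(cors[upper.tri(cors)], rep(1, sum(upper.tri(cors))),
                 tolerance = 1e-12)
  }
})
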