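test_that("RSD follows |sigma/mu| with sample SD and flags degenerate input", {
  mat <- matrix(c(2, 1, -1,
                  2, 2, 1,
                  2, 3, NA), nrow = 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  expect_equal(corem_rsd(c("g1", "g2", "g3"), mat, "c1"), 0)
  expect_equal(corem_rsd(c("g1", "g2", "g3"), mat, "c2"), 0.5)
  v <- corem_rsd(c("g1", "g2", "g3"), mat, "c3")  # values -1, 1 -> mu = 0
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "zero mean")
  v2 <- corem_rsd(c("g1", "g3"), mat, "c3")  # single usable value
  expect_equal(attr(v2, "reason"), "insufficient data")
})

test_that("RSD is scale invariant and the permutation test is seed-deterministic", {
  set.seed(31)
  mat <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:20)))
  genes <- sprintf("g%02d", 1:6)
  base <- corem_rsd(genes, mat, "c03")
  mat2 <- mat; mat2[, "c03"] <- mat2[, "c03"] * -7.5
  expect_equal(corem_rsd(genes, mat2, "c03"), base)

  a1 <- rsd_permutation_test(genes, mat, n_perm = 199, seed = 5)
  a2 <- rsd_permutation_test(genes, mat, n_perm = 199, seed = 5)
  expect_identical(a1, a2)
  # the +1 correction keeps p away from zero
  expect_true(all(a1$p_value >= 1 / 200))
  expect_true(all(a1$p_value <= 1))
})

test_that("a corem spanning the whole gene universe has p = 1 everywhere", {
  set.seed(32)
  mat <- matrix(rnorm(12 * 6), 12, 6,
                dimnames = list(sprintf("g%02d", 1:12), sprintf("c%d", 1:6)))
  a <- rsd_permutation_test(rownames(mat), mat, n_perm = 50, seed = 1)
  expect_true(all(a$p_value == 1))
  expect_error(rsd_permutation_test(c(rownames(mat), "extra"), mat), "not in expression")
})

test_that("noiseless planted modules hit the permutation floor in their active block", {
  fx <- small_fixture()
  gt <- fx$ground_truth
  for (m in 1:2) {
    a <- rsd_permutation_test(gt$modules$genes[[m]], fx$expression,
                              n_perm = 199, seed = 7)
    active <- a$condition_id %in% gt$modules$active_conditions[[m]]
    expect_equal(a$rsd[active], rep(0, sum(active)), tolerance = 1e-6)
    expect_equal(a$p_value[active], rep(1 / 200, sum(active)))
    expect_true(all(a$coregulated[active]))
    # the planted block is always contained in the recovered blocks
    blocks <- coregulated_blocks(a, min_len = 3)
    expect_true(all(gt$modules$active_conditions[[m]] %in% blocks$condition_id))
  }
})

test_that("block aggregation prunes runs shorter than the minimum length", {
  act <- tibble::tibble(condition_id = sprintf("c%02d", 1:12),
                        coregulated = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                        TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  b <- coregulated_blocks(act, min_len = 3)
  expect_equal(unique(b$block), 1L)
  expect_equal(b$condition_id, sprintf("c%02d", 4:7))
  expect_equal(nrow(coregulated_blocks(act, min_len = 5)), 0L)
})

test_that("GRE association needs both a promoter hit and top-bicluster support", {
  fx <- small_fixture()
  motifs <- ensemble_motifs(fx$ensemble)
  gres <- discover_gres(motifs, seed = 3)
  hits <- scan_genome(gres, fx$genome, motifs = motifs)
  gt <- fx$ground_truth
  # identify which GRE carries which planted motif
  gre_module <- purrr::map_int(gres, function(g) {
    which.min(purrr::map_dbl(gt$pssms, ~ pssm_distance(g$combined, .x)$distance))
  })
  for (m in 1:3) {
    assoc <- associate_gres_to_corem(gt$modules$genes[[m]], gres, hits,
                                     motifs, fx$ensemble, fx$genome)
    own <- assoc[assoc$gre_id == which(gre_module == m), ]
    expect_true(own$associated)
    expect_true(own$has_promoter_hit && own$in_top_biclusters)
    # foreign GREs fail the top-bicluster criterion
    foreign <- assoc[assoc$gre_id != which(gre_module == m), ]
    expect_false(any(foreign$in_top_biclusters))
    # the top-weight GRE is the module's own planted motif
    expect_equal(assoc$gre_id[which.max(assoc$weight)], which(gre_module == m))
  }
})

test_that("GRE composition weights are normalised and ordered", {
  assoc <- tibble::tibble(gre_id = c(2L, 7L, 9L),
                          has_promoter_hit = c(TRUE, TRUE, FALSE),
                          in_top_biclusters = c(TRUE, TRUE, TRUE),
                          n_supporting = c(30L, 10L, 50L),
                          associated = c(TRUE, TRUE, FALSE))
  comp <- corem_gre_composition(assoc)
  expect_equal(comp$gre_id, c(2L, 7L))
  expect_equal(comp$weight, c(0.75, 0.25))
  expect_equal(sum(comp$weight), 1)
  none <- dplyr::mutate(assoc, associated = FALSE)
  expect_equal(nrow(corem_gre_composition(none)), 0L)
})

test_that("condition-group enrichment follows the hypergeometric upper tail", {
  universe <- sprintf("c%02d", 1:10)
  coreg <- universe[1:4]
  ann <- tibble::tibble(condition_id = universe[1:4], group = "exact")
  e <- condition_enrichment(coreg, ann, universe)
  expect_equal(e$p_value, 1 / choose(10, 4), tolerance = 1e-12)

  ann2 <- tibble::tibble(condition_id = universe[5:7], group = "disjoint")
  e2 <- condition_enrichment(coreg, ann2, universe)
  expect_equal(e2$p_value, 1)

  # co-regulated set = universe: any overlap is forced, p = 1
  ann3 <- tibble::tibble(condition_id = universe[2:5], group = "g")
  e3 <- condition_enrichment(universe, ann3, universe)
  expect_equal(e3$p_value, 1)

  # groups outside the universe are skipped
  ann4 <- tibble::tibble(condition_id = c("zz1", "zz2"), group = "absent")
  expect_equal(nrow(condition_enrichment(coreg, ann4, universe)), 0L)
})

test_that("operon splitting is flagged for distinct corem intersection patterns", {
  operons <- tibble::tibble(operon_id = rep(c("op1", "op2", "op3"), each = 3),
                            gene_id = c("a", "b", "c", "d", "e", "f", "h", "i", "j"))
  corems <- tibble::tibble(corem_id = 1:3,
                           genes = list(c("a", "b", "c", "z"), c("b", "c"),
                                        c("h", "i", "j")))
  rep <- detect_operon_splits(operons, corems)
  expect_equal(rep$status[rep$operon_id == "op1"], "conditional isoforms predicted")
  expect_equal(sort(purrr::map_chr(rep$patterns[rep$operon_id == "op1"][[1]],
                                   paste, collapse = ",")),
               c("a,b,c", "b,c"))
  expect_equal(rep$status[rep$operon_id == "op2"], "no co-regulation evidence")
  expect_equal(rep$status[rep$operon_id == "op3"], "single isoform")
})
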