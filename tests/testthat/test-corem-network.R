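mini_ensemble <- function(gene_sets) {
  ensemble(tibble::tibble(
    bicluster_id = sprintf("b%d", seq_along(gene_sets)),
    run_id = "r1",
    genes = gene_sets,
    conditions = list("c1")[rep(1, length(gene_sets))],
    motifs = rep(list(list()), length(gene_sets))))
}

test_that("co-occurrence weights count shared bicluster memberships", {
  ens <- mini_ensemble(list(c("g1", "g2", "g3"), c("g1", "g2")))
  net <- count_cooccurrence(ens)
  w <- function(a, b) net$weight[net$gene_a == a & net$gene_b == b]
  expect_equal(w("g1", "g2"), 2)
  expect_equal(w("g1", "g3"), 1)
  expect_equal(w("g2", "g3"), 1)
  # genes never co-clustered are absent
  expect_false("g9" %in% c(net$gene_a, net$gene_b))
})

test_that("co-occurrence equals an independent all-pairs recount on a random ensemble", {
  set.seed(14)
  genes <- sprintf("g%02d", 1:25)
  sets <- lapply(1:100, function(i) sample(genes, sample(3:8, 1)))
  net <- count_cooccurrence(mini_ensemble(sets))
  # brute force: count every unordered pair directly
  counts <- new.env()
  for (s in sets) {
    s <- sort(s)
    for (i in seq_len(length(s) - 1)) for (j in seq(i + 1, length(s))) {
      k <- paste(s[i], s[j])
      prev <- if (exists(k, envir = counts, inherits = FALSE)) get(k, envir = counts) else 0
      assign(k, prev + 1, envir = counts)
    }
  }
  for (r in seq_len(nrow(net))) {
    expect_equal(net$weight[r],
                 get(paste(net$gene_a[r], net$gene_b[r]), envir = counts))
  }
  expect_equal(nrow(net), length(ls(counts)))
})

test_that("disparity alpha follows the closed form and the OR retention rule", {
  net <- tibble::tibble(gene_a = "x", gene_b = c("p", "q", "r"),
                        weight = c(6, 3, 1))
  d <- disparity_filter(net, alpha = 0.05)
  expect_equal(d$alpha_a, c(0.16, 0.49, 0.81))   # (1 - p)^(k-1), k = 3
  expect_equal(d$alpha_b, c(1, 1, 1))            # degree-1 endpoints
  expect_false(any(d$retained))

  # uniform weights over k = 2: alpha = 0.5 each, never retained at 0.05
  net2 <- tibble::tibble(gene_a = "x", gene_b = c("p", "q"), weight = c(5, 5))
  d2 <- disparity_filter(net2, alpha = 0.05)
  expect_equal(d2$alpha_a, c(0.5, 0.5))

  # star centre with a dominant edge: alpha -> 0, always retained
  net3 <- tibble::tibble(gene_a = "x", gene_b = sprintf("n%d", 1:10),
                         weight = c(1000, rep(1, 9)))
  d3 <- disparity_filter(net3, alpha = 0.05)
  expect_true(d3$retained[1])
  expect_false(any(d3$retained[-1]))

  expect_error(disparity_filter(net, alpha = 1.5), "alpha")
})

test_that("disparity alpha matches numeric integration of the filter integrand", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    net <- tibble::tibble(gene_a = sprintf("n%d", sample(n, 40, replace = TRUE)),
                          gene_b = sprintf("n%d", sample(n, 40, replace = TRUE)),
                          weight = round(runif(40, 1, 20)))
    net <- dplyr::filter(net, gene_a < gene_b)
    net <- dplyr::summarise(dplyr::group_by(net, gene_a, gene_b),
                            weight = sum(weight), .groups = "drop")
    d <- disparity_filter(net)
    strength <- tapply(c(net$weight, net$weight), c(net$gene_a, net$gene_b), sum)
    degree <- tapply(c(net$weight, net$weight), c(net$gene_a, net$gene_b), length)
    for (r in seq_len(nrow(d))) {
      for (side in c("a", "b")) {
        node <- d[[paste0("gene_", side)]][r]
        k <- degree[[node]]
        expected <- if (k < 2) 1 else {
          p <- d$weight[r] / strength[[node]]
          1 - stats::integrate(function(x) (k - 1) * (1 - x)^(k - 2), 0, p,
                               rel.tol = 1e-12)$value
        }
        expect_equal(d[[paste0("alpha_", side)]][r], expected, tolerance = 1e-9)
      }
    }
  }
})

test_that("lowering alpha never adds backbone edges", {
  fx <- small_fixture()
  net <- count_cooccurrence(fx$ensemble)
  keys <- function(alpha) {
    b <- backbone(disparity_filter(net, alpha))
    paste(b$gene_a, b$gene_b)
  }
  k10 <- keys(0.10); k05 <- keys(0.05); k01 <- keys(0.01)
  expect_true(all(k05 %in% k10))
  expect_true(all(k01 %in% k05))
})

test_that("link similarity follows the inclusive-neighbourhood Jaccard", {
  tri <- tibble::tibble(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  expect_equal(link_similarity(tri, c("a", "b"), c("a", "c")), 1)
  expect_equal(link_similarity(tri, c("a", "b"), c("a", "b")), 1)
  withpend <- dplyr::bind_rows(tri, tibble::tibble(gene_a = "a", gene_b = "d"))
  expect_equal(link_similarity(withpend, c("a", "b"), c("a", "d")), 0.25)
  expect_equal(link_similarity(withpend, c("b", "c"), c("a", "d")), 0)
})

test_that("partition density is 1 for cliques and 0 for trees", {
  clique <- utils::combn(letters[1:4], 2)
  ce <- tibble::tibble(gene_a = clique[1, ], gene_b = clique[2, ])
  expect_equal(partition_density(ce, rep(1L, nrow(ce)))$D, 1)
  tree <- tibble::tibble(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"))
  expect_equal(partition_density(tree, rep(1L, 3))$D, 0)
})

test_that("two cliques sharing a node give two link communities and overlapping corems", {
  q1 <- utils::combn(c("x", "a", "b", "c"), 2)
  q2 <- utils::combn(c("x", "d", "e", "f"), 2)
  g <- tibble::tibble(gene_a = c(q1[1, ], q2[1, ]), gene_b = c(q1[2, ], q2[2, ]))
  lc <- link_communities(g)
  expect_equal(length(unique(lc$edges$community)), 2L)
  expect_equal(lc$D, 1)
  # the chosen cut maximises D over all evaluated cuts
  expect_true(all(lc$D >= lc$heights$D - 1e-12))
  # communities partition the links
  expect_equal(sum(lc$communities$m), nrow(g))

  corems <- extract_corems(lc)
  expect_equal(nrow(corems), 2L)
  expect_true(all(purrr::map_lgl(corems$genes, ~ "x" %in% .x)))

  # a single-edge community falls below the corem size threshold
  lone <- tibble::tibble(gene_a = "u", gene_b = "v")
  lc1 <- link_communities(lone)
  expect_equal(nrow(extract_corems(lc1)), 0L)

  expect_error(link_communities(lone[0, ]), "no links")
})
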