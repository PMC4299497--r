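# Shared helpers: small PSSM constructors and a cached small fixture.

random_pssm <- function(width, seed = NULL, pseudocount = 0.001) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(width * 4), ncol = 4)
  pssm(m / rowSums(m), pseudocount = pseudocount)
}

onehot_pssm <- function(bases, pseudocount = 0.001) {
  idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0, nrow = length(idx), ncol = 4)
  m[cbind(seq_along(idx), idx)] <- 1
  pssm(m, pseudocount = pseudocount)
}

# Independent brute-force oracle for pssm_distance: plain loops, no shared
# code with the implementation.
oracle_pssm_distance <- function(a, b, min_overlap = 6) {
  revcomp_mat <- function(p) p[rev(seq_len(nrow(p))), c(4, 3, 2, 1)]
  best <- Inf
  for (orient in 1:2) {
    bm <- if (orient == 1) b$prob else revcomp_mat(b$prob)
    wa <- nrow(a$prob); wb <- nrow(bm)
    for (off in -wb:wa) {
      cols <- 0; tot <- 0
      for (j in seq_len(wb)) {
        ai <- off + j
        if (ai >= 1 && ai <= wa) {
          cols <- cols + 1
          tot <- tot + sqrt(sum((a$prob[ai, ] - bm[j, ])^2))
        }
      }
      if (cols >= min_overlap && tot / cols < best) best <- tot / cols
    }
  }
  best
}

# Small noiseless fixture shared by cheap tests (built once per test run).
.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    cfg <- noiseless_config(seed = 3, n_genes = 60, n_conditions = 40,
                            n_modules = 3, module_size_range = c(6, 8),
                            n_runs = 12, promoter_length = 300)
    .fixture_cache$fx <- generate_fixture(cfg)
  }
  .fixture_cache$fx
}
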