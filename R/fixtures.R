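#' Configuration for the synthetic fixture generator
#'
#' The generator plants co-regulated gene modules, each with a contiguous
#' block of active conditions and a cis-regulatory motif placed at a fixed
#' offset in member promoters, then emulates an ensemble of biclustering
#' runs over condition subsamples, with gene dropout, spurious genes, motif
#' column noise, and decoy biclusters. Defaults are the package's reference
#' study conditions (see the methods vignette).
#'
#' @param seed Integer seed; the same seed reproduces every artifact
#'   byte-identically.
#' @param n_genes,n_conditions Compendium dimensions.
#' @param n_modules Number of planted modules.
#' @param module_size_range Inclusive range of module sizes (genes).
#' @param module_gene_overlap_fraction Fraction of genes shared between
#'   consecutive modules (0 = disjoint).
#' @param condition_blocks_per_module Contiguous active blocks per module.
#' @param condition_block_length Length of each active block; `NULL` means
#'   15% of `n_conditions` (at least 3).
#' @param planted_motif_width Motif width in nt.
#' @param planted_motif_information_content Target bits per motif position
#'   (2 = one-hot columns, instances equal the consensus).
#' @param promoter_length Intergenic spacing upstream of each gene, nt.
#' @param gene_length Coding length of each gene, nt.
#' @param expression_noise_sd Per-gene expression noise, log-ratio units.
#' @param n_runs Number of emulated biclustering runs.
#' @param conditions_per_run_fraction Fraction of conditions sampled per run.
#' @param gene_dropout_rate Per-gene probability a module member is dropped
#'   from a bicluster.
#' @param spurious_gene_rate Expected spurious genes per bicluster, as a
#'   fraction of module size.
#' @param motif_emission_rate Per-gene probability a motif instance is
#'   planted in the promoter.
#' @param motif_noise Magnitude of Dirichlet column noise on bicluster
#'   motifs (0 = exact copies of the planted PSSM; the Dirichlet
#'   concentration is `1/motif_noise`).
#' @param fitness_conditions Number of fitness conditions.
#' @param fitness_within_correlation Target pairwise Pearson correlation of
#'   fitness vectors within a module (1 = identical copies).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_genes = 200L,
                           n_conditions = 100L,
                           n_modules = 5L,
                           module_size_range = c(10L, 20L),
                           module_gene_overlap_fraction = 0,
                           condition_blocks_per_module = 1L,
                           condition_block_length = NULL,
                           planted_motif_width = 14L,
                           planted_motif_information_content = 2,
                           promoter_length = 1000L,
                           gene_length = 120L,
                           expression_noise_sd = 0.3,
                           n_runs = 20L,
                           conditions_per_run_fraction = 0.5,
                           gene_dropout_rate = 0.1,
                           spurious_gene_rate = 0.05,
                           motif_emission_rate = 1,
                           motif_noise = 0.02,
                           fitness_conditions = 30L,
                           fitness_within_correlation = 0.9) {
  cfg <- as.list(environment())
  if (is.null(cfg$condition_block_length)) {
    cfg$condition_block_length <- max(3L, round(0.15 * n_conditions))
  }
  rates <- c(cfg$module_gene_overlap_fraction, cfg$conditions_per_run_fraction,
             cfg$gene_dropout_rate, cfg$spurious_gene_rate, cfg$motif_emission_rate)
  if (!is_prob(rates)) stopf("all rates must lie in [0, 1]")
  if (min(cfg$module_size_range) < 3) stopf("module sizes must be >= 3")
  if (cfg$n_runs < 1) stopf("n_runs must be >= 1")
  if (cfg$promoter_length < cfg$planted_motif_width) {
    stopf("promoter_length (%d) < planted_motif_width (%d)",
          cfg$promoter_length, cfg$planted_motif_width)
  }
  if (cfg$planted_motif_information_content < 0 || cfg$planted_motif_information_content > 2) {
    stopf("information content must lie in [0, 2] bits/column")
  }
  structure(cfg, class = "fixture_config")
}

#' Noiseless variant of a fixture configuration
#'
#' All noise rates zero and motif emission certain: downstream recovery of
#' modules, motifs, condition blocks and the regulatory network must then
#' be exact, which is the pipeline's strongest integration test.
#'
#' @param ... Passed to [fixture_config()].
#' @export
noiseless_config <- function(...) {
  fixture_config(expression_noise_sd = 0, gene_dropout_rate = 0,
                 spurious_gene_rate = 0, motif_emission_rate = 1,
                 motif_noise = 0, ...)
}

# Strand-relative offset (relative to the start codon) at which planted
# instances begin. Fixed by design so promoter-profile recovery has a known
# mode.
PLANTED_OFFSET <- -100L

# Dominant-base probability achieving a target per-column information
# content, with the remaining mass split evenly over the other three bases.
ic_dominant_prob <- function(bits) {
  if (bits >= 2 - 1e-12) return(1)
  f <- function(p) {
    q <- (1 - p) / 3
    h <- -p * log2(p) - ifelse(q > 0, 3 * q * log2(q), 0)
    (2 - h) - bits
  }
  stats::uniroot(f, c(0.2500001, 1 - 1e-9), tol = 1e-12)$root
}

sample_planted_pssm <- function(width, bits) {
  p <- ic_dominant_prob(bits)
  cons <- sample(4, width, replace = TRUE)
  prob <- matrix((1 - p) / 3, nrow = width, ncol = 4)
  prob[cbind(seq_len(width), cons)] <- p
  prob <- prob / rowSums(prob)
  pssm(prob)
}

# Dirichlet column perturbation; concentration 1/noise, with a 5% uniform
# floor so one-hot columns can actually move.
perturb_pssm <- function(m, noise) {
  if (noise <= 0) return(m)
  kappa <- 1 / noise
  eps <- 0.05
  prob <- t(apply(m$prob, 1, function(p) {
    alpha <- kappa * (p * (1 - eps) + eps / 4)
    g <- stats::rgamma(4, shape = alpha)
    g / sum(g)
  }))
  colnames(prob) <- DNA_BASES
  out <- m
  out$prob <- prob
  out
}

#' Generate the synthetic genome and planted ground truth
#'
#' Lays `n_genes` forward-strand genes on one circular replicon with
#' `promoter_length` spacing over a uniform i.i.d. background sequence,
#' plants one PSSM per module and writes an instance sampled from it at a
#' fixed strand-relative promoter offset in each member gene (with
#' probability `motif_emission_rate`), and assigns each module a contiguous
#' block of active conditions.
#'
#' @param config A [fixture_config()].
#' @return List with `genome` (a [genome_annotation()]) and `ground_truth`
#'   (planted modules, condition blocks, PSSMs, instances).
#' @export
generate_genome <- function(config) {
  with_seed(stage_seed(config$seed, "genome"), {
    n <- config$n_genes
    spacing <- config$promoter_length + config$gene_length
    L <- n * spacing
    seq_chars <- sample(DNA_BASES, L, replace = TRUE)
    gene_ids <- sprintf("g%03d", seq_len(n))
    starts <- (seq_len(n) - 1L) * spacing + config$promoter_length
    genes <- tibble(gene_id = gene_ids, replicon_id = "chr",
                    start = as.integer(starts),
                    end = as.integer(starts + config$gene_length),
                    strand = "+", operon_id = NA_character_)

    # module membership: chunks of a random permutation, optionally
    # overlapping between consecutive modules
    size_choices <- seq(config$module_size_range[1], config$module_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), config$n_modules, replace = TRUE)]
    ov <- round(config$module_gene_overlap_fraction * sizes)
    perm <- sample(gene_ids)
    modules <- vector("list", config$n_modules)
    cursor <- 0L
    for (m in seq_len(config$n_modules)) {
      fresh <- sizes[m] - if (m > 1) ov[m] else 0L
      if (cursor + fresh > n) stopf("modules do not fit into %d genes", n)
      mem <- perm[cursor + seq_len(fresh)]
      if (m > 1 && ov[m] > 0) mem <- c(tail(modules[[m - 1]], ov[m]), mem)
      modules[[m]] <- mem
      cursor <- cursor + fresh
    }

    # active condition blocks: placed without overlap when they fit
    cond_ids <- sprintf("c%03d", seq_len(config$n_conditions))
    blk <- config$condition_block_length
    nblk <- config$condition_blocks_per_module * config$n_modules
    blocks <- vector("list", config$n_modules)
    if (nblk * blk <= config$n_conditions) {
      slack <- config$n_conditions - nblk * blk
      gaps <- if (slack > 0) diff(c(0, sort(sample.int(slack + nblk, nblk)) - seq_len(nblk))) else rep(0L, nblk)
      pos <- 0L; k <- 0L
      for (m in seq_len(config$n_modules)) {
        conds <- integer()
        for (b in seq_len(config$condition_blocks_per_module)) {
          k <- k + 1L
          pos <- pos + gaps[k]
          conds <- c(conds, pos + seq_len(blk))
          pos <- pos + blk
        }
        blocks[[m]] <- cond_ids[conds]
      }
    } else {
      for (m in seq_len(config$n_modules)) {
        starts_b <- sample.int(config$n_conditions - blk + 1, config$condition_blocks_per_module)
        blocks[[m]] <- cond_ids[unique(unlist(lapply(starts_b, function(s) s + seq_len(blk) - 1L)))]
      }
    }

    # planted motifs are resampled until mutually dissimilar (alignment
    # distance >= 0.45) so the ground truth is identifiable: two planted
    # motifs closer than the ensemble's own motif variability could not be
    # told apart by any discovery method
    pssms <- list()
    for (m in seq_len(config$n_modules)) {
      for (try in 1:100) {
        cand <- sample_planted_pssm(config$planted_motif_width,
                                    config$planted_motif_information_content)
        ok <- config$planted_motif_width < 6 || length(pssms) == 0 ||
          all(vapply(pssms, function(p) pssm_distance(p, cand)$distance >= 0.45,
                     logical(1)))
        if (ok) break
      }
      pssms[[m]] <- cand
    }
    inst <- list()
    w <- config$planted_motif_width
    for (m in seq_len(config$n_modules)) {
      for (g in modules[[m]]) {
        if (stats::runif(1) > config$motif_emission_rate) next
        scp <- starts[match(g, gene_ids)]  # start codon = interval start (+ strand)
        at <- scp + PLANTED_OFFSET
        word <- strsplit(pssm_sample(pssms[[m]]), "")[[1]]
        seq_chars[at + seq_len(w)] <- word  # `at` is 0-based; R indexing adds 1
        inst[[length(inst) + 1]] <- tibble(module_id = m, gene_id = g,
                                           replicon_id = "chr",
                                           start = as.integer(at), end = as.integer(at + w),
                                           strand = "+")
      }
    }
    instances <- if (length(inst) > 0) bind_rows(inst) else
      tibble(module_id = integer(), gene_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character())

    replicons <- tibble(replicon_id = "chr", length = L, topology = "circular",
                        sequence = paste(seq_chars, collapse = ""))
    genome <- genome_annotation(replicons, genes)
    gt <- list(
      modules = tibble(module_id = seq_len(config$n_modules),
                       genes = modules, active_conditions = blocks),
      pssms = pssms,
      instances = instances,
      condition_ids = cond_ids)
    list(genome = genome, ground_truth = gt)
  })
}

#' Generate the synthetic expression matrix
#'
#' Background entries are i.i.d. Normal(0, `expression_noise_sd` + 1).
#' Within a module's active condition block, member genes share a
#' condition-specific mean (Normal(0,1), resampled until its magnitude is
#' at least 1) plus Normal(0, `expression_noise_sd`) gene noise, so the
#' module's relative standard deviation is low exactly in active blocks.
#'
#' @param config A [fixture_config()].
#' @param ground_truth From [generate_genome()].
#' @return Numeric matrix, genes x conditions.
#' @export
generate_expression <- function(config, ground_truth) {
  with_seed(stage_seed(config$seed, "expression"), {
    gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
    cond_ids <- ground_truth$condition_ids
    mat <- matrix(stats::rnorm(config$n_genes * config$n_conditions,
                               sd = config$expression_noise_sd + 1),
                  nrow = config$n_genes,
                  dimnames = list(gene_ids, cond_ids))
    for (m in seq_len(nrow(ground_truth$modules))) {
      genes <- ground_truth$modules$genes[[m]]
      for (cond in ground_truth$modules$active_conditions[[m]]) {
        mu <- 0
        while (abs(mu) < 1) mu <- stats::rnorm(1)
        mat[genes, cond] <- mu + stats::rnorm(length(genes), sd = config$expression_noise_sd)
      }
    }
    mat
  })
}

#' Generate the synthetic bicluster ensemble
#'
#' Each run samples `conditions_per_run_fraction` of the conditions. Every
#' module whose active block intersects the run's conditions yields a
#' bicluster: the module genes minus binomial dropout, plus spurious random
#' genes, with the planted PSSM perturbed by Dirichlet column noise as the
#' bicluster motif. Each true bicluster is paired with a decoy of random
#' genes carrying a column-shuffled planted motif, so that backbone
#' extraction has noise to remove.
#'
#' @param config A [fixture_config()].
#' @param ground_truth From [generate_genome()].
#' @param expression From [generate_expression()] (supplies condition ids).
#' @return An [ensemble()].
#' @export
generate_ensemble <- function(config, ground_truth, expression) {
  with_seed(stage_seed(config$seed, "ensemble"), {
    gene_ids <- rownames(expression)
    cond_ids <- colnames(expression)
    n_per_run <- max(1L, round(config$conditions_per_run_fraction * length(cond_ids)))
    rows <- list()
    for (r in seq_len(config$n_runs)) {
      run_id <- sprintf("r%03d", r)
      run_conds <- sample(cond_ids, n_per_run)
      idx <- 0L
      decoys <- list()
      for (m in seq_len(nrow(ground_truth$modules))) {
        overlap <- intersect(ground_truth$modules$active_conditions[[m]], run_conds)
        if (length(overlap) == 0) next
        members <- ground_truth$modules$genes[[m]]
        keep <- members[stats::runif(length(members)) >= config$gene_dropout_rate]
        if (length(keep) < 2) keep <- members[seq_len(2)]
        n_spur <- stats::rbinom(1, length(members), config$spurious_gene_rate)
        spur <- sample(setdiff(gene_ids, members), n_spur)
        idx <- idx + 1L
        rows[[length(rows) + 1]] <- tibble(
          bicluster_id = sprintf("%s_b%03d", run_id, idx), run_id = run_id,
          genes = list(c(keep, spur)), conditions = list(sort(overlap)),
          motifs = list(list(perturb_pssm(ground_truth$pssms[[m]], config$motif_noise))),
          residual = NA_real_)
        decoys[[length(decoys) + 1]] <- length(members)
      }
      for (d in seq_along(decoys)) {
        idx <- idx + 1L
        # decoy motif: a fresh random PSSM of the same width and information
        # content, column-shuffled -- spurious motifs in random gene sets are
        # independent of the planted signal
        decoy_motif <- pssm_shuffle(sample_planted_pssm(
          config$planted_motif_width,
          config$planted_motif_information_content))
        rows[[length(rows) + 1]] <- tibble(
          bicluster_id = sprintf("%s_b%03d", run_id, idx), run_id = run_id,
          genes = list(sample(gene_ids, decoys[[d]])),
          conditions = list(sort(sample(run_conds, min(length(run_conds), 10L)))),
          motifs = list(list(decoy_motif)),
          residual = NA_real_)
      }
    }
    ensemble(bind_rows(rows))
  })
}

#' Generate auxiliary fixture inputs
#'
#' One synthetic TF per planted motif (sites = the planted instance
#' intervals), the planted TF-to-gene gold standard, a fitness matrix with
#' correlated vectors inside modules, a condition annotation whose groups
#' include the planted active blocks, and an operon table of consecutive
#' gene runs (some spanning module boundaries).
#'
#' @param config A [fixture_config()].
#' @param ground_truth From [generate_genome()].
#' @return List with `tf_sites`, `gold_edges`, `fitness`,
#'   `condition_annotation`, `operons`.
#' @export
generate_auxiliary <- function(config, ground_truth) {
  with_seed(stage_seed(config$seed, "auxiliary"), {
    inst <- ground_truth$instances
    tf_ids <- sprintf("TF_m%d", seq_len(nrow(ground_truth$modules)))
    tf_sites <- if (nrow(inst) > 0) {
      tibble(tf_id = tf_ids[inst$module_id], replicon_id = inst$replicon_id,
             start = inst$start, end = inst$end, strand = inst$strand)
    } else {
      tibble(tf_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character())
    }
    gold_edges <- if (nrow(inst) > 0) {
      distinct(tibble(tf_id = tf_ids[inst$module_id], gene_id = inst$gene_id))
    } else {
      tibble(tf_id = character(), gene_id = character())
    }

    gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
    k <- config$fitness_conditions
    rho <- config$fitness_within_correlation
    fitness <- matrix(stats::rnorm(config$n_genes * k), nrow = config$n_genes,
                      dimnames = list(gene_ids, sprintf("f%03d", seq_len(k))))
    for (m in seq_len(nrow(ground_truth$modules))) {
      f_m <- stats::rnorm(k)
      for (g in ground_truth$modules$genes[[m]]) {
        fitness[g, ] <- sqrt(rho) * f_m + sqrt(1 - rho) * stats::rnorm(k)
      }
    }

    ann <- bind_rows(
      bind_rows(lapply(seq_len(nrow(ground_truth$modules)), function(m) {
        tibble(condition_id = ground_truth$modules$active_conditions[[m]],
               group = sprintf("block_m%d", m))
      })),
      bind_rows(lapply(seq_len(config$n_modules), function(j) {
        tibble(condition_id = sort(sample(ground_truth$condition_ids,
                                          config$condition_block_length)),
               group = sprintf("random_%d", j))
      })))

    # operons: consecutive runs of genes in genome order, with gaps
    ops <- list()
    i <- 1L; op <- 0L
    while (i <= config$n_genes) {
      len <- sample(1:4, 1)
      if (len >= 2 && i + len - 1 <= config$n_genes) {
        op <- op + 1L
        ops[[op]] <- tibble(operon_id = sprintf("op%03d", op),
                            gene_id = gene_ids[i + seq_len(len) - 1L])
      }
      i <- i + len + sample(0:2, 1)
    }
    operons <- if (length(ops) > 0) bind_rows(ops) else
      tibble(operon_id = character(), gene_id = character())

    list(tf_sites = tf_sites, gold_edges = gold_edges, fitness = fitness,
         condition_annotation = distinct(ann), operons = operons)
  })
}

#' Generate a complete synthetic fixture
#'
#' Runs [generate_genome()], [generate_expression()],
#' [generate_ensemble()] and [generate_auxiliary()] under one seed.
#'
#' @param config A [fixture_config()].
#' @return List with `config`, `genome`, `ground_truth`, `expression`,
#'   `ensemble`, `tf_sites`, `gold_edges`, `fitness`,
#'   `condition_annotation`, `operons`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  g <- generate_genome(config)
  expr <- generate_expression(config, g$ground_truth)
  ens <- generate_ensemble(config, g$ground_truth, expr)
  aux <- generate_auxiliary(config, g$ground_truth)
  c(list(config = config, genome = g$genome, ground_truth = g$ground_truth,
         expression = expr, ensemble = ens), aux)
}

#' Write a fixture to disk in the pipeline's external formats
#'
#' Emits FASTA + GFF3, the expression TSV, per-run ensemble JSON, TF-site
#' BED, gold-standard TSV, fitness TSV, condition-annotation TSV, operon
#' TSV, the configuration as `fixture.yaml`, and `ground_truth.json`.
#'
#' @param fixture From [generate_fixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_genome(fixture$genome, p("genome.fasta"), p("genome.gff3"))
  write_expression_tsv(fixture$expression, p("expression.tsv"))
  write_ensemble(fixture$ensemble, p("ensemble"))
  write_tf_sites(fixture$tf_sites, p("tf_sites.bed"))
  readr::write_tsv(fixture$gold_edges, p("gold_edges.tsv"))
  write_expression_tsv(fixture$fitness, p("fitness.tsv"))
  readr::write_tsv(fixture$condition_annotation, p("condition_annotation.tsv"))
  readr::write_tsv(fixture$operons, p("operons.tsv"))
  yaml::write_yaml(unclass(fixture$config), p("fixture.yaml"))
  gt <- fixture$ground_truth
  jsonlite::write_json(
    list(modules = lapply(seq_len(nrow(gt$modules)), function(m) {
           list(module_id = m, genes = gt$modules$genes[[m]],
                active_conditions = gt$modules$active_conditions[[m]])
         }),
         pssms = lapply(gt$pssms, function(x) unname(x$prob)),
         instances = gt$instances),
    p("ground_truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
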