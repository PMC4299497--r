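#' Run the full ensemble post-processing pipeline
#'
#' Executes, in order: input loading (or fixture generation), motif
#' clustering into GREs, genome scanning, promoter profiling, gene-gene
#' co-occurrence counting, backbone extraction, link-community corem
#' detection, per-corem condition activity, GRE association, GRE-TF
#' matching, and network/fitness evaluation. Stages with missing optional
#' inputs are skipped and logged. All outputs are plain-text files under
#' `config$out_dir`; the manifest records per-stage status and counts (but
#' no timings, so repeated runs with one seed are byte-identical).
#'
#' @param config A [default_config()] list (or YAML path accepted by
#'   [validate_config()]).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- do.call(default_config, yaml::read_yaml(config))
  report <- validate_config(unclass(config))
  if (!attr(report, "valid")) {
    stopf("invalid configuration: %s (%s)", report$field[report$severity == "error"][1],
          report$problem[report$severity == "error"][1])
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, status, counts = list()) {
    message(sprintf("[egrin2] %-12s %s %s", stage, status,
                    paste(sprintf("%s=%s", names(counts), unlist(counts)), collapse = " ")))
    manifest[[stage]] <<- list(status = status, counts = counts)
  }

  # -- load ------------------------------------------------------------
  aux <- list(tf_sites = NULL, gold_edges = NULL, fitness = NULL,
              condition_annotation = NULL, operons = NULL)
  if (!is.null(config$fixture)) {
    fcfg <- do.call(fixture_config, c(list(seed = config$seed), config$fixture))
    fx <- generate_fixture(fcfg)
    write_fixture(fx, file.path(out_dir, "fixture"))
    genome <- fx$genome; expression <- fx$expression; ens <- fx$ensemble
    aux <- fx[c("tf_sites", "gold_edges", "fitness", "condition_annotation", "operons")]
  } else {
    if (is.null(config$genome_fasta) || is.null(config$genome_gff) ||
        is.null(config$expression_tsv) || is.null(config$ensemble_dir)) {
      stopf("config needs either `fixture` or genome_fasta/genome_gff/expression_tsv/ensemble_dir")
    }
    genome <- read_genome(config$genome_fasta, config$genome_gff, config$topology)
    expression <- read_expression_tsv(config$expression_tsv)
    ens <- read_ensemble(config$ensemble_dir)
    if (!is.null(config$tf_sites_bed)) aux$tf_sites <- read_tf_sites(config$tf_sites_bed, config$min_tf_sites)
    if (!is.null(config$gold_edges_tsv)) aux$gold_edges <- readr::read_tsv(config$gold_edges_tsv, col_types = "cc")
    if (!is.null(config$fitness_tsv)) aux$fitness <- read_expression_tsv(config$fitness_tsv)
    if (!is.null(config$condition_annotation_tsv)) aux$condition_annotation <- read_condition_annotation(config$condition_annotation_tsv)
    if (!is.null(config$operons_tsv)) aux$operons <- readr::read_tsv(config$operons_tsv, col_types = "cc")
  }
  note("load", "completed", list(biclusters = nrow(ens$biclusters),
                                 genes = nrow(genome$genes),
                                 conditions = ncol(expression)))

  # -- motif clustering ------------------------------------------------
  motifs <- ensemble_motifs(ens)
  gres <- discover_gres(motifs, fdr = config$motif_fdr,
                        min_overlap = config$min_overlap, n_null = config$n_null,
                        inflation = config$inflation, min_size = config$min_gre_size,
                        seed = config$seed)
  write_meme(lapply(gres, `[[`, "combined"), file.path(out_dir, "gres.meme"),
             names = sprintf("GRE_%d", map_int(gres, "gre_id")))
  readr::write_tsv(tidy(gres), file.path(out_dir, "gre_members.tsv"))
  note("motifs", "completed", list(motifs = length(motifs), gres = length(gres)))

  # -- genome scan -----------------------------------------------------
  hits <- scan_genome(gres, genome, background = config$background,
                      qmax = config$scan_qmax, bin = config$scan_bin,
                      motifs = motifs)
  readr::write_tsv(hits, file.path(out_dir, "gre_hits.tsv"))
  write_hits_bed(hits, file.path(out_dir, "gre_hits.bed"))
  profile <- gre_scan_profile(hits, genome, upstream = config$window_upstream,
                              downstream = config$window_downstream)
  readr::write_tsv(profile, file.path(out_dir, "gre_profiles.tsv"))
  note("scan", "completed", list(hits = nrow(hits)))

  # -- network / backbone / corems ------------------------------------
  network <- count_cooccurrence(ens, normalize = config$normalize)
  readr::write_tsv(network, file.path(out_dir, "cooccurrence.tsv"))
  filtered <- disparity_filter(network, alpha = config$alpha)
  readr::write_tsv(filtered, file.path(out_dir, "backbone.tsv"))
  bb <- backbone(filtered)
  note("network", "completed", list(edges = nrow(network), backbone = nrow(bb)))

  lc <- link_communities(bb)
  corems <- extract_corems(lc, min_genes = config$min_corem_genes)
  corem_long <- tidyr::unnest(select(corems, "corem_id", "genes"), "genes")
  names(corem_long) <- c("corem_id", "gene_id")
  readr::write_tsv(corem_long, file.path(out_dir, "corems.tsv"))
  write_gmt(corems, file.path(out_dir, "corems.gmt"))
  note("corems", "completed", list(communities = nrow(lc$communities),
                                   corems = nrow(corems),
                                   partition_density = sprintf("%.4f", lc$D)))

  # -- corem condition activity ---------------------------------------
  activity <- bind_rows(lapply(seq_len(nrow(corems)), function(i) {
    a <- rsd_permutation_test(corems$genes[[i]], expression,
                              n_perm = config$n_perm,
                              seed = config$seed + corems$corem_id[i],
                              p_cut = config$p_cut)
    mutate(a, corem_id = corems$corem_id[i], .before = 1)
  }))
  readr::write_tsv(activity, file.path(out_dir, "corem_activity.tsv"))
  note("activity", "completed",
       list(coregulated = sum(activity$coregulated)))

  # -- GRE association -------------------------------------------------
  assoc <- bind_rows(lapply(seq_len(nrow(corems)), function(i) {
    a <- associate_gres_to_corem(corems$genes[[i]], gres, hits, motifs, ens,
                                 genome, top_fraction = config$top_fraction,
                                 upstream = config$window_upstream,
                                 downstream = config$window_downstream)
    mutate(a, corem_id = corems$corem_id[i], .before = 1)
  }))
  readr::write_tsv(assoc, file.path(out_dir, "corem_gre_associations.tsv"))
  note("gre_assoc", "completed", list(associations = sum(assoc$associated)))

  # -- condition enrichment / operons ---------------------------------
  if (!is.null(aux$condition_annotation) && nrow(corems) > 0) {
    enr <- bind_rows(lapply(seq_len(nrow(corems)), function(i) {
      co <- activity$condition_id[activity$corem_id == corems$corem_id[i] & activity$coregulated]
      e <- condition_enrichment(co, aux$condition_annotation, colnames(expression))
      mutate(e, corem_id = corems$corem_id[i], .before = 1)
    }))
    readr::write_tsv(enr, file.path(out_dir, "condition_enrichment.tsv"))
    note("enrichment", "completed", list(tests = nrow(enr)))
  } else {
    note("enrichment", "skipped: no condition_annotation")
  }
  if (!is.null(aux$operons)) {
    splits <- detect_operon_splits(aux$operons, corems)
    readr::write_tsv(select(splits, -"patterns"), file.path(out_dir, "operon_splits.tsv"))
    note("operons", "completed",
         list(flagged = sum(splits$status == "conditional isoforms predicted")))
  } else {
    note("operons", "skipped: no operons")
  }

  # -- TF matching / evaluation ---------------------------------------
  grn <- NULL; matches <- NULL
  if (!is.null(aux$tf_sites) && nrow(aux$tf_sites) > 0) {
    matches <- match_gre_to_tf(gres, hits, aux$tf_sites, genome,
                               bin_size = config$bin_size,
                               p_site = config$p_site, fdr = config$match_fdr)
    readr::write_tsv(matches, file.path(out_dir, "gre_tf_matches.tsv"))
    grn <- gre_based_grn(matches, hits, genome,
                         upstream = config$window_upstream,
                         downstream = config$window_downstream)
    readr::write_tsv(grn, file.path(out_dir, "grn.tsv"))
    note("tf_match", "completed", list(matches = sum(matches$retained),
                                       grn_edges = nrow(grn)))
  } else {
    note("tf_match", "skipped: no tf_sites")
  }
  pr <- NULL
  if (!is.null(grn) && !is.null(aux$gold_edges) && nrow(aux$gold_edges) > 0) {
    pr <- precision_recall_aupr(grn, aux$gold_edges, cutoffs = config$precision_cutoffs)
    readr::write_tsv(pr$curve, file.path(out_dir, "pr_curve.tsv"))
    jsonlite::write_json(list(aupr = pr$aupr, hits_at = as.list(pr$hits_at),
                              n_gold = pr$n_gold, n_predictions = pr$n_predictions),
                         file.path(out_dir, "pr_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("grn_eval", "completed", list(aupr = sprintf("%.4f", pr$aupr)))
  } else {
    note("grn_eval", if (is.null(grn)) "skipped: no grn" else "skipped: no gold_edges")
  }
  ksres <- NULL
  if (!is.null(aux$fitness)) {
    ksres <- fitness_coherence_ks(list(corems = corems$genes), aux$fitness,
                                  thresholds = config$fitness_thresholds)
    readr::write_tsv(ksres, file.path(out_dir, "fitness_ks.tsv"))
    note("fitness", "completed", list(D = sprintf("%.4f", ksres$D[1])))
  } else {
    note("fitness", "skipped: no fitness")
  }

  manifest_out <- list(
    package_version = as.character(utils::packageVersion("egrin2")),
    seed = config$seed,
    parameter_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    stages = manifest)
  jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, expression = expression, ensemble = ens,
                 motifs = motifs, gres = gres, hits = hits, profile = profile,
                 network = network, backbone = bb, link_communities = lc,
                 corems = corems, activity = activity, associations = assoc,
                 matches = matches, grn = grn, pr = pr, fitness_ks = ksres,
                 manifest = manifest_out))
}

# BED6: name = GRE id, score = -10*log10(q) capped at 1000.
write_hits_bed <- function(hits, path) {
  if (nrow(hits) == 0) { writeLines(character(), path); return(invisible(path)) }
  score <- pmin(round(-10 * log10(pmax(hits$q_value, 1e-100))), 1000)
  lines <- sprintf("%s\t%d\t%d\tGRE_%s\t%d\t%s",
                   hits$replicon_id, hits$position, hits$position + hits$width,
                   ifelse(is.na(hits$gre_id), "NA", hits$gre_id), score, hits$strand)
  writeLines(lines, path)
  invisible(path)
}

write_gmt <- function(corems, path) {
  lines <- vapply(seq_len(nrow(corems)), function(i) {
    paste(c(sprintf("corem_%03d", corems$corem_id[i]), "egrin2",
            corems$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
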