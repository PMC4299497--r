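#' Default pipeline configuration
#'
#' Returns the full set of tunables with the framework's reference
#' defaults: motif-pair FDR 0.01 with a 6 nt minimum alignment overlap, at
#' least 10 PSSMs per GRE, scan q <= 0.01, promoter window -875..+125 nt
#' around the start codon, disparity-filter alpha 0.05, corems of at least
#' 3 genes, RSD permutation p <= 0.05 with 1000 permutations, top 10% of
#' biclusters for GRE association, GRE-TF match FDR 0.05 with per-PSSM
#' overlap p <= 0.01, and TFs required to have at least 3 unique sites.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `egrin2_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # inputs (all optional when `fixture` is given)
    genome_fasta = NULL, genome_gff = NULL, topology = "circular",
    expression_tsv = NULL, ensemble_dir = NULL,
    tf_sites_bed = NULL, gold_edges_tsv = NULL, fitness_tsv = NULL,
    condition_annotation_tsv = NULL, operons_tsv = NULL,
    fixture = NULL,  # named list of fixture_config() overrides
    out_dir = "egrin2_out",
    # motif clustering / GRE discovery
    motif_fdr = 0.01, min_overlap = 6, min_gre_size = 10,
    inflation = 2.0, n_null = 1000,
    # genome scanning
    scan_qmax = 0.01, scan_bin = 1e-3, background = c(0.25, 0.25, 0.25, 0.25),
    # promoter window
    window_upstream = 875, window_downstream = 125,
    # co-occurrence network / backbone / corems
    normalize = "none", alpha = 0.05, min_corem_genes = 3,
    # corem condition analysis
    n_perm = 1000, p_cut = 0.05, top_fraction = 0.10,
    # GRE-TF matching
    bin_size = 50, p_site = 0.01, match_fdr = 0.05, min_tf_sites = 3,
    # evaluation
    precision_cutoffs = c(0.10, 0.25, 0.50),
    fitness_thresholds = c(0.75, 0.9))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) stopf("unknown configuration key: %s", unknown[1])
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "egrin2_config")
}

config_ranges <- function() {
  list(motif_fdr = c(0, 1), scan_qmax = c(0, 1), alpha = c(0, 1),
       p_cut = c(0, 1), top_fraction = c(0, 1), p_site = c(0, 1),
       match_fdr = c(0, 1), conditions_per_run_fraction = c(0, 1))
}

#' Validate a pipeline configuration
#'
#' Reports every missing input file, out-of-range threshold and unknown
#' key. Unknown keys are warnings (forward compatibility); the other two
#' are errors.
#'
#' @param config A list, an `egrin2_config`, or a path to a YAML file.
#' @return Tibble (`field`, `problem`, `severity`); attribute `valid` is
#'   TRUE iff no error-severity rows.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- default_config()
  rows <- list()
  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) {
    rows[[length(rows) + 1]] <- tibble(field = k, problem = "unknown key (ignored)",
                                       severity = "warning")
  }
  ranges <- config_ranges()
  for (k in intersect(names(ranges), names(config))) {
    v <- config[[k]]
    if (!is.numeric(v) || any(v < ranges[[k]][1]) || any(v > ranges[[k]][2])) {
      rows[[length(rows) + 1]] <- tibble(
        field = k,
        problem = sprintf("value %s outside [%g, %g]",
                          paste(format(v), collapse = ","), ranges[[k]][1], ranges[[k]][2]),
        severity = "error")
    }
  }
  file_keys <- c("genome_fasta", "genome_gff", "expression_tsv", "tf_sites_bed",
                 "gold_edges_tsv", "fitness_tsv", "condition_annotation_tsv",
                 "operons_tsv", "ensemble_dir")
  for (k in intersect(file_keys, names(config))) {
    v <- config[[k]]
    if (!is.null(v) && !file.exists(v)) {
      rows[[length(rows) + 1]] <- tibble(field = k,
                                         problem = sprintf("file not found: %s", v),
                                         severity = "error")
    }
  }
  out <- if (length(rows) == 0) {
    tibble(field = character(), problem = character(), severity = character())
  } else bind_rows(rows)
  attr(out, "valid") <- !any(out$severity == "error")
  out
}
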