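#' Bicluster ensemble container
#'
#' Holds the pooled biclusters from many independent biclustering runs,
#' each trained on a subsample of conditions: the raw material every
#' aggregation step mines.
#'
#' @param biclusters Tibble with columns `bicluster_id`, `run_id`, `genes`
#'   (list of character vectors), `conditions` (list of character vectors),
#'   `motifs` (list of lists of [pssm]), and optionally `residual`.
#' @return Object of class `ensemble`.
#' @export
ensemble <- function(biclusters) {
  biclusters <- as_tibble(biclusters)
  need <- c("bicluster_id", "run_id", "genes", "conditions", "motifs")
  if (!all(need %in% names(biclusters))) {
    stopf("biclusters needs columns %s", paste(need, collapse = ", "))
  }
  dup <- biclusters$bicluster_id[duplicated(biclusters$bicluster_id)]
  if (length(dup) > 0) stopf("duplicate bicluster_id in ensemble: %s", dup[1])
  if (any(lengths(biclusters$genes) == 0)) stopf("bicluster with empty gene set")
  structure(list(biclusters = biclusters,
                 runs = sort(unique(biclusters$run_id))),
            class = "ensemble")
}

#' @exportS3Method base::print
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d biclusters from %d run(s); %d motif(s)\n",
              nrow(x$biclusters), length(x$runs),
              sum(lengths(x$biclusters$motifs))))
  invisible(x)
}

#' All motifs of an ensemble
#'
#' @param ens An [ensemble()].
#' @return A flat list of [pssm] objects, each carrying its
#'   (run, bicluster, index) provenance.
#' @export
ensemble_motifs <- function(ens) {
  out <- list()
  for (i in seq_len(nrow(ens$biclusters))) {
    ms <- ens$biclusters$motifs[[i]]
    if (length(ms) == 0) next
    for (k in seq_along(ms)) {
      m <- ms[[k]]
      m$provenance <- list(run_id = ens$biclusters$run_id[i],
                           bicluster_id = ens$biclusters$bicluster_id[i],
                           motif_index = k)
      out[[length(out) + 1]] <- m
    }
  }
  out
}

#' Read a bicluster ensemble from a directory of per-run JSON files
#'
#' Each file holds one run:
#' `{"run_id": ..., "biclusters": [{"id": ..., "genes": [...],
#' "conditions": [...], "motifs": ["<MEME block>", ...]}]}`.
#' Biclusters with an empty gene set are skipped with a warning; an
#' unparsable motif block is a hard error naming the bicluster.
#'
#' @param dir_path Directory containing `*.json` run files.
#' @return An [ensemble()].
#' @export
read_ensemble <- function(dir_path) {
  files <- sort(list.files(dir_path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0) stopf("no run JSON files in %s", dir_path)
  rows <- list()
  for (f in files) {
    run <- jsonlite::read_json(f)
    run_id <- run$run_id %||% tools::file_path_sans_ext(basename(f))
    for (bc in run$biclusters) {
      genes <- unlist(bc$genes)
      if (length(genes) == 0) {
        warnf("skipping bicluster '%s' in run '%s': empty gene set", bc$id, run_id)
        next
      }
      motifs <- list()
      for (k in seq_along(bc$motifs)) {
        parsed <- tryCatch(read_meme(bc$motifs[[k]]),
                           error = function(e) stopf("unparsable motif block %d in bicluster '%s' (run '%s'): %s",
                                                     k, bc$id, run_id, conditionMessage(e)))
        for (m in parsed) motifs[[length(motifs) + 1]] <- m
      }
      rows[[length(rows) + 1]] <- tibble(
        bicluster_id = as.character(bc$id), run_id = as.character(run_id),
        genes = list(as.character(genes)),
        conditions = list(as.character(unlist(bc$conditions))),
        motifs = list(motifs),
        residual = if (length(bc$residual) == 1) as.numeric(bc$residual) else NA_real_)
    }
  }
  ensemble(bind_rows(rows))
}

#' Write an ensemble as per-run JSON files
#'
#' Inverse of [read_ensemble()].
#'
#' @param ens An [ensemble()].
#' @param dir_path Output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_ensemble <- function(ens, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (r in ens$runs) {
    bcs <- ens$biclusters[ens$biclusters$run_id == r, ]
    payload <- list(
      run_id = r,
      biclusters = lapply(seq_len(nrow(bcs)), function(i) {
        out <- list(id = bcs$bicluster_id[i],
                    genes = as.list(bcs$genes[[i]]),
                    conditions = as.list(bcs$conditions[[i]]),
                    motifs = lapply(bcs$motifs[[i]], function(m) write_meme(m)))
        if (!is.na(bcs$residual[i])) out$residual <- bcs$residual[i]
        out
      }))
    jsonlite::write_json(payload, file.path(dir_path, paste0(r, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = FALSE)
  }
  invisible(dir_path)
}

#' Validate an ensemble against a genome annotation and expression matrix
#'
#' Biclusters naming genes absent from the annotation are kept (they still
#' count for co-occurrence) but flagged here, since motif/promoter work
#' needs coordinates.
#'
#' @param ens An [ensemble()].
#' @param genome Optional [genome_annotation()].
#' @param expression Optional expression matrix.
#' @return Tibble report (bicluster_id, issue, detail); zero rows when clean.
#' @export
validate_ensemble <- function(ens, genome = NULL, expression = NULL) {
  rows <- list()
  for (i in seq_len(nrow(ens$biclusters))) {
    id <- ens$biclusters$bicluster_id[i]
    if (!is.null(genome)) {
      missing <- setdiff(ens$biclusters$genes[[i]], genome$genes$gene_id)
      if (length(missing) > 0) {
        rows[[length(rows) + 1]] <- tibble(bicluster_id = id, issue = "unknown_gene",
                                           detail = paste(missing, collapse = ","))
      }
    }
    if (!is.null(expression)) {
      missing <- setdiff(ens$biclusters$conditions[[i]], colnames(expression))
      if (length(missing) > 0) {
        rows[[length(rows) + 1]] <- tibble(bicluster_id = id, issue = "unknown_condition",
                                           detail = paste(missing, collapse = ","))
      }
    }
  }
  if (length(rows) == 0) {
    tibble(bicluster_id = character(), issue = character(), detail = character())
  } else {
    bind_rows(rows)
  }
}
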