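#' Read transcription-factor binding sites from BED
#'
#' Expects BED (0-based, half-open) whose 4th column names the TF; an
#' optional 6th column carries strand. Exact duplicate intervals per TF are
#' collapsed, and TFs with fewer than `min_sites` unique sites are dropped
#' (with a message), mirroring the convention of keeping only TFs with at
#' least three experimentally mapped, unique binding sites.
#'
#' @param bed_path Path to a BED4/BED6 file.
#' @param min_sites Minimum number of unique sites per TF (default 3).
#' @return Tibble with columns `tf_id`, `replicon_id`, `start`, `end`,
#'   `strand`.
#' @export
read_tf_sites <- function(bed_path, min_sites = 3) {
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(tf_id = character(), replicon_id = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (length(p) < 4 || is.na(start) || is.na(end) || end <= start) {
      stopf("malformed BED line %d: '%s'", i, lines[i])
    }
  }
  sites <- tibble(
    replicon_id = map_chr(parts, 1),
    start = map_int(parts, ~ as.integer(.x[2])),
    end = map_int(parts, ~ as.integer(.x[3])),
    tf_id = map_chr(parts, 4),
    strand = map_chr(parts, ~ if (length(.x) >= 6) .x[6] else NA_character_))
  sites <- distinct(sites, .data$tf_id, .data$replicon_id, .data$start, .data$end,
                    .keep_all = TRUE)
  counts <- count(sites, .data$tf_id)
  drop <- counts$tf_id[counts$n < min_sites]
  if (length(drop) > 0) {
    message(sprintf("dropping %d TF(s) with < %d unique sites: %s",
                    length(drop), min_sites, paste(drop, collapse = ", ")))
  }
  sites <- filter(sites, .data$tf_id %not_in% drop)
  select(sites, "tf_id", "replicon_id", "start", "end", "strand")
}

#' Write TF binding sites as BED
#'
#' @param sites Tibble as returned by [read_tf_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_sites <- function(sites, path) {
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    base <- paste(sites$replicon_id[i], sites$start[i], sites$end[i],
                  sites$tf_id[i], sep = "\t")
    if (!is.na(sites$strand[i])) paste(base, "0", sites$strand[i], sep = "\t") else base
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a condition-annotation table
#'
#' Two-column TSV `condition_id<TAB>group`; a condition may appear on
#' several rows (hierarchical labels flattened to ancestor-closed sets).
#'
#' @param path TSV path.
#' @return Tibble (`condition_id`, `group`).
#' @export
read_condition_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  names(df)[1:2] <- c("condition_id", "group")
  distinct(as_tibble(df))
}
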