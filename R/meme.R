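#' Write motifs in MEME minimal format
#'
#' Serialises a list of [pssm] objects as a "MEME version 4" minimal motif
#' text block (alphabet ACGT, letter-probability matrices).
#'
#' @param pssms A list of [pssm] objects, or a single [pssm].
#' @param path Output file path; if `NULL` the text is returned invisibly as
#'   a character scalar.
#' @param names Motif names; defaults to `motif_1`, `motif_2`, ...
#' @param background Background letter frequencies recorded in the header.
#' @return The MEME text, invisibly.
#' @export
write_meme <- function(pssms, path = NULL, names = NULL,
                       background = rep(0.25, 4)) {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  if (is.null(names)) names <- sprintf("motif_%d", seq_along(pssms))
  head_txt <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES, background), collapse = " "),
    "")
  body <- unlist(map2(pssms, names, function(m, nm) {
    c(sprintf("MOTIF %s", nm),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              pssm_width(m)),
      apply(m$prob, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      "")
  }))
  txt <- paste(c(head_txt, body), collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Parse motifs from MEME minimal format
#'
#' Reads "MEME version 4" minimal motif text (a file path or a character
#' scalar/vector of lines) into a list of [pssm] objects. Rows of each
#' letter-probability matrix are renormalised to machine precision so that
#' round-trips through fixed-precision text stay valid.
#'
#' @param x A file path, or the MEME text itself.
#' @param pseudocount Pseudocount stored on the parsed motifs.
#' @return Named list of [pssm] objects.
#' @export
read_meme <- function(x, pseudocount = 0.001) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  if (!any(grepl("^MEME version", lines))) stopf("not MEME minimal format: missing 'MEME version' header")
  motif_at <- grep("^MOTIF\\b", lines)
  out <- list()
  for (i in motif_at) {
    name <- sub("^MOTIF\\s+", "", lines[i])
    name <- strsplit(trimws(name), "\\s+")[[1]][1]
    j <- i + 1
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) stopf("motif '%s': no letter-probability matrix", name)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
    if (is.na(w)) stopf("motif '%s': cannot parse matrix width", name)
    rows <- lines[j + seq_len(w)]
    vals <- suppressWarnings(lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    if (any(vapply(vals, function(v) length(v) != 4 || anyNA(v), logical(1)))) {
      stopf("motif '%s': malformed probability row", name)
    }
    prob <- do.call(rbind, vals)
    prob <- prob / rowSums(prob)
    out[[name]] <- pssm(prob, pseudocount = pseudocount)
  }
  out
}
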