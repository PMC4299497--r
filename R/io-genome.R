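#' Genome annotation container
#'
#' Internal coordinates are 0-based, half-open, on the forward strand;
#' GFF3 I/O converts from/to 1-based inclusive. `start_codon_pos` is the
#' forward-strand coordinate of the first base of the start codon: the
#' interval start for `+` genes and the interval end minus one for `-`
#' genes.
#'
#' @param replicons Tibble with columns `replicon_id`, `length`, `topology`
#'   (`"circular"` or `"linear"`), `sequence` (character over ACGTN).
#' @param genes Tibble with columns `gene_id`, `replicon_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`) and optionally
#'   `operon_id`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(replicons, genes) {
  replicons <- as_tibble(replicons)
  genes <- as_tibble(genes)
  if (!all(c("replicon_id", "length", "topology", "sequence") %in% names(replicons))) {
    stopf("replicons needs columns replicon_id, length, topology, sequence")
  }
  if (any(nchar(replicons$sequence) != replicons$length)) {
    stopf("replicon sequence length disagrees with declared length")
  }
  if (!all(replicons$topology %in% c("circular", "linear"))) {
    stopf("topology must be 'circular' or 'linear'")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) stopf("duplicate gene_id: %s", dup[1])
  if (!"operon_id" %in% names(genes)) genes$operon_id <- NA_character_
  unknown <- setdiff(genes$replicon_id, replicons$replicon_id)
  if (length(unknown) > 0) stopf("gene references unknown replicon: %s", unknown[1])
  rl <- setNames(replicons$length, replicons$replicon_id)
  if (any(genes$start < 0 | genes$end > rl[genes$replicon_id] | genes$end <= genes$start)) {
    bad <- which(genes$start < 0 | genes$end > rl[genes$replicon_id] | genes$end <= genes$start)[1]
    stopf("gene '%s' has coordinates outside its replicon", genes$gene_id[bad])
  }
  genes$start_codon_pos <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  structure(list(replicons = replicons, genes = genes),
            class = "genome_annotation")
}

#' @exportS3Method base::print
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d replicon(s), %d gene(s)\n",
              nrow(x$replicons), nrow(x$genes)))
  invisible(x)
}

#' Read a genome from FASTA and GFF3
#'
#' Gene features (GFF3 type `gene`) are converted from 1-based inclusive to
#' the package's 0-based half-open forward-strand convention.
#'
#' @param fasta_path FASTA file of replicon sequences.
#' @param gff_path GFF3 annotation; seqids must match the FASTA ids.
#' @param topology_map Named character vector mapping replicon id to
#'   `"circular"` or `"linear"`; unnamed scalar applies to all replicons
#'   (default `"circular"`).
#' @return A [genome_annotation()].
#' @export
read_genome <- function(fasta_path, gff_path, topology_map = "circular") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  topo <- if (is.null(names(topology_map)) && length(topology_map) == 1) {
    setNames(rep(topology_map, length(seqs)), names(seqs))
  } else {
    setNames(as.character(topology_map), names(topology_map))
  }
  replicons <- tibble(
    replicon_id = names(seqs),
    length = Biostrings::width(seqs),
    topology = unname(ifelse(is.na(topo[names(seqs)]), "circular", topo[names(seqs)])),
    sequence = as.character(seqs))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[gff$type == "gene"]
  meta <- as.data.frame(gff)
  gene_id <- if ("ID" %in% names(meta)) meta$ID else meta$Name
  genes <- tibble(
    gene_id = as.character(gene_id),
    replicon_id = as.character(meta$seqnames),
    start = as.integer(meta$start) - 1L,
    end = as.integer(meta$end),
    strand = as.character(meta$strand),
    operon_id = if ("operon_id" %in% names(meta)) as.character(meta$operon_id) else NA_character_)
  genome_annotation(replicons, genes)
}

#' Write a genome to FASTA and GFF3
#'
#' Inverse of [read_genome()].
#'
#' @param genome A [genome_annotation()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, `genome`.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(setNames(genome$replicons$sequence,
                                            genome$replicons$replicon_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$replicon_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$type <- "gene"
  gr$source <- "egrin2"
  gr$ID <- g$gene_id
  gr$operon_id <- g$operon_id
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(genome)
}

replicon_row <- function(genome, replicon_id) {
  i <- match(replicon_id, genome$replicons$replicon_id)
  if (is.na(i)) stopf("unknown replicon: %s", replicon_id)
  genome$replicons[i, ]
}

#' Promoter window around a gene's start codon
#'
#' Returns the strand-oriented window covering `upstream` nt upstream
#' through `downstream` nt downstream of the start codon, reported as
#' forward-strand, 0-based, half-open interval(s). The window is clipped on
#' linear replicons and wraps (splitting into two intervals) on circular
#' ones.
#'
#' @param gene A gene id, or a one-row slice of `genome$genes`.
#' @param genome A [genome_annotation()].
#' @param upstream,downstream Window extent in nt along the gene's strand
#'   (defaults 875 and 125, a 1,000 nt window).
#' @return Tibble with columns `replicon_id`, `start`, `end`.
#' @examples
#' \dontrun{
#' promoter_window("g001", genome)
#' }
#' @export
promoter_window <- function(gene, genome, upstream = 875, downstream = 125) {
  if (is.character(gene)) {
    i <- match(gene, genome$genes$gene_id)
    if (is.na(i)) stopf("gene '%s' not in genome", gene)
    gene <- genome$genes[i, ]
  }
  rep_row <- replicon_row(genome, gene$replicon_id)
  L <- rep_row$length
  s <- gene$start_codon_pos
  if (gene$strand == "+") {
    lo <- s - upstream; hi <- s + downstream
  } else {
    lo <- s - downstream + 1L; hi <- s + upstream + 1L
  }
  if (rep_row$topology == "linear") {
    lo <- max(lo, 0L); hi <- min(hi, L)
    if (hi <= lo) return(tibble(replicon_id = character(), start = integer(), end = integer()))
    return(tibble(replicon_id = gene$replicon_id, start = as.integer(lo), end = as.integer(hi)))
  }
  # circular: wrap around the origin, at most one split
  if (hi - lo >= L) { lo <- 0L; hi <- L }
  lo_m <- ((lo %% L) + L) %% L
  hi_m <- ((hi - 1L) %% L) + 1L  # position of last covered base, +1
  if (lo_m < hi_m && (hi - lo) == (hi_m - lo_m)) {
    tibble(replicon_id = gene$replicon_id, start = as.integer(lo_m), end = as.integer(hi_m))
  } else {
    tibble(replicon_id = gene$replicon_id,
           start = as.integer(c(lo_m, 0L)),
           end = as.integer(c(L, hi_m)))
  }
}

# Positions (0-based, forward strand) covered by a gene's promoter window,
# as an integer vector; used by profile and association operations.
promoter_positions <- function(gene, genome, upstream = 875, downstream = 125) {
  win <- promoter_window(gene, genome, upstream, downstream)
  if (nrow(win) == 0) return(integer())
  unlist(lapply(seq_len(nrow(win)), function(i) seq(win$start[i], win$end[i] - 1L)))
}
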