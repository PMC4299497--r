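#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows rename n row_number
#'   desc across pull slice count
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2 pmap imap keep
#' @importFrom stats p.adjust phyper pbinom sd cor ks.test rnorm runif
#'   rmultinom hclust cutree as.dist setNames
#' @importFrom utils head tail combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%not_in%` <- function(x, table) !(x %in% table)

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)

#' Seeded evaluation
#'
#' All stochastic stages route their RNG through this wrapper so that a
#' single integer seed makes every artifact reproducible.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seed for a named pipeline stage, kept below 2^31.
stage_seed <- function(seed, stage) {
  offs <- c(genome = 11L, expression = 23L, ensemble = 37L, auxiliary = 53L,
            motif_null = 71L, activity = 89L, decoys = 101L)
  o <- offs[[stage]] %||% 127L
  (as.integer(seed) + o) %% .Machine$integer.max
}
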