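#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a GRE set into one row per member motif
#'
#' @param x A `gre_set` ([build_gres()]).
#' @param ... Unused.
#' @return Tibble (`gre_id`, `member`, `motif`, `offset`, `orientation`,
#'   `is_medoid`).
#' @export
tidy.gre_set <- function(x, ...) {
  bind_rows(lapply(x, function(g) {
    tibble(gre_id = g$gre_id, member = seq_along(g$members),
           motif = g$members, offset = g$offsets, orientation = g$orientations,
           is_medoid = g$members == g$medoid)
  }))
}

#' One-row summary of a GRE set
#' @param x A `gre_set`.
#' @param ... Unused.
#' @return Tibble (`n_gres`, `n_member_motifs`, `median_size`,
#'   `median_width`).
#' @export
glance.gre_set <- function(x, ...) {
  sizes <- map_int(x, ~ length(.x$members))
  tibble(n_gres = length(x),
         n_member_motifs = sum(sizes),
         median_size = if (length(x)) stats::median(sizes) else NA_real_,
         median_width = if (length(x)) stats::median(map_int(x, ~ pssm_width(.x$combined))) else NA_real_)
}

#' Tidy link communities into one row per link
#' @param x A [link_communities()] result.
#' @param ... Unused.
#' @return The edge tibble with its `community` column.
#' @export
tidy.link_communities <- function(x, ...) as_tibble(x$edges)

#' One-row summary of a link-community clustering
#' @param x A [link_communities()] result.
#' @param ... Unused.
#' @return Tibble (`n_links`, `n_communities`, `partition_density`,
#'   `cut_height`).
#' @export
glance.link_communities <- function(x, ...) {
  tibble(n_links = nrow(x$edges),
         n_communities = length(unique(x$edges$community)),
         partition_density = x$D, cut_height = x$cut_height)
}

#' Tidy a precision-recall evaluation into its curve
#' @param x A [precision_recall_aupr()] result.
#' @param ... Unused.
#' @export
tidy.pr_eval <- function(x, ...) x$curve

#' One-row summary of a precision-recall evaluation
#' @param x A [precision_recall_aupr()] result.
#' @param ... Unused.
#' @return Tibble with `aupr`, `n_predictions`, `n_gold` and one
#'   `hits_at_<cutoff>` column per cutoff.
#' @export
glance.pr_eval <- function(x, ...) {
  out <- tibble(aupr = x$aupr, n_predictions = x$n_predictions, n_gold = x$n_gold)
  for (nm in names(x$hits_at)) out[[paste0("hits_at_", nm)]] <- x$hits_at[[nm]]
  out
}
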