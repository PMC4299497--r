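#' Plot a promoter-aligned GRE match profile
#'
#' Start-codon-relative match counts per GRE, one panel per GRE.
#'
#' @param profile Tibble from [gre_scan_profile()].
#' @return A ggplot object.
#' @export
plot_promoter_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue4") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~gre_id, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position relative to start codon (nt)",
                  y = "significant matches") +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param x A [precision_recall_aupr()] result.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(x) {
  ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", colour = "firebrick") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  title = sprintf("AUPR = %.3f", x$aupr)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_pr_curve
#' @param object A `pr_eval` object.
#' @param ... Unused.
#' @export
autoplot.pr_eval <- function(object, ...) plot_pr_curve(object)

#' Plot a corem's condition activity profile
#'
#' RSD and permutation p-value per condition, with the co-regulated set
#' highlighted.
#'
#' @param activity Tibble from [rsd_permutation_test()].
#' @return A ggplot object.
#' @export
plot_corem_activity <- function(activity) {
  df <- mutate(activity, index = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = -log10(.data$p_value),
                                   fill = .data$coregulated)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70")) +
    ggplot2::labs(x = "condition (matrix order)", y = "-log10 permutation p") +
    ggplot2::theme_minimal()
}
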