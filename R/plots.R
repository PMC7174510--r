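#' Plot a per-residue Z-score profile
#'
#' Displacement Z-score against residue number, with an optional set of site
#' residues highlighted in red (e.g. the ligand-contacting residues) and a
#' dashed line at z = 0: points below it are the relatively rigid residues.
#'
#' @param object A `zscore_profile`.
#' @param site Optional integer vector of residue numbers to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zscore_profile <- function(object, site = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$site <- df$res_number %in% (site %||% integer(0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_number, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$site), size = 1.8,
                        show.legend = any(df$site)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25",
                                            `TRUE` = "red"),
                                 labels = c("other", "site"),
                                 name = NULL) +
    ggplot2::labs(
      x = "residue number",
      y = "displacement Z-score",
      title = paste("Per-residue mobility,",
                    attr(object, "conformer_a") %||% "a", "vs",
                    attr(object, "conformer_b") %||% "b")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the pooled affinity distribution of an ensemble docking run
#'
#' Relative frequency (percent) of the per-run best scores.
#'
#' @param object An `affinity_table`.
#' @param bin_width Bin width in kcal/mol (default 0.25).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.affinity_table <- function(object, bin_width = 0.25, ...) {
  h <- affinity_histogram(object, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$rel_freq_pct)) +
    ggplot2::geom_col(width = bin_width * 0.92, fill = "steelblue") +
    ggplot2::labs(
      x = "binding affinity (kcal/mol)",
      y = "relative frequency (%)",
      subtitle = sprintf("mean %.2f +/- %.3f kcal/mol (n = %d)",
                         object$pooled$mean, object$pooled$sd,
                         object$pooled$n)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise RMSD matrix
#'
#' @param object An `rmsd_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rmsd_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- expand.grid(conformer_a = ids, conformer_b = ids,
                    stringsAsFactors = FALSE)
  df$rmsd <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conformer_a,
                                   y = .data$conformer_b,
                                   fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "RMSD (A)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
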