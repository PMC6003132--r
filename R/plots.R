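#' Whole-genome copy-number profile plot
#'
#' Relative copy number per bin against cumulative genome position, with
#' chromosome boundaries drawn and the diploid line at 2 — the usual way to
#' eyeball CNV profiles of individual samples.
#'
#' @param object `cia_copy_number` tibble.
#' @param point_size dot size.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot cia_copy_number
#' @export
autoplot.cia_copy_number <- function(object, point_size = 0.4, ...) {
  df <- genome_position(as_tibble(object))
  offsets <- attr(df, "chrom_offsets")
  ggplot2::ggplot(df[df$usable, ], ggplot2::aes(x = .data$genome_pos, y = .data$xi)) +
    ggplot2::geom_vline(xintercept = offsets[-1], colour = "grey85", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 2, colour = "grey40", linetype = 2) +
    ggplot2::geom_point(size = point_size, colour = "steelblue4") +
    ggplot2::scale_x_continuous(
      breaks = offsets + diff(c(offsets, max(df$genome_pos))) / 2,
      labels = strip_chr(names(offsets))
    ) +
    ggplot2::labs(
      x = NULL, y = "relative copy number (xi)",
      title = paste0("CNV profile: ", attr(object, "sample_id"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(size = 6))
}

#' ROC curve plot
#'
#' @param object `cia_eval` from [roc_and_cutoff()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot cia_eval
#' @export
autoplot.cia_eval <- function(object, ...) {
  at_cut <- object$metrics
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70", linetype = 2) +
    ggplot2::geom_step(colour = "steelblue4") +
    ggplot2::annotate("point",
      x = 1 - at_cut$specificity, y = at_cut$sensitivity,
      colour = "firebrick", size = 2
    ) +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC (AUC = %.3f, cutoff = %g)", object$auc, object$cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Cohort score strip plot
#'
#' CIA scores by group with the decision cutoff drawn, mirroring how cohort
#' score distributions are usually displayed.
#'
#' @param scores data frame with `score` and `label` columns.
#' @param cutoff horizontal decision line. Default 24.
#' @return a ggplot object.
#' @export
plot_scores <- function(scores, cutoff = 24) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$label, y = .data$score)) +
    ggplot2::geom_hline(yintercept = cutoff, colour = "firebrick", linetype = 2) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1, colour = "steelblue4") +
    ggplot2::labs(x = NULL, y = "CIA score") +
    ggplot2::theme_minimal()
}
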