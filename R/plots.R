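#' Barcode-rank knee plot
#'
#' Log-log barcode-rank curve with the knee threshold and retained
#' fraction annotated, the standard diagnostic for droplet cell calling.
#'
#' @param object A `knee_result` from [adaptive_cell_call()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knee_result <- function(object, ...) {
  curve <- object$curve
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$rank, y = .data$n)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "barcode rank", y = "contacts",
      title = sprintf("%d cells called (S = %s, %.1f%% contacts retained)",
                      object$n_called, object$sensitivity,
                      100 * object$retained_fraction)
    )
  if (!is.na(object$knee_rank)) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$knee_rank, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = object$threshold_count, linetype = "dotted")
  }
  p
}

#' Distance-decay plot
#'
#' Contact frequency versus genomic distance on log-log axes.
#'
#' @param object A `ps_curve` tibble from [ps_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_curve <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$freq), ],
                  ggplot2::aes(x = .data$s, y = .data$freq)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance s (bp)", y = "contact frequency P(s)")
}

#' Insulation-score track plot
#'
#' Normalized insulation score along the genome, one panel per
#' chromosome; dips mark TAD boundaries.
#'
#' @param object An `insulation_track` from [insulation()].
#' @param boundaries Optional boundary tibble from [call_boundaries()]
#'   drawn as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.insulation_track <- function(object, boundaries = NULL, ...) {
  df <- object[!is.na(object$score), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "insulation score (log2)")
  if (!is.null(boundaries) && nrow(boundaries) > 0) {
    p <- p + ggplot2::geom_point(data = boundaries, color = "red", size = 1)
  }
  p
}

#' Volcano-style plot of differential compartment bins
#'
#' @param object A `diff_table` from [diff_compartment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_diff_compartment <- function(object, ...) {
  df <- object[object$tested, ]
  df$status <- ifelse(!is.na(df$direction), df$direction,
                      ifelse(df$retained, "retained", "ns"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, y = -log10(.data$p_adj),
                                   color = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "delta scA/B (median A - median B)",
                  y = "-log10 adjusted p", color = NULL)
}
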