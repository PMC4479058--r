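#' Plot a CE-vs-length trend with outliers annotated
#'
#' Scatter of CE against remaining exon length on a log scale with 95% CI
#' error bars, the fitted reference curve, and high/low outliers labelled in
#' `(x,y)` deletion notation.
#'
#' @param object A `ce_trend` from [length_trend()].
#' @param curve Reference curve, see [fitted_ce()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_trend <- function(object, curve = c("smooth", "linear"), ...) {
  curve <- match.arg(curve)
  data <- object$data
  has_ci <- all(c("ci_low", "ci_high") %in% names(data))
  if (has_ci) {
    data <- flag_outliers(data, object, curve = curve)
  }
  grid <- tibble(
    remaining_length = seq(min(data$remaining_length),
                           max(data$remaining_length), length.out = 200)
  )
  grid$ce <- fitted_ce(object, grid$remaining_length, curve = curve)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$remaining_length, y = .data$ce)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "remaining exon length (nt)",
      y = "circularization efficiency (CE)",
      subtitle = sprintf("Spearman rho = %.2f (p = %.2g)",
                         object$spearman$rho, object$spearman$p_value)
    ) +
    ggplot2::theme_bw()
  if (has_ci) {
    p <- p +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
        width = 0, colour = "grey60"
      ) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
      ggplot2::scale_colour_manual(
        values = c(high = "firebrick", low = "steelblue", none = "black"),
        name = "outlier"
      )
    out <- data[data$outlier != "none", , drop = FALSE]
    if (nrow(out) > 0 && all(c("del_start", "del_end") %in% names(out))) {
      out$label <- isoform_label(out$del_start, out$del_end)
      p <- p + ggplot2::geom_text(
        data = out, ggplot2::aes(label = .data$label),
        vjust = -0.8, size = 3
      )
    }
  } else {
    p <- p + ggplot2::geom_point()
  }
  p
}

#' Plot the positional deletion profile
#'
#' Horizontal bars, one per deletion, spanning the deleted interval and
#' coloured by CE (log scale) -- the per-deletion view of position effects.
#'
#' @param data CE records with `del_start`, `del_end`, `ce`.
#' @param exon_length Optional exon length to fix the x-axis.
#' @return A ggplot object.
#' @export
plot_deletion_spans <- function(data, exon_length = NULL) {
  stopifnot(all(c("del_start", "del_end", "ce") %in% names(data)))
  data <- data |>
    as_tibble() |>
    dplyr::arrange(.data$ce) |>
    dplyr::mutate(rank = dplyr::row_number())
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$del_start, xend = .data$del_end,
    y = .data$rank, yend = .data$rank, colour = .data$ce
  )) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::scale_colour_viridis_c(trans = "log10", name = "CE") +
    ggplot2::labs(x = "exon position (nt)", y = "deletion (ranked by CE)") +
    ggplot2::theme_bw()
  if (!is.null(exon_length)) {
    p <- p + ggplot2::xlim(1, exon_length)
  }
  p
}

#' Notched box plots of exon-length cohorts
#'
#' Box plots of length distributions with notches `median +/- 1.57 IQR /
#' sqrt(n)` drawn from [notch_stats()] (approximate 95% CI of the median).
#'
#' @param data Data frame with `length` and `cohort` columns.
#' @return A ggplot object.
#' @export
plot_length_cohorts <- function(data) {
  stats <- cohort_stats(data)$cohorts
  ggplot2::ggplot(data, ggplot2::aes(x = .data$cohort, y = .data$length)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::geom_crossbar(
      data = stats,
      ggplot2::aes(x = .data$cohort, y = .data$median,
                   ymin = .data$notch_low, ymax = .data$notch_high),
      inherit.aes = FALSE, width = 0.6, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "exon length (nt)") +
    ggplot2::theme_bw()
}

#' Bar plot of observed vs predicted second-step fold changes
#'
#' The circle:lariat analysis: observed log2 relative circle:lariat ratios
#' per mutant with error bars, coloured by the kinetic-model prediction
#' (unchanged second step: 0; impaired second step: below 0).
#'
#' @param data Data frame with `mutant`, `log2_fold_change`, `sd` and
#'   optionally `predicted` (`"zero"`/`"negative"`).
#' @return A ggplot object.
#' @export
plot_k2_fold_changes <- function(data) {
  stopifnot(all(c("mutant", "log2_fold_change", "sd") %in% names(data)))
  aes_fill <- if ("predicted" %in% names(data)) {
    ggplot2::aes(fill = .data$predicted)
  } else {
    NULL
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$mutant,
                                          y = .data$log2_fold_change))
  p <- if (is.null(aes_fill)) {
    p + ggplot2::geom_col()
  } else {
    p + ggplot2::geom_col(aes_fill) +
      ggplot2::scale_fill_manual(
        values = c(zero = "forestgreen", negative = "firebrick"),
        name = "predicted"
      )
  }
  p +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$log2_fold_change - .data$sd,
                   ymax = .data$log2_fold_change + .data$sd),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "log2 relative circle:lariat ratio") +
    ggplot2::theme_bw()
}
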