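#' Spaghetti plot of t0-normalized traces
#'
#' One line per cell, faceted by channel, the standard way temporal calcium
#' dynamics cohorts are displayed.
#'
#' @param traces An `eec_traces` (normalized on the fly if needed).
#' @param channels Normalized columns to show.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces,
                        channels = c("cyto_norm", "mito_norm", "ratio_norm")) {
  traces <- .ensure_norm(traces)
  fi <- attr(traces, "frame_interval") %||% 1
  long <- tidyr::pivot_longer(traces[, c("cell", "frame", channels)],
                              dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame * fi, y = .data$value,
                                     group = .data$cell)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "normalized intensity (t0 = 1)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eec_quadrant <- function(object, ...) {
  d <- object$counts
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cv_direction, y = .data$n,
                                  fill = .data$eec_direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "CV-vs-GF direction (significant genes)", y = "genes",
                  fill = "EEC axis") +
    ggplot2::theme_minimal()
}

#' Quadrant scatter of the dual-contrast fold changes
#'
#' @param table An `eec_gene_table`.
#' @param alpha Significance level colouring the CV contrast.
#' @return A ggplot object.
#' @export
plot_quadrant <- function(table, alpha = 0.05) {
  d <- tibble::as_tibble(table)
  d$significant <- !is.na(d$padj_cv) & d$padj_cv < alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc_cv, y = .data$log2fc_eec,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 FC (CV vs GF, EEC)", y = "log2 FC (EEC vs IEC)",
                  colour = sprintf("padj < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Base-to-apex profile plot
#'
#' @param profiles Long profile tibble (`cell`, `bin`, `value`) from
#'   [profile_cells()], or a single `mito_profile`.
#' @return A ggplot object.
#' @export
plot_mito_profile <- function(profiles) {
  if (inherits(profiles, "mito_profile")) profiles <- tidy(profiles)
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$bin, y = .data$value,
                                         group = .data$cell)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "bin (1 = base, last = apex)",
                  y = "normalized mitochondrial intensity") +
    ggplot2::theme_minimal()
}
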