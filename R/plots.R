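#' Plot REV distributions per condition
#'
#' Density of log10 REV per condition — the standard first look at how
#' expression variability shifts between conditions.
#'
#' @param revs REV tibble from [compute_rev()].
#' @return A ggplot object.
#' @export
plot_rev_distribution <- function(revs) {
  ggplot2::ggplot(revs, ggplot2::aes(x = .data$rev,
                                     colour = .data$condition)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "REV (%)", y = "density", colour = NULL,
                  title = "Relative expression variability") +
    ggplot2::theme_minimal()
}

#' Plot the GES stability shift between conditions
#'
#' Scatter of per-gene stability percentiles in one condition against the
#' other; genes far off the diagonal changed their expression control.
#'
#' @param shift Tibble from [ges_shift()].
#' @return A ggplot object.
#' @export
plot_ges_shift <- function(shift) {
  ggplot2::ggplot(shift, ggplot2::aes(x = .data$ges_a, y = .data$ges_b,
                                      colour = .data$outlier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "GES (condition A)", y = "GES (condition B)",
                  colour = "GES outlier") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_regulation Autoplot method for regulation tables.
#' @exportS3Method ggplot2::autoplot
autoplot.gfp_regulation <- function(object, ...) {
  plot_regulation(object, ...)
}

#' Plot regulation calls against the adaptive cut-off
#'
#' Absolute fold change against the per-gene cut-off; called genes sit
#' above the identity line with a significant p-value.
#'
#' @param records A `gfp_regulation` tibble from [call_regulation()].
#' @param object A `gfp_regulation` tibble (autoplot method).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_regulation <- function(records, ...) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$cut, y = abs(.data$x),
                                        colour = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(up = "red3", down = "blue3",
                                            unchanged = "grey50")) +
    ggplot2::labs(x = "per-gene cut-off (CUT)", y = "|fold change|",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_coordination Autoplot method for coordination matrices.
#' @exportS3Method ggplot2::autoplot
autoplot.gfp_coord <- function(object, ...) {
  plot_coordination(object, ...)
}

#' Heatmap of a coordination matrix
#'
#' @param coord A `gfp_coord` matrix from [coordination_matrix()].
#' @param object A `gfp_coord` matrix (autoplot method).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_coordination <- function(coord, ...) {
  df <- tibble::as_tibble(as.table(unclass(coord)), .name_repair = "minimal")
  names(df) <- c("gene_a", "gene_b", "rho")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_a, y = .data$gene_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                  high = "red3", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ρ",
                  title = paste("Coordination,", attr(coord, "condition"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @describeIn plot_norm_trace Autoplot method for normalization results.
#' @exportS3Method ggplot2::autoplot
autoplot.gfp_norm <- function(object, ...) {
  plot_norm_trace(object, ...)
}

#' Plot the normalization convergence trace
#'
#' @param norm A `gfp_norm` object from [normalize_iterative()].
#' @param object A `gfp_norm` object (autoplot method).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_norm_trace <- function(norm, ...) {
  ggplot2::ggplot(norm$trace,
                  ggplot2::aes(x = .data$iteration,
                               y = .data$max_rel_change)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "max relative change") +
    ggplot2::theme_minimal()
}
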