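#' Replicate-agreement scatter plot
#'
#' Scatter of replicate 2 against replicate 1 log2 enrichment over shared
#' proteins, with the OLS fit and an R-squared annotation.
#'
#' @param a,b `enrichment_table`s on the same axis (rep1, rep2).
#' @param correlation Optional precomputed `correlation_report`; computed
#'   from `a` and `b` when missing.
#' @return A ggplot object.
#' @export
plot_replicate_scatter <- function(a, b, correlation = NULL) {
  if (is.null(correlation)) correlation <- replicate_correlation(a, b)
  shared <- intersect(names(a$values), names(b$values))
  df <- data.frame(rep1 = a$values[shared], rep2 = b$values[shared])
  lab <- sprintf("R² = %.3f", correlation$r_squared)
  ggplot2::ggplot(df, ggplot2::aes(x = rep1, y = rep2)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = correlation$slope,
                         intercept = correlation$intercept,
                         colour = "firebrick") +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = paste0("log2 enrichment, replicate 1 (", a$axis, ")"),
                  y = paste0("log2 enrichment, replicate 2 (", b$axis, ")")) +
    ggplot2::theme_bw()
}

#' FPI curve with the chosen cutoff marked
#'
#' @param curve An `fpi_curve`.
#' @param cutoff Optional `cutoff_result` to mark with dashed lines.
#' @return A ggplot object.
#' @export
plot_fpi_curve <- function(curve, cutoff = NULL) {
  p <- ggplot2::ggplot(curve$points,
                       ggplot2::aes(x = cutoff, y = fpi)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = paste0("log2 ratio cutoff (", curve$axis, ", ",
                             curve$replicate, ")"),
                  y = paste0("FPI rate (", curve$fp_list_name, ", n = ",
                             curve$n_fp_observed, ")")) +
    ggplot2::theme_bw()
  if (!is.null(cutoff)) {
    p <- p +
      ggplot2::geom_vline(xintercept = cutoff$cutoff, linetype = "dashed",
                          colour = "firebrick") +
      ggplot2::geom_hline(yintercept = cutoff$target_fpi, linetype = "dotted")
  }
  p
}

#' Filter-1 vs filter-2 scatter with cutoff lines
#'
#' Each protein's no-ligase-axis ratio against its spatial-control-axis
#' ratio for one replicate; proteins in the upper-right quadrant (above both
#' cutoffs) pass the replicate's dual filter. Final-proteome proteins can be
#' highlighted.
#'
#' @param r_f1,r_f2 The replicate's `enrichment_table`s on the no-ligase
#'   and spatial-control axes.
#' @param c_f1,c_f2 The matching `cutoff_result`s.
#' @param highlight Optional accessions to colour (e.g. the final proteome).
#' @return A ggplot object.
#' @export
plot_filter_scatter <- function(r_f1, r_f2, c_f1, c_f2, highlight = NULL) {
  shared <- intersect(names(r_f1$values), names(r_f2$values))
  df <- data.frame(accession = shared,
                   f1 = r_f1$values[shared], f2 = r_f2$values[shared])
  df$final <- df$accession %in% highlight
  ggplot2::ggplot(df, ggplot2::aes(x = f1, y = f2,
                                   colour = final)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = c_f1$cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c_f2$cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = paste0("log2 ratio ", r_f1$axis, " (", r_f1$replicate, ")"),
                  y = paste0("log2 ratio ", r_f2$axis, " (", r_f2$replicate, ")")) +
    ggplot2::theme_bw()
}
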