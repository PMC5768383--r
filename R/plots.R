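coexmod_fill <- function(modules) {
  known <- grDevices::colors()
  stats::setNames(
    ifelse(modules %in% known, modules, "grey30"), modules)
}

#' Plot module sizes
#'
#' Bar chart of module sizes, bars filled with their module color (grey
#' last).
#'
#' @param object A `module_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot module_assignment
#' @export
autoplot.module_assignment <- function(object, ...) {
  lv <- c(object$colors, "grey")
  df <- tibble::tibble(
    module = factor(names(object$sizes), levels = lv),
    size = as.integer(object$sizes)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$size,
    fill = .data$module)) +
    ggplot2::geom_col(color = "grey20", show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = coexmod_fill(lv)) +
    ggplot2::labs(x = "consensus module", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot the eigengene-preservation heatmap
#'
#' Module x module heatmap of the pairwise preservation statistic
#' `P_ij`; high values (red) mean the eigengene correlation of that module
#' pair is nearly identical in the two cohorts.
#'
#' @param object A `preservation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot preservation_result
#' @export
autoplot.preservation_result <- function(object, ...) {
  mods <- rownames(object$P)
  df <- tidyr::expand_grid(row = mods, col = mods)
  df$preservation <- as.vector(t(object$P))
  df$row <- factor(df$row, levels = rev(mods))
  df$col <- factor(df$col, levels = mods)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
    fill = .data$preservation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
      high = "red", midpoint = 0.5, limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "preservation",
      title = sprintf("Eigengene preservation: %s vs %s (overall D = %.2f)",
        object$cohorts[1], object$cohorts[2], object$overall_d)
    ) +
    ggplot2::theme_minimal()
}

#' Per-module preservation bar plot
#'
#' Bar graph of the per-module preservation indices `D_i`, bars filled with
#' module colors.
#'
#' @param result A `preservation_result`.
#' @return A ggplot.
#' @export
plot_preservation_d <- function(result) {
  stopifnot(inherits(result, "preservation_result"))
  df <- result$module_d
  df$module <- factor(df$module, levels = df$module)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$d,
    fill = .data$module)) +
    ggplot2::geom_col(color = "grey20", show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = coexmod_fill(levels(df$module))) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "preservation D") +
    ggplot2::theme_minimal()
}

#' Plot an eigengene network correlation heatmap
#'
#' @param object An `eigengene_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eigengene_network
#' @export
autoplot.eigengene_network <- function(object, ...) {
  ord <- object$tree$labels[object$tree$order]
  df <- tidyr::expand_grid(row = ord, col = ord)
  df$correlation <- as.vector(t(object$cor[ord, ord]))
  df$row <- factor(df$row, levels = rev(ord))
  df$col <- factor(df$col, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
    fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
      high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
      title = sprintf("Eigengene network: %s", object$cohort)) +
    ggplot2::theme_minimal()
}
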