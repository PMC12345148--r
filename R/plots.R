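# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_col facet_wrap labs
#'   coord_polar theme_minimal scale_y_continuous
#' @export
ggplot2::autoplot

#' Plot the feature-class distribution of edit sites per genotype
#'
#' Pie charts (the field's usual display for editome element proportions) or
#' stacked bars of the per-genotype feature-class proportions.
#'
#' @param x An `editome_summary` from [distribution_summary()].
#' @param style `"pie"` or `"bar"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.editome_summary <- function(x, style = c("pie", "bar"), ...) {
  style <- match.arg(style)
  p <- ggplot(x$features,
              aes(x = if (style == "pie") "" else .data$genotype,
                  y = .data$prop, fill = .data$feature_class)) +
    geom_col(width = 1, colour = "white") +
    labs(x = NULL, y = "proportion of consensus sites",
         fill = "feature class") +
    theme_minimal()
  if (style == "pie") {
    p + coord_polar(theta = "y") + facet_wrap(~genotype)
  } else {
    p
  }
}

#' Plot Venn cell sizes
#'
#' An UpSet-style bar chart of the exclusive Venn cells (ordered by degree),
#' which scales to four sets better than overlapping ellipses.
#'
#' @param x A `venn_partition` from [venn_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.venn_partition <- function(x, ...) {
  df <- as_tibble(x) |>
    mutate(cell = factor(.data$cell, levels = .data$cell))
  ggplot(df, aes(x = .data$cell, y = .data$n, fill = factor(.data$degree))) +
    geom_col() +
    labs(x = "exclusive cell", y = "elements", fill = "sets") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-genotype unique-set sizes and percent change
#'
#' @param x An `editome_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot of unique consensus sites and genes per genotype.
#' @export
autoplot.editome_report <- function(x, ...) {
  df <- x$counts |>
    tidyr::pivot_longer(c("n_unique_sites", "n_unique_genes"),
                        names_to = "what", values_to = "n") |>
    mutate(what = ifelse(.data$what == "n_unique_sites", "sites", "genes"))
  ggplot(df, aes(x = .data$genotype, y = .data$n, fill = .data$what)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "uniquely edited elements", fill = NULL) +
    theme_minimal()
}
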