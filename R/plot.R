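#' Heatmap of a per-plot effect on the field lattice
#'
#' Renders any per-plot column (an error component, a genetic value, a
#' phenotype) as a column x row heatmap, optionally faceted by
#' environment — the standard way to eyeball simulated global trend,
#' local trend, and extraneous stripes.
#'
#' @param df Table with columns `col`, `row`, optionally `env`, and the
#'   effect column.
#' @param effect Name of the column to render, e.g. `"e.total.Trait1"` or
#'   `"y.Trait1"`.
#' @param env Optional single environment to display.
#' @return A ggplot object.
#' @importFrom ggplot2 .data
#' @export
plot_effects <- function(df, effect, env = NULL) {
  if (!effect %in% names(df))
    stop(sprintf("no column `%s` in `df`", effect), call. = FALSE)
  if (!is.null(env)) df <- df[df$env == env, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data[[effect]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "#ffffbf",
                                  high = "#a50026",
                                  midpoint = stats::median(df[[effect]])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Column", y = "Row", fill = effect) +
    ggplot2::theme_minimal()
  if (!is.null(df$env) && length(unique(df$env)) > 1L)
    p <- p + ggplot2::facet_wrap(~env, labeller = ggplot2::label_both)
  p
}
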