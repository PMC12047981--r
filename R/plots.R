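#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_raster geom_tile
#'   scale_fill_viridis_c scale_fill_manual labs theme_minimal facet_wrap
NULL

#' Plot a morphospace
#'
#' Scatter of the submissions' discretized grid positions.
#'
#' @param object A `morphospace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot morphospace
#' @export
autoplot.morphospace <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$gx, y = .data$gy)) +
    geom_point(size = 2) +
    labs(x = "grid x", y = "grid y",
         title = paste0("Morphospace (", nrow(df), " submissions, ",
                        object$grid_size, "×", object$grid_size,
                        " grid)")) +
    theme_minimal()
}

#' Plot a permutation t-map
#'
#' Heatmap of the t-statistic grid with significant cells outlined and
#' cluster local maxima marked.
#'
#' @param object A `statmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot statmap
#' @export
autoplot.statmap <- function(object, ...) {
  df <- tidy(object)
  pl <- ggplot(df, aes(x = .data$gx, y = .data$gy)) +
    geom_raster(aes(fill = .data$t)) +
    scale_fill_viridis_c(name = "t") +
    labs(x = "grid x", y = "grid y",
         title = paste0("Permutation t-map",
                        if (!is.null(object$score_name))
                          paste0(": ", object$score_name) else "")) +
    theme_minimal()
  if (any(df$sig)) {
    pl <- pl + geom_tile(data = df[df$sig, ], fill = NA,
                         colour = "white", linewidth = 0.2)
  }
  if (nrow(object$maxima) > 0L) {
    pl <- pl + geom_point(data = object$maxima, colour = "red", size = 2)
  }
  pl
}

#' Plot a per-domain recipe table
#'
#' Tile plot of the features-by-domains binary recipe table, mirroring the
#' way optimal feature combinations are usually tabulated.
#'
#' @param recipes A domain recipe table from [aggregate_domain_recipes()]
#'   or [plant_recipes()].
#' @return A ggplot.
#' @export
plot_domain_recipes <- function(recipes) {
  domains <- setdiff(names(recipes), "feature")
  df <- tidyr::pivot_longer(recipes, -"feature", names_to = "domain",
                            values_to = "included")
  df$feature <- factor(df$feature, levels = rev(feature_names()))
  df$domain <- factor(df$domain, levels = domains)
  ggplot(df, aes(x = .data$domain, y = .data$feature,
                 fill = factor(.data$included))) +
    geom_tile(colour = "grey70") +
    scale_fill_manual(values = c(`0` = "white", `1` = "grey25"),
                      name = "included") +
    labs(x = NULL, y = NULL, title = "Optimal recipes by outcome domain") +
    theme_minimal()
}
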