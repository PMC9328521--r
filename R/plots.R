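#' Score plot of a fitted tcam
#'
#' Scatter plot of subject trajectories in the reduced space. Each point is
#' a whole trajectory; axis labels carry the explained-variance fractions.
#'
#' @param object A fitted `tcam`.
#' @param x,y Factor indices for the axes.
#' @param colour Optional vector (or named vector keyed by subject) used to
#'   colour points, e.g. group labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcam <- function(object, x = 1, y = 2, colour = NULL, ...) {
  sc <- tcam_scores(object, q = max(x, y))
  df <- tibble(
    subject = sc$subject,
    fx = sc[[paste0("F", x)]],
    fy = sc[[paste0("F", y)]]
  )
  if (!is.null(colour)) {
    df$colour <- if (!is.null(names(colour))) colour[df$subject] else colour
  }
  ev <- object$explained_variance
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fx, y = .data$fy)) +
    ggplot2::labs(
      x = sprintf("F%d (%.1f%%)", x, 100 * ev[x]),
      y = sprintf("F%d (%.1f%%)", y, 100 * ev[y])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    g + ggplot2::geom_point()
  } else {
    g + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Scree plot of a fitted tcam
#'
#' @param model A fitted `tcam`.
#' @param n_factors How many leading factors to show.
#' @return A ggplot object.
#' @export
plot_scree <- function(model, n_factors = min(20L, length(model$explained_variance))) {
  df <- head(scree_table(model), n_factors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::labs(x = "factor", y = "explained variance fraction") +
    ggplot2::theme_minimal()
}

#' Bar plot of top feature loadings
#'
#' @param ranking A tibble from [top_loadings_features()] or
#'   [project_loadings_direction()].
#' @param n_features How many top features to show.
#' @return A ggplot object.
#' @export
plot_top_loadings <- function(ranking, n_features = min(20L, nrow(ranking))) {
  df <- head(ranking, n_features)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "signed contribution", y = NULL) +
    ggplot2::theme_minimal()
}
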