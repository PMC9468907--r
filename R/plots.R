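#' Plot a growth-form classification
#'
#' Species on the first two trait principal components, coloured by
#' assigned growth form.
#'
#' @param object A `growthform_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot growthform_model
#' @export
autoplot.growthform_model <- function(object, ...) {
  scores <- tibble::as_tibble(object$pca$scores, rownames = "species") |>
    dplyr::left_join(object$assignments, by = "species")
  ggplot2::ggplot(scores,
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$growth_form)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$pca$variance_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$pca$variance_pct[2]),
      colour = "Growth form",
      title = "Growth-form classification on trait principal components"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fourth-corner trait-environment coefficients
#'
#' Heat-map of the trait-by-environment interaction coefficients of a
#' fitted fourth-corner model.
#'
#' @param object A `fourthcorner_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fourthcorner_fit
#' @export
autoplot.fourthcorner_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df,
    ggplot2::aes(.data$env_variable, .data$trait, fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
      high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "Environment variable", y = "Trait index",
      fill = "Coefficient",
      title = "Fourth-corner trait-environment coefficients") +
    ggplot2::theme_minimal()
}

#' Plot an environmental site ordination
#'
#' Site scores on the first two environment principal components with
#' variable loadings as arrows.
#'
#' @param object A `site_ordination`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot site_ordination
#' @export
autoplot.site_ordination <- function(object, ...) {
  arrow_scale <- 0.8 * max(abs(as.matrix(
    object$scores[c("PC1", "PC2")])))
  loadings <- tibble::as_tibble(object$loadings, rownames = "variable")
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$site_id), vjust = -0.6,
      size = 2.5) +
    ggplot2::geom_segment(data = loadings,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
        yend = .data$PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey40") +
    ggplot2::geom_text(data = loadings,
      ggplot2::aes(x = .data$PC1 * arrow_scale, y = .data$PC2 * arrow_scale,
        label = .data$variable),
      colour = "grey30", vjust = 1.5, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$variance_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$variance_pct[2]),
      title = "Site environmental ordination"
    ) +
    ggplot2::theme_minimal()
}

#' Plot interpolated growth-form cover surfaces
#'
#' Filled contour surfaces of growth-form percent cover across the first
#' two environmental ordination axes, one facet per growth form; grid
#' cells outside the convex hull of the sites are blank.
#'
#' @param object A `cover_surfaces` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cover_surfaces
#' @export
autoplot.cover_surfaces <- function(object, ...) {
  df <- object$surfaces[!is.na(object$surfaces$cover), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$cover)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$cover),
      breaks = unique(unlist(object$levels)), colour = "white",
      linewidth = 0.2) +
    ggplot2::geom_point(data = object$sites,
      ggplot2::aes(.data$PC1, .data$PC2), size = 0.8, colour = "black") +
    ggplot2::facet_wrap(~form) +
    ggplot2::scale_fill_viridis_c(option = "viridis") +
    ggplot2::labs(x = "Environment PC1", y = "Environment PC2",
      fill = "% cover",
      title = "Growth-form cover across environmental space") +
    ggplot2::theme_minimal()
}

#' Plot bare ground against grazing pressure by dominance group
#'
#' Site bare ground versus the dung-proportion grazing proxy, split by
#' lateral- vs tufted-attractor dominance, with per-group least-squares
#' lines.
#'
#' @param object A `site_summary` tibble with `dominance` set.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_bareground_dung <- function(object, ...) {
  df <- object[!is.na(object$dominance), ]
  ggplot2::ggplot(df,
    ggplot2::aes(.data$dung_proportion, .data$bare_ground_mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
      colour = "steelblue") +
    ggplot2::facet_wrap(~dominance, labeller = ggplot2::as_labeller(c(
      lateral = "Lateral-attractor dominated",
      tufted = "Tufted-attractor dominated"))) +
    ggplot2::labs(x = "Proportion of quadrats with dung",
      y = "Mean bare ground (%)",
      title = "Bare ground vs grazing pressure by dominant growth form") +
    ggplot2::theme_minimal()
}
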