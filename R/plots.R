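#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an AIC ranking
#'
#' Dot plot of dAIC by model, colored by model class (conventional OM vs
#' misclassification MM), with the dAIC = 2 competitiveness threshold drawn.
#'
#' @param object An `occu_ranking` from [rank_models()].
#' @param max_models Show at most this many top models.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occu_ranking <- function(object, max_models = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), max_models)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dAIC, y = .data$label,
                                  colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(Delta * "AIC"), y = NULL, colour = "class",
      title = "Candidate models ranked by AIC"
    ) +
    ggplot2::theme_minimal()
}

#' Map model-averaged occurrence probabilities over a grid
#'
#' Tile map of `psi_avg` (or `p_avg`) by cell coordinates when
#' `easting`/`northing` are present, otherwise by cell index.
#'
#' @param grid A tibble with `cell_id`, optional `easting`/`northing`, and
#'   the probability column.
#' @param what `"psi_avg"` or `"p_avg"`.
#' @return A ggplot object.
#' @export
plot_occurrence_map <- function(grid, what = c("psi_avg", "p_avg")) {
  what <- match.arg(what)
  grid <- tibble::as_tibble(grid)
  if (!all(c("easting", "northing") %in% names(grid))) {
    n <- nrow(grid)
    side <- ceiling(sqrt(n))
    grid$easting <- (seq_len(n) - 1) %% side
    grid$northing <- (seq_len(n) - 1) %/% side
  }
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$easting, y = .data$northing,
                                     fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      fill = if (what == "psi_avg") expression(bar(psi)) else expression(bar(p)),
      title = if (what == "psi_avg") {
        "Model-averaged occurrence probability"
      } else {
        "Model-averaged detection probability"
      }
    ) +
    ggplot2::theme_minimal()
}
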