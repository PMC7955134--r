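#' Plot an epistasis analysis
#'
#' Tile matrix of splits (rows) by traits (columns), filled by interaction
#' class and annotated with the interaction magnitude epsilon.
#'
#' @param object An `epistasis_tbl` from [analyze_epistasis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epistasis_tbl <- function(object, ...) {
  df <- tidy_results(object) |>
    dplyr::mutate(
      family = factor(sub("^[+-]", "", .data$label),
                      levels = c("ADD", "ME", "SE", "RSE")),
      combination = factor(.data$combination,
                           levels = rev(unique(.data$combination)))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$combination,
                                   fill = .data$family)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = format_epistasis_cell(.data$label, .data$epsilon)
    ), size = 3) +
    ggplot2::scale_fill_manual(values = c(
      ADD = "grey85", ME = "#9ecae1", SE = "#fdae6b", RSE = "#a1d99b"
    ), drop = FALSE, name = "class") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Epistatic interactions by split and trait") +
    ggplot2::theme_minimal()
}

#' Plot pathway verdicts
#'
#' One tile per (pathway, step) coloured by whether the step is permitted
#' on every considered trait; blocked steps are marked.
#'
#' @param object A `pathway_tbl` from [classify_pathways()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathway_tbl <- function(object, ...) {
  steps <- pathway_steps(object) |>
    dplyr::group_by(.data$pathway, .data$step, .data$to) |>
    dplyr::summarise(permitted = all(.data$permitted), .groups = "drop")
  ggplot2::ggplot(steps, ggplot2::aes(x = factor(.data$pathway),
                                      y = .data$step,
                                      fill = .data$permitted)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$to), size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#a1d99b",
                                          `FALSE` = "#fc9272"),
                               name = "permitted") +
    ggplot2::labs(x = "pathway", y = "step",
                  title = "Stepwise pathway accessibility") +
    ggplot2::theme_minimal()
}

#' Heat map of the fitness-pathway landscape
#'
#' Value-faithful tile rendering of [landscape_grid()]: pathways on the
#' x-axis, evolutionary step on the y-axis, tile fill = trait value, one
#' facet per trait.  No interpolation is applied.
#'
#' @param x A [deconvolution()].
#' @param traits Traits to show (default: all).
#' @return A ggplot.
#' @examples
#' plot_landscape(bm3_fixture(), traits = c("ddg", "ttf"))
#' @export
plot_landscape <- function(x, traits = NULL) {
  grid <- landscape_grid(x, traits = traits)
  ggplot2::ggplot(grid, ggplot2::aes(x = factor(.data$pathway),
                                     y = .data$step,
                                     fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype), size = 2.6) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::scale_fill_gradient(low = "white", high = "#2171b5") +
    ggplot2::labs(x = "pathway", y = "evolutionary step",
                  title = "Multiparametric fitness-pathway landscape") +
    ggplot2::theme_minimal()
}
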