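#' Plot a mutational fitness landscape
#'
#' Position-by-amino-acid heat map of predicted activities: wild-type
#' identity cells outlined, masked cells left blank (missing, not zero).
#'
#' @param ls A `fitness_landscape`.
#' @return A ggplot.
#' @export
plot_landscape <- function(ls) {
  df <- as_tibble(ls) |>
    dplyr::mutate(mut_aa = factor(.data$mut_aa,
                                  levels = rev(sort(unique(.data$mut_aa)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mut_aa)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$activity), color = "grey90") +
    ggplot2::geom_point(data = dplyr::filter(df, .data$is_wt_cell),
                        shape = 16, size = 0.8) +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "mean log\nfluorescence") +
    ggplot2::labs(x = "residue position", y = "mutant amino acid") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @export
#' @method autoplot fitness_landscape
#' @importFrom ggplot2 autoplot
autoplot.fitness_landscape <- function(object, ...) plot_landscape(object)

#' Plot leave-one-out cross-validation error against lambda
#'
#' @param loo Output of [loo_cv()], or the `loo` element of a
#'   `sortscape_run`.
#' @return A ggplot.
#' @export
plot_loo <- function(loo) {
  summary <- if (!is.null(loo$summary)) loo$summary else loo
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$lambda,
                                        y = .data$mean_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "mean LOO MSE") +
    ggplot2::theme_minimal()
}

#' Violin plot of activity by residue subgroup
#'
#' @param groups Output of [group_distributions()].
#' @return A ggplot.
#' @export
plot_group_violins <- function(groups) {
  ggplot2::ggplot(groups$values,
                  ggplot2::aes(x = .data$group, y = .data$activity)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "predicted mean log fluorescence") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of predicted mutant activities
#'
#' Variants ranked by activity, the wild type marked — the activity
#' distribution across the whole library at a glance.
#'
#' @param estimates An `activity_estimates` tibble.
#' @return A ggplot.
#' @export
plot_waterfall <- function(estimates) {
  df <- estimates |>
    dplyr::arrange(dplyr::desc(.data$activity)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$activity)) +
    ggplot2::geom_col(width = 1, fill = "grey60") +
    ggplot2::geom_point(data = dplyr::filter(df, .data$variant_id == "WT"),
                        color = "red", size = 2) +
    ggplot2::labs(x = "variant rank", y = "predicted mean log fluorescence") +
    ggplot2::theme_minimal()
}
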