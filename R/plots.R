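#' Plot explained-variance curves
#'
#' Cross-validated R-squared against the number of principal components,
#' one line per predictor set (and one panel per trait when several are
#' present).
#'
#' @param object An `ev_curve` tibble (possibly several sets/traits bound
#'   together).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ev_curve
#' @export
autoplot.ev_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$r2_cv,
                                            colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "number of principal components",
                  y = expression("cross-validated" ~ R^2),
                  colour = "predictor set") +
    ggplot2::theme_minimal()
  if (length(unique(object$trait[!is.na(object$trait)])) > 1) {
    p <- p + ggplot2::facet_wrap(~trait)
  }
  p
}

#' Plot cluster allele-frequency clines
#'
#' Restored (or mean) cluster clines against the environmental gradient.
#'
#' @param model A [cluster_snps()] result (ideally after
#'   [restore_variance()]).
#' @param env Named gradient vector per population.
#' @param env_label Axis label (default "environmental gradient").
#' @return A ggplot object.
#' @export
plot_cline_clusters <- function(model, env,
                                env_label = "environmental gradient") {
  M <- model$restored_cline %||% model$cluster_mean_cline
  d <- as_tibble(as.data.frame(t(M)), rownames = "population") |>
    tidyr::pivot_longer(-"population", names_to = "cluster",
                        values_to = "frequency")
  d$env <- env[d$population]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$env, y = .data$frequency,
                                  colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = env_label, y = "PEA frequency", colour = "cluster") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot climate-driver rankings
#'
#' Explained variance per climate variable, grouped by data source.
#'
#' @param ranking A [rank_climate_drivers()] tibble.
#' @return A ggplot object.
#' @export
plot_driver_ranking <- function(ranking) {
  ord <- ranking |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(m = mean(.data$r2_cv), .groups = "drop") |>
    dplyr::arrange(.data$m)
  ranking$variable <- factor(ranking$variable, levels = ord$variable)
  ggplot2::ggplot(ranking, ggplot2::aes(x = .data$variable, y = .data$r2_cv,
                                        fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression("cross-validated" ~ R^2),
                  fill = "data source") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
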