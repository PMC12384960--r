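#' Plot the Mexican-hat kernel profile
#'
#' Radial kernel profile with the zero-crossing radius marked; under the
#' static approximation that radius is the classifier's detection
#' radius.
#'
#' @param params A [kernel_params()] object.
#' @param r_max Right end of the distance axis (default 4 sigma1).
#' @return A ggplot object.
#' @export
plot_kernel <- function(params, r_max = 4 * params$sigma1) {
  r <- seq(0, r_max, length.out = 400)
  df <- tibble(r = r, omega = kernel_profile(r, params))
  zc <- zero_crossing_radius(params$sigma1)
  ggplot2::ggplot(df, ggplot2::aes(x = r, y = .data$omega)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = zc, linetype = "dashed") +
    ggplot2::annotate("text", x = zc, y = max(df$omega), hjust = -0.1,
                      label = sprintf("zero crossing r = %.3g", zc)) +
    ggplot2::labs(x = "distance", y = expression(omega(r)),
                  title = "Mexican-hat lateral kernel") +
    ggplot2::theme_minimal()
}

#' Plot a fitted model's support geometry
#'
#' Scatter of the first two embedding coordinates: support samples
#' coloured by class, class-mean neurons as crosses, and (Euclidean
#' metric only) the initial detection radius drawn around each class
#' mean.
#'
#' @param object A [fieldshot()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fieldshot_model <- function(object, ...) {
  td <- tidy(object)
  dn <- colnames(object$support)[1:2]
  means <- as_tibble(object$class_positions)
  means$label <- factor(object$class_levels, levels = object$class_levels)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data[[dn[1]]], y = .data[[dn[2]]],
                                        colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = means, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::labs(title = "Support geometry",
                  subtitle = sprintf("sigma1 = %.3g, detection radius %.3g (%s)",
                                     object$sigma1,
                                     zero_crossing_radius(object$sigma1),
                                     object$metric)) +
    ggplot2::theme_minimal()
  if (object$metric == "euclidean") {
    th <- seq(0, 2 * pi, length.out = 120)
    rad <- zero_crossing_radius(object$sigma1)
    circ <- tidyr::crossing(means[c(dn, "label")], tibble(.th = th)) |>
      dplyr::mutate(
        !!dn[1] := .data[[dn[1]]] + rad * cos(.data$.th),
        !!dn[2] := .data[[dn[2]]] + rad * sin(.data$.th))
    p <- p + ggplot2::geom_path(data = circ,
                                ggplot2::aes(group = .data$label),
                                linetype = "dotted", alpha = 0.7)
  }
  p
}

#' Plot per-episode accuracies of an evaluation
#'
#' Histogram of episode accuracies with the mean marked; the 1-NN
#' baseline mean is overlaid when it was scored.
#'
#' @param object A `fieldshot_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fieldshot_eval <- function(object, ...) {
  g <- glance(object)
  p <- ggplot2::ggplot(object$episodes, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = g$mean_accuracy, linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%d-way %d-shot accuracy over %d episodes",
                      object$config$n_way, object$config$k_shot,
                      nrow(object$episodes)),
      subtitle = sprintf("mean %.4f (se %.4f)", g$mean_accuracy, g$se_accuracy),
      x = "episode accuracy", y = "episodes") +
    ggplot2::theme_minimal()
  if (!is.na(g$knn_accuracy)) {
    p <- p + ggplot2::geom_vline(xintercept = g$knn_accuracy,
                                 linetype = "dotted", colour = "red")
  }
  p
}
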