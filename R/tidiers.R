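#' Tidy a fitted neural-field model
#'
#' Returns the support set as the model sees it: embedded coordinates,
#' label, class index, and the distance from each support sample to its
#' class-mean neuron.
#'
#' @param x A [fieldshot()] model.
#' @param ... Unused.
#' @return A tibble with one row per support sample.
#' @exportS3Method generics::tidy
tidy.fieldshot_model <- function(x, ...) {
  coords <- as_tibble(x$support)
  coords$label <- factor(x$class_levels[x$labels], levels = x$class_levels)
  coords$class_index <- x$labels
  coords$dist_to_class_mean <- vapply(seq_len(nrow(x$support)), function(i) {
    pairwise_distance(x$support[i, ], x$class_positions[x$labels[i], ],
                      x$metric, x$p)
  }, numeric(1))
  coords
}

#' One-row summary of a fitted neural-field model
#'
#' @param x A [fieldshot()] model.
#' @param ... Unused.
#' @return A one-row tibble: class/support counts, embedding dimension,
#'   the derived detection distance `z`, the initial scale and its
#'   bracket, and the metric.
#' @exportS3Method generics::glance
glance.fieldshot_model <- function(x, ...) {
  tibble(n_classes = nrow(x$class_positions), n_support = nrow(x$support),
         dim = ncol(x$support), z = x$z, sigma1 = x$sigma1,
         sigma_min = x$sigma_min, sigma_max = x$sigma_max,
         radius = zero_crossing_radius(x$sigma1),
         lambda = x$lambda, metric = x$metric)
}

#' Per-episode results of a multi-episode evaluation
#'
#' @param x A `fieldshot_eval` object from [evaluate_episodes()].
#' @param ... Unused.
#' @return Tibble with one row per episode (accuracy, 1-NN baseline
#'   accuracy and agreement, adaptation-iteration summary, seed).
#' @exportS3Method generics::tidy
tidy.fieldshot_eval <- function(x, ...) x$episodes

#' One-row summary of a multi-episode evaluation
#'
#' @param x A `fieldshot_eval` object.
#' @param ... Unused.
#' @return One-row tibble: mean accuracy over episodes, its standard
#'   error, the 1-NN baseline mean and per-query agreement, and the mean
#'   number of scale-adaptation iterations.
#' @exportS3Method generics::glance
glance.fieldshot_eval <- function(x, ...) {
  e <- x$episodes
  tibble(
    n_episodes = nrow(e),
    mean_accuracy = mean(e$accuracy),
    se_accuracy = stats::sd(e$accuracy) / sqrt(nrow(e)),
    knn_accuracy = mean(e$knn_accuracy),
    knn_agreement = mean(e$knn_agreement),
    mean_iterations = mean(e$mean_iterations)
  )
}
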