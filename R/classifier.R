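#' Support-derived initial detection distance z
#'
#' The kernel scale is initialised from a characteristic distance `z`
#' measured on the support set, chosen so that the zero-crossing radius
#' starts at `z`.  With one shot per class, `z` is half the smallest
#' distance between samples of different classes (the most conservative
#' radius: it never spans two classes' nearest frontier).  With more than
#' one shot, `z` is the largest within-class pairwise distance, so the
#' initial radius covers the spread of a class.
#'
#' @param positions `m x d` matrix of support positions.
#' @param labels Factor or integer class assignment per row.
#' @param metric,p Distance metric (see [pairwise_distance()]).
#' @return A single positive distance.
#' @examples
#' initial_z(matrix(c(0, 10)), factor(c("a", "b")))  # 5
#' @export
initial_z <- function(positions, labels, metric = "euclidean", p = 2) {
  positions <- as.matrix(positions)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(positions)) abort("one label per row required.")
  if (length(unique(labels)) < 2L) abort("at least two classes are required.")
  D <- cross_distance(positions, positions, metric, p)
  same <- outer(labels, labels, "==")
  one_shot <- max(tabulate(labels)) == 1L
  z <- if (one_shot) {
    min(D[!same]) / 2
  } else {
    diag(same) <- FALSE
    if (!any(same)) min(D[upper.tri(D)]) / 2 else max(D[same])
  }
  if (!is.finite(z) || z <= 0) {
    abort(paste0("degenerate support: the derived detection distance z is 0 ",
                 "(duplicate points); jitter the data or change the metric."),
          class = "fieldshot_degenerate_support")
  }
  z
}

#' Fit a neural-field few-shot classifier on a support set
#'
#' Training is one-shot: class-neuron positions are set to the mean of
#' each class's support positions, a binary Hebbian connection matrix is
#' wired between sample and class neurons, and the kernel scale is
#' initialised from the support geometry ([initial_z()], then
#' [sigma_from_z()] and the 3-sigma bracket [sigma_bounds()]).  Nothing
#' is optimised.
#'
#' @param data Data frame with numeric feature columns and a `label`
#'   column (the embedded support set).
#' @param metric,p Distance metric used both in the field kernels and for
#'   all support/query distances.
#' @param lambda Contraction constant of the scale-adaptation search, in
#'   (0, 1).
#' @param max_iter Scale-adaptation iteration cap.
#' @param eps Activation threshold passed to [activated_classes()].
#' @param lateral_enabled Include the high-level lateral interaction when
#'   computing class activations (default `FALSE`: classes are assumed
#'   distant, the usual few-shot regime).
#' @param sigma_v Scale of the high-level lateral kernel; defaults to the
#'   fitted elementary scale.
#' @return A `fieldshot_model` object.
#' @examples
#' sup <- tibble::tibble(x1 = c(0, 10), label = c("a", "b"))
#' m <- fieldshot(sup)
#' predict(m, tibble::tibble(x1 = c(1, 20)))
#' @export
fieldshot <- function(data, metric = "euclidean", p = 2, lambda = 0.5,
                      max_iter = 100L, eps = 0, lateral_enabled = FALSE,
                      sigma_v = NULL) {
  x <- fs_feature_matrix(data, "data")
  y <- fs_labels(data)
  metric <- match.arg(metric, fs_metrics)
  if (!is.numeric(lambda) || lambda <= 0 || lambda >= 1) {
    abort("`lambda` must lie strictly between 0 and 1.")
  }
  if (max_iter < 1L) abort("`max_iter` must be at least 1.")
  yi <- as.integer(y)
  n <- nlevels(y)
  if (n < 2L) abort("at least two classes are required.")
  class_positions <- rowsum(x, yi) / as.vector(table(yi))
  z <- initial_z(x, yi, metric, p)
  sigma1 <- sigma_from_z(z)
  b <- sigma_bounds(sigma1)
  structure(
    list(support = x, labels = yi, class_levels = levels(y),
         class_positions = class_positions,
         W = hebbian_connections(yi, n),
         z = z, sigma1 = sigma1,
         sigma_min = b[["sigma_min"]], sigma_max = b[["sigma_max"]],
         lambda = lambda, max_iter = as.integer(max_iter), eps = eps,
         metric = metric, p = p, lateral_enabled = lateral_enabled,
         sigma_v = sigma_v %||% sigma1,
         feature_names = colnames(x)),
    class = "fieldshot_model"
  )
}

#' @export
print.fieldshot_model <- function(x, ...) {
  cat(sprintf("<fieldshot_model> %d classes, %d support samples, dim %d\n",
              nrow(x$class_positions), nrow(x$support), ncol(x$support)))
  cat(sprintf("  metric: %s | sigma1 = %.4g (bracket %.4g..%.4g) | lambda = %g\n",
              x$metric, x$sigma1, x$sigma_min, x$sigma_max, x$lambda))
  invisible(x)
}

# Class activations at a given scale via the static field path.
fs_static_pass <- function(model, dists, sigma) {
  params <- kernel_params(sigma)
  u <- eta(kernel_profile(dists, params) * phi(1))
  if (model$lateral_enabled) {
    static_highlevel_response(u, model$W, model$class_positions,
                              kernel_params(model$sigma_v), lateral = TRUE,
                              metric = model$metric, p = model$p)
  } else {
    static_highlevel_response(u, model$W)
  }
}

#' Predict one query with scale adaptation
#'
#' Runs the static field response at the current scale and counts the
#' activated class neurons.  Exactly one activated neuron ends the
#' search; zero means the detection radius is too small and the scale is
#' enlarged; several mean it is too large and the scale is shrunk.  The
#' moves are a contraction-constant bracket search: on zero activations
#' the lower bound moves up to the current scale and the scale jumps a
#' fraction `lambda` into the bracket; on multiple activations the
#' mirror-image shrink step is taken.  While the relevant far bound has
#' not yet been pinned by an observation, an escape factor (`sigma /
#' lambda` upward, `lambda * sigma` downward) lets the bracket grow past
#' its initial 3-sigma range; once both bounds are observation-backed the
#' bracket only contracts, which guarantees termination whenever the
#' class-minimum distances are distinct.  If the cap is reached (exact ties make a
#' single-activation scale unattainable) the fallback predicts the class
#' with the smallest minimum distance to the query, remaining ties going
#' to the smallest class index.
#'
#' @param model A fitted [fieldshot()] model.
#' @param query Numeric query position (length = embedding dimension).
#' @return A list: `label` (factor), `class_index`, `iterations` (number
#'   of scale adjustments), `sigma_final`, `converged`, and per-pass
#'   traces `sigma_trace`, `num_activated`, `bracket_lo`, `bracket_hi`.
#' @export
scale_adapt_predict <- function(model, query) {
  stopifnot(inherits(model, "fieldshot_model"))
  check_finite(query, "query")
  if (length(query) != ncol(model$support)) {
    abort("`query` does not match the model's embedding dimension.")
  }
  dists <- drop(cross_distance(model$support, matrix(query, nrow = 1),
                               model$metric, model$p))
  sigma <- model$sigma1
  lo <- model$sigma_min
  hi <- model$sigma_max
  lam <- model$lambda
  # a bound is "certified" once an observation pins it: num = 0 at sigma
  # certifies sigma as a true lower bound, num > 1 as a true upper bound.
  # Until the opposite bound is certified, the 1/lambda (resp. lambda)
  # escape factor lets the bracket grow beyond the initial 3-sigma range.
  lo_cert <- FALSE
  hi_cert <- FALSE
  sigma_trace <- numeric(model$max_iter)
  num_trace <- integer(model$max_iter)
  lo_trace <- numeric(model$max_iter)
  hi_trace <- numeric(model$max_iter)
  for (it in seq_len(model$max_iter)) {
    v <- fs_static_pass(model, dists, sigma)
    act <- activated_classes(v, model$eps)
    sigma_trace[it] <- sigma
    num_trace[it] <- length(act)
    lo_trace[it] <- lo
    hi_trace[it] <- hi
    if (length(act) == 1L) {
      keep <- seq_len(it)
      return(fs_pred_result(model, act, it - 1L, sigma, TRUE,
                            sigma_trace[keep], num_trace[keep],
                            lo_trace[keep], hi_trace[keep]))
    }
    if (length(act) == 0L) {
      lo <- sigma
      lo_cert <- TRUE
      if (!hi_cert) hi <- max(hi, sigma / lam)
      sigma <- lo + lam * (hi - lo)
    } else {
      hi <- sigma
      hi_cert <- TRUE
      if (!lo_cert) lo <- min(lo, lam * sigma)
      sigma <- hi - lam * (hi - lo)
    }
  }
  # fallback: nearest class, ties to the smallest class index
  class_min <- vapply(seq_len(nrow(model$class_positions)),
                      function(j) min(dists[model$labels == j]), numeric(1))
  fs_pred_result(model, which.min(class_min), model$max_iter, sigma, FALSE,
                 sigma_trace, num_trace, lo_trace, hi_trace)
}

fs_pred_result <- function(model, j, iterations, sigma, converged,
                           sigma_trace, num_trace, lo_trace, hi_trace) {
  list(label = factor(model$class_levels[j], levels = model$class_levels),
       class_index = j, iterations = iterations, sigma_final = sigma,
       converged = converged, sigma_trace = sigma_trace,
       num_activated = num_trace,
       bracket_lo = lo_trace, bracket_hi = hi_trace)
}

#' Predict query labels from a fitted neural-field model
#'
#' Batch wrapper over [scale_adapt_predict()]: each query is adapted
#' independently, with the scale state reset to the fitted initial value
#' first (queries never influence one another).
#'
#' @param object A [fieldshot()] model.
#' @param new_data Data frame of embedded queries (numeric feature
#'   columns; a `label` column, if present, is ignored).
#' @param ... Unused.
#' @return A tibble with one row per query: `query_id`, `.pred`
#'   (factor on the model's class levels), `iterations` (scale
#'   adjustments used), `sigma_final` and `converged`.
#' @export
predict.fieldshot_model <- function(object, new_data, ...) {
  if (nrow(new_data) == 0L) {
    return(tibble(query_id = integer(), .pred = factor(levels = object$class_levels),
                  iterations = integer(), sigma_final = numeric(),
                  converged = logical()))
  }
  q <- fs_feature_matrix(new_data, "new_data")
  if (ncol(q) != ncol(object$support)) {
    abort("`new_data` does not match the model's embedding dimension.")
  }
  res <- purrr::map(seq_len(nrow(q)),
                    function(i) scale_adapt_predict(object, q[i, ]))
  tibble(
    query_id = seq_len(nrow(q)),
    .pred = factor(purrr::map_chr(res, ~ as.character(.x$label)),
                   levels = object$class_levels),
    iterations = purrr::map_int(res, "iterations"),
    sigma_final = purrr::map_dbl(res, "sigma_final"),
    converged = purrr::map_lgl(res, "converged")
  )
}
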