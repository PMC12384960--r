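#' One-shot Hebbian connection matrix
#'
#' Builds the binary weight matrix linking elementary (sample) neurons to
#' high-level (class) neurons: `w[j, i] = 1` iff sample `i` carries label
#' `j`.  This single assignment is the entire training rule of the
#' classifier ("fire together, wire together"): every column sums to 1
#' and row `j` sums to the size of class `j`.
#'
#' @param labels Integer vector of class indices in `1..n_classes`, one
#'   per sample.
#' @param n_classes Number of high-level neurons.  Empty classes are only
#'   permitted when `allow_empty = TRUE`.
#' @param allow_empty Allow classes with no samples (default `FALSE`).
#' @return An `n_classes` x `length(labels)` binary matrix.
#' @examples
#' hebbian_connections(c(1, 1, 2), 2)
#' @export
hebbian_connections <- function(labels, n_classes, allow_empty = FALSE) {
  if (!is.numeric(labels) || anyNA(labels) || any(labels != as.integer(labels))) {
    abort("`labels` must be integer class indices.")
  }
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > n_classes)) {
    abort(sprintf("labels out of range 1..%d.", n_classes))
  }
  if (!allow_empty && length(unique(labels)) < n_classes) {
    abort("some classes have no samples (set `allow_empty = TRUE` to permit).")
  }
  w <- matrix(0, nrow = n_classes, ncol = length(labels))
  w[cbind(labels, seq_along(labels))] <- 1
  w
}

#' Static response of the elementary field to a probe
#'
#' One-pass approximation of the elementary field's steady state when a
#' single external probe (the query) is switched on: each sample neuron
#' responds with `eta(omega(d_i) * phi(1))` where `d_i` is the distance
#' from its position to the probe and `omega` the Mexican-hat profile.
#' The response is positive exactly when the sample lies inside the
#' kernel's zero-crossing radius of the probe.
#'
#' @param positions `m x d` matrix of embedded sample positions.
#' @param probe Length-`d` query position.
#' @param params [kernel_params()] for the elementary field.
#' @param metric,p Distance metric used between samples and probe (see
#'   [pairwise_distance()]).
#' @return Numeric vector of `m` activations in (-1, 1).
#' @export
static_elementary_response <- function(positions, probe,
                                       params, metric = "euclidean", p = 2) {
  positions <- as.matrix(positions)
  check_finite(probe, "probe")
  if (length(probe) != ncol(positions)) {
    abort("`probe` does not match the embedding dimension of `positions`.")
  }
  d <- drop(cross_distance(positions, matrix(probe, nrow = 1), metric, p))
  eta(kernel_profile(d, params) * phi(1))
}

#' Static response of the high-level field
#'
#' Feedforward class activations `v_j = phi(sum_i w[j,i] phi(u_i))`.
#' With `lateral = FALSE` (the default, appropriate when classes are far
#' apart) this is a single pass.  With `lateral = TRUE` the high-level
#' lateral interaction `eta(sum_k omega_v(||ztilde_j - ztilde_k||)
#' phi(v_k))` is added and the equation solved by damped fixed-point
#' iteration started from the feedforward solution.
#'
#' @param u Elementary activations (length `m`).
#' @param W Binary connection matrix (`n x m`), see
#'   [hebbian_connections()].
#' @param class_positions `n x d` class-neuron positions; required when
#'   `lateral = TRUE`.
#' @param params_v Kernel for the high-level lateral interaction;
#'   required when `lateral = TRUE`.
#' @param lateral Include the high-level lateral term?
#' @param metric,p Metric for class-to-class distances.
#' @param tol,max_iter Fixed-point stopping rule: iterate until the
#'   largest change falls below `tol` or error after `max_iter` sweeps
#'   (the error condition carries the last iterate in field `last`).
#' @return Numeric vector of `n` class activations.
#' @export
static_highlevel_response <- function(u, W, class_positions = NULL,
                                      params_v = NULL, lateral = FALSE,
                                      metric = "euclidean", p = 2,
                                      tol = 1e-10, max_iter = 1000L) {
  check_finite(u, "u")
  if (!is.matrix(W) || ncol(W) != length(u)) {
    abort("`W` must be an n x length(u) matrix.")
  }
  ff <- phi(drop(W %*% phi(u)))
  if (!lateral) return(ff)
  if (is.null(class_positions) || is.null(params_v)) {
    abort("`class_positions` and `params_v` are required when `lateral = TRUE`.")
  }
  class_positions <- as.matrix(class_positions)
  Kv <- kernel_profile(cross_distance(class_positions, class_positions,
                                      metric, p), params_v)
  v <- ff
  for (it in seq_len(max_iter)) {
    v_new <- eta(drop(Kv %*% phi(v))) + ff
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- 0.5 * v + 0.5 * v_new
  }
  abort("high-level lateral fixed point did not converge.",
        class = "fieldshot_fixed_point_error", last = v)
}

#' Activated high-level neurons
#'
#' Indices of class neurons whose activation exceeds the threshold
#' `eps` (default 0, i.e. strictly positive net drive).  The size of
#' this set — zero, one, or several — is what the scale-adaptation loop
#' reacts to.
#'
#' @param v High-level activations.
#' @param eps Non-negative activation threshold.
#' @return Integer vector of activated class indices (possibly empty).
#' @examples
#' activated_classes(c(0.4, 0))      # 1
#' activated_classes(c(0.2, 0.1))    # 1 2
#' @export
activated_classes <- function(v, eps = 0) {
  check_finite(v, "v")
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps < 0) {
    abort("`eps` must be a single non-negative number.")
  }
  which(v > eps)
}

#' Elementary and high-level field states for dynamic integration
#'
#' Lightweight constructors for the full dynamic model.  `inputs` are the
#' binary external drives (`e`), one per neuron; `tau` the positive
#' evolution rate.  The high-level field additionally carries its lateral
#' kernel and a switch to disable the class-to-class lateral term.
#'
#' @param positions Neuron positions (`m x d` matrix or data frame of
#'   numeric columns).
#' @param inputs Binary external input per neuron (recycled scalar 0/1
#'   allowed).
#' @param params [kernel_params()] of the field's lateral kernel, or
#'   `NULL` for a field with no lateral interaction (pure relaxation to
#'   its input).
#' @param tau Positive evolution rate.
#' @param lateral_enabled Include the high-level lateral interaction?
#' @return A list of class `elementary_field` / `highlevel_field`.
#' @export
elementary_field <- function(positions, inputs, params, tau = 1) {
  positions <- as.matrix(positions)
  inputs <- rep_len(inputs, nrow(positions))
  if (!all(inputs %in% c(0, 1))) abort("`inputs` must be binary (0/1).")
  if (tau <= 0) abort("`tau` must be positive.")
  structure(list(positions = positions, inputs = inputs, params = params,
                 tau = tau),
            class = "elementary_field")
}

#' @rdname elementary_field
#' @export
highlevel_field <- function(positions, inputs = 0, params, tau = 1,
                            lateral_enabled = TRUE) {
  f <- elementary_field(positions, inputs, params, tau)
  f$lateral_enabled <- isTRUE(lateral_enabled)
  class(f) <- "highlevel_field"
  f
}

#' Forward-Euler integration of the coupled field dynamics
#'
#' Integrates the full relaxation dynamics of the two fields,
#' \deqn{\tau_u \dot u_i = \eta\!\big(\textstyle\sum_k \omega_u(\|z_i - z_k\|)\,\phi(u_k)\big) + e_{u,i} - u_i,}
#' \deqn{\tau_v \dot v_j = \eta\!\big(\textstyle\sum_k \omega_v(\|\tilde z_j - \tilde z_k\|)\,\phi(v_k)\big) + \phi\!\big(\textstyle\sum_i w_{j,i}\,\phi(u_i)\big) + e_{v,j} - v_j,}
#' by forward Euler from zero initial activations until the largest
#' time-derivative magnitude drops below `tol` or `t_max` is reached.
#' The static one-pass approximation used for prediction is the cheap
#' stand-in for this solver; [static_highlevel_response()] should agree
#' with the steady state's activation ranking when classes are well
#' separated.
#'
#' @param elem An [elementary_field()].
#' @param high A [highlevel_field()].
#' @param W Binary connection matrix (`n x m`).
#' @param dt Euler step; defaults to `0.1 * min(tau_u, tau_v)` and must
#'   stay below `min(tau)` for stability.
#' @param t_max Integration horizon (default `1e4 * max(tau)`).
#' @param tol Residual tolerance on `max(|du/dt|, |dv/dt|)`.
#' @param metric,p Distance metric for both kernels.
#' @return List with steady-state `u`, `v`, logical `converged`, the
#'   final time `t` and residual.
#' @export
integrate_fields <- function(elem, high, W, dt = NULL, t_max = NULL,
                             tol = 1e-8, metric = "euclidean", p = 2) {
  stopifnot(inherits(elem, "elementary_field"), inherits(high, "highlevel_field"))
  m <- nrow(elem$positions); n <- nrow(high$positions)
  if (!is.matrix(W) || nrow(W) != n || ncol(W) != m) {
    abort("`W` must be an n x m matrix matching the two fields.")
  }
  if (is.null(dt)) dt <- 0.1 * min(elem$tau, high$tau)
  if (is.null(t_max)) t_max <- 1e4 * max(elem$tau, high$tau)
  if (dt <= 0 || dt >= min(elem$tau, high$tau)) {
    abort("`dt` must satisfy 0 < dt < min(tau_u, tau_v).")
  }
  if (tol <= 0) abort("`tol` must be positive.")

  kmat <- function(f) {
    if (is.null(f$params)) return(matrix(0, nrow(f$positions), nrow(f$positions)))
    kernel_profile(cross_distance(f$positions, f$positions, metric, p), f$params)
  }
  Ku <- kmat(elem)
  Kv <- kmat(high)
  u <- numeric(m); v <- numeric(n)
  t <- 0; residual <- Inf
  while (t < t_max) {
    du <- (eta(drop(Ku %*% phi(u))) + elem$inputs - u) / elem$tau
    lat_v <- if (high$lateral_enabled) eta(drop(Kv %*% phi(v))) else numeric(n)
    dv <- (lat_v + phi(drop(W %*% phi(u))) + high$inputs - v) / high$tau
    residual <- max(abs(du), abs(dv))
    if (residual < tol) break
    u <- u + dt * du
    v <- v + dt * dv
    t <- t + dt
    if (any(abs(u) > 1e3) || any(abs(v) > 1e3)) {
      abort("field dynamics diverged (|activation| > 1e3).")
    }
  }
  list(u = u, v = v, converged = residual < tol, t = t, residual = residual)
}
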