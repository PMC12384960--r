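#' Mexican-hat kernel parameters
#'
#' Bundles the scales and amplitudes of the difference-of-Gaussians lateral
#' interaction kernel used by both neural fields.  The kernel family is
#' deliberately rigid: the inhibitory scale is three times the excitatory
#' scale, and the amplitudes are fixed at A = 3/2 and B = 1/2 so that
#' A - B = 1 (the kernel equals 1 at zero displacement) and A/B = 3.
#' The only free parameter is `sigma1`.
#'
#' @param sigma1 Positive excitatory scale, in embedding-space distance
#'   units.
#'
#' @return An object of class `kernel_params`: a list with elements
#'   `sigma1`, `sigma2` (= 3 sigma1), `amp_exc` (= 3/2) and `amp_inh`
#'   (= 1/2).
#'
#' @examples
#' kp <- kernel_params(1)
#' lateral_kernel(c(0, 0), kp)   # 1 at zero displacement
#' zero_crossing_radius(1)       # ~1.5722: where the kernel changes sign
#' @export
kernel_params <- function(sigma1) {
  if (!is.numeric(sigma1) || length(sigma1) != 1L || !is.finite(sigma1) ||
      sigma1 <= 0) {
    abort("`sigma1` must be a single finite positive number.")
  }
  structure(
    list(sigma1 = sigma1, sigma2 = 3 * sigma1, amp_exc = 3 / 2,
         amp_inh = 1 / 2),
    class = "kernel_params"
  )
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "<kernel_params> Mexican hat: sigma1 = %.4g, sigma2 = %.4g, A = %.3g, B = %.3g\n",
    x$sigma1, x$sigma2, x$amp_exc, x$amp_inh))
  cat(sprintf("  zero crossing at r = %.4g\n", zero_crossing_radius(x$sigma1)))
  invisible(x)
}

check_finite <- function(u, arg) {
  if (!is.numeric(u) || length(u) == 0L || anyNA(u) || !all(is.finite(u))) {
    abort(sprintf("`%s` must be finite numeric (no NA/NaN/Inf).", arg))
  }
  invisible(u)
}

#' Field activation and threshold nonlinearities
#'
#' `phi()` is the rate nonlinearity of the fields: `1 - exp(-u)` for
#' positive input and exactly 0 otherwise, so it is non-negative, bounded
#' by 1, and kills any non-positive drive.  `eta()` is the odd threshold
#' function applied to lateral-interaction sums: `1 - exp(-u)` for `u > 0`
#' and `-1 + exp(u)` for `u <= 0`, mapping the reals into (-1, 1) while
#' preserving sign.
#'
#' Both are vectorised and reject non-finite input.
#'
#' @param u Numeric vector of finite values.
#' @return Numeric vector of the same length; `phi` in \[0, 1), `eta` in
#'   (-1, 1).
#' @examples
#' phi(c(-1, 0, log(2)))   # 0, 0, 0.5
#' eta(c(-log(2), log(2))) # -0.5, 0.5
#' @export
phi <- function(u) {
  check_finite(u, "u")
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- 1 - exp(-u[pos])
  out
}

#' @rdname phi
#' @export
eta <- function(u) {
  check_finite(u, "u")
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- 1 - exp(-u[pos])
  out[!pos] <- -1 + exp(u[!pos])
  out
}

#' Mexican-hat lateral interaction kernel
#'
#' `lateral_kernel()` evaluates the difference-of-Gaussians kernel at a
#' displacement vector in embedding space; the kernel is radial, so the
#' value depends only on the Euclidean norm of the displacement.
#' `kernel_profile()` is the radial profile itself, vectorised over
#' non-negative distances, used wherever distances are computed under a
#' configurable metric rather than as displacement vectors.
#'
#' The profile is
#' \deqn{\omega(r) = \tfrac{3}{2} e^{-r^2 / (2\sigma_1^2)}
#'                 - \tfrac{1}{2} e^{-r^2 / (2\sigma_2^2)},\quad
#'       \sigma_2 = 3\sigma_1,}
#' positive for `r` below the zero-crossing radius, negative beyond it,
#' and vanishing at infinity.
#'
#' @param d Numeric displacement vector (any embedding dimension).
#' @param r Numeric vector of non-negative distances.
#' @param params A [kernel_params()] object.
#' @return Kernel value(s).
#' @examples
#' kp <- kernel_params(1)
#' lateral_kernel(c(3, 4), kp)           # evaluated at ||d|| = 5
#' kernel_profile(c(0, 1, 5), kp)
#' @export
lateral_kernel <- function(d, params) {
  check_finite(d, "d")
  stopifnot(inherits(params, "kernel_params"))
  kernel_profile(sqrt(sum(d^2)), params)
}

#' @rdname lateral_kernel
#' @export
kernel_profile <- function(r, params) {
  check_finite(r, "r")
  stopifnot(inherits(params, "kernel_params"))
  if (any(r < 0)) abort("distances `r` must be non-negative.")
  params$amp_exc * exp(-r^2 / (2 * params$sigma1^2)) -
    params$amp_inh * exp(-r^2 / (2 * params$sigma2^2))
}

#' Zero crossing of the kernel and its inverse scale relation
#'
#' With amplitudes 3/2 and 1/2 and `sigma2 = 3 sigma1`, the kernel profile
#' has a unique positive root at
#' \deqn{r = \tfrac{3}{2}\sqrt{\ln 3}\,\sigma_1 \approx 1.5722\,\sigma_1.}
#' `zero_crossing_radius()` returns that root; `sigma_from_z()` inverts
#' it, returning the scale whose zero crossing sits exactly at a target
#' distance `z` (`sigma1 = 2 z / (3 sqrt(ln 3))`).  Under the static
#' field approximation the zero-crossing radius is the classifier's
#' effective detection radius, so this pair of functions ties the kernel
#' scale to distances measured on the support set.
#'
#' @param sigma1 Positive kernel scale(s).
#' @param z Positive target distance(s).
#' @return Positive numeric of the same length as the input.
#' @examples
#' zero_crossing_radius(1)
#' sigma_from_z(zero_crossing_radius(1))  # 1: round trip
#' @export
zero_crossing_radius <- function(sigma1) {
  check_finite(sigma1, "sigma1")
  if (any(sigma1 <= 0)) abort("`sigma1` must be positive.")
  (3 / 2) * sqrt(log(3)) * sigma1
}

#' @rdname zero_crossing_radius
#' @export
sigma_from_z <- function(z) {
  check_finite(z, "z")
  if (any(z <= 0)) abort("`z` must be positive.")
  2 * z / (3 * sqrt(log(3)))
}

#' Scale-adaptation bracket from the 3-sigma rule
#'
#' Initial search bracket for the adaptive scale: `sigma_max = 3 sigma1`,
#' `sigma_min = sigma1 / 3`.
#'
#' @param sigma1 Positive kernel scale.
#' @return Named numeric vector `c(sigma_min, sigma_max)`.
#' @examples
#' sigma_bounds(1)  # 1/3, 3
#' @export
sigma_bounds <- function(sigma1) {
  check_finite(sigma1, "sigma1")
  if (any(sigma1 <= 0)) abort("`sigma1` must be positive.")
  c(sigma_min = sigma1 / 3, sigma_max = 3 * sigma1)
}
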