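fs_metrics <- c("euclidean", "cosine", "correlation", "minkowski")

#' Pairwise distance between two vectors
#'
#' The four embedding-space metrics supported throughout the package:
#' Euclidean (l2), cosine (1 - cosine of the angle), correlation
#' (1 - Pearson r), and Minkowski (lp with configurable `p`).  Cosine
#' requires non-zero vectors and correlation non-constant vectors.
#'
#' @param x,y Numeric vectors of equal length.
#' @param metric One of `"euclidean"`, `"cosine"`, `"correlation"`,
#'   `"minkowski"`.
#' @param p Minkowski order (default 2); ignored by the other metrics.
#' @return A single non-negative distance.
#' @examples
#' pairwise_distance(c(0, 0), c(3, 4), "euclidean")   # 5
#' pairwise_distance(c(1, 0), c(0, 1), "cosine")      # 1
#' @export
pairwise_distance <- function(x, y, metric = "euclidean", p = 2) {
  check_finite(x, "x"); check_finite(y, "y")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  metric <- match.arg(metric, fs_metrics)
  drop(cross_distance(matrix(x, nrow = 1), matrix(y, nrow = 1), metric, p))
}

# All cross distances between rows of a (n x d) and rows of b (m x d).
# Returns an n x m matrix. Workhorse for fields, kNN and the LE graph.
cross_distance <- function(a, b, metric = "euclidean", p = 2) {
  metric <- match.arg(metric, fs_metrics)
  if (ncol(a) != ncol(b)) abort("dimension mismatch between point sets.")
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      sqrt(pmax(d2, 0))
    },
    cosine = {
      na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
      if (any(na == 0) || any(nb == 0)) {
        abort("cosine distance is undefined for zero vectors.")
      }
      d <- 1 - tcrossprod(a / na, b / nb)
      pmax(d, 0)
    },
    correlation = {
      if (ncol(a) < 2) abort("correlation distance needs dimension >= 2.")
      ac <- a - rowMeans(a); bc <- b - rowMeans(b)
      sa <- sqrt(rowSums(ac^2)); sb <- sqrt(rowSums(bc^2))
      if (any(sa == 0) || any(sb == 0)) {
        abort("correlation distance is undefined for constant vectors.")
      }
      d <- 1 - tcrossprod(ac / sa, bc / sb)
      pmax(d, 0)
    },
    minkowski = {
      if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1) {
        abort("Minkowski order `p` must be a finite number >= 1.")
      }
      out <- matrix(0, nrow(a), nrow(b))
      for (i in seq_len(nrow(a))) {
        out[i, ] <- colSums(abs(t(b) - a[i, ])^p)^(1 / p)
      }
      out
    }
  )
}
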