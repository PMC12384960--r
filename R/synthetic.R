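#' Generate a synthetic labeled cluster bank
#'
#' Gaussian class clusters with exactly controlled geometry, standing in
#' for embedded real-image features so that every pipeline stage can be
#' exercised without downloads.  Class means are placed at the vertices
#' of a regular simplex scaled so that all pairwise mean distances equal
#' `separation` (requires `dim >= n_classes - 1`); with
#' `placement = "random"` means are instead drawn uniformly in a ball and
#' rejected until all pairwise distances reach `separation`.  Samples are
#' mean plus isotropic Gaussian noise with standard deviation `spread`;
#' `on_sphere = TRUE` projects every sample to the unit sphere for
#' cosine-metric work.
#'
#' @param n_classes Number of classes (>= 2).
#' @param per_class Samples per class.
#' @param dim Feature dimension.
#' @param separation Pairwise distance between class means.
#' @param spread Within-class standard deviation (> 0).
#' @param on_sphere Project samples to the unit sphere?
#' @param placement `"simplex"` (exact geometry, default) or `"random"`.
#' @param seed Optional integer seed (local RNG state).
#' @return Tibble with feature columns `x1..xdim` and a `label` factor,
#'   `n_classes * per_class` rows.
#' @examples
#' bank <- generate_clusters(n_classes = 5, per_class = 20, dim = 4,
#'                           separation = 10, spread = 0.5, seed = 1)
#' table(bank$label)
#' @export
generate_clusters <- function(n_classes = 5, per_class = 20, dim = 4,
                              separation = 10, spread = 0.5,
                              on_sphere = FALSE,
                              placement = c("simplex", "random"),
                              seed = NULL) {
  placement <- match.arg(placement)
  if (n_classes < 2) abort("`n_classes` must be at least 2.")
  if (per_class < 1) abort("`per_class` must be at least 1.")
  if (separation < 0) abort("`separation` must be non-negative.")
  if (spread <= 0) abort("`spread` must be positive.")
  gen <- function() {
    means <- switch(placement,
      simplex = simplex_means(n_classes, dim, separation),
      random = random_means(n_classes, dim, separation))
    x <- means[rep(seq_len(n_classes), each = per_class), , drop = FALSE] +
      matrix(rnorm(n_classes * per_class * dim, sd = spread),
             ncol = dim)
    if (on_sphere) {
      nrm <- sqrt(rowSums(x^2))
      if (any(nrm == 0)) nrm[nrm == 0] <- 1
      x <- x / nrm
    }
    colnames(x) <- paste0("x", seq_len(dim))
    out <- as_tibble(x)
    out$label <- factor(rep(sprintf("c%02d", seq_len(n_classes)),
                            each = per_class))
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Vertices of a regular simplex in R^dim with all pairwise distances
# equal to `separation`, centred at the origin.
simplex_means <- function(n_classes, dim, separation) {
  if (dim < n_classes - 1) {
    abort("simplex placement needs dim >= n_classes - 1.")
  }
  C <- stats::contr.helmert(n_classes)            # n x (n-1), columns span sum-zero
  Q <- qr.Q(qr(C))                                # orthonormal basis
  V <- Q * separation / sqrt(2)                   # unit-vertex distances are sqrt(2)
  cbind(V, matrix(0, n_classes, dim - ncol(V)))
}

random_means <- function(n_classes, dim, separation, max_tries = 1000L) {
  for (t in seq_len(max_tries)) {
    m <- matrix(runif(n_classes * dim, -2 * separation * sqrt(n_classes),
                      2 * separation * sqrt(n_classes)), ncol = dim)
    D <- cross_distance(m, m)
    if (all(D[upper.tri(D)] >= separation)) return(m)
  }
  abort("could not place class means with the requested separation.")
}

#' Catalogue of degenerate edge-case fixtures
#'
#' Named fixtures that drive each documented guard or fallback:
#' duplicated support points (the derived detection distance z collapses
#' to zero), a query exactly tied between two classes (the adaptation
#' loop cannot isolate one class and falls back), a single-class bank
#' (fitting requires >= 2 classes), and a two-island bank whose
#' neighbour graph disconnects at small `n_neighbors`.
#'
#' @return Named list; each element is a list with the fixture data
#'   (`support`, and `query` / `bank` / `n_neighbors` where relevant)
#'   and an `expect` string describing the behaviour it triggers.
#' @examples
#' names(degenerate_cases())
#' @export
degenerate_cases <- function() {
  dup <- tibble(x1 = c(0, 0), x2 = c(0, 0), label = c("a", "b"))
  tie <- list(
    support = tibble(x1 = c(0, 2), x2 = c(0, 0), label = c("a", "b")),
    query = tibble(x1 = 1, x2 = 0))
  island <- generate_clusters(n_classes = 2, per_class = 10, dim = 2,
                              separation = 50, spread = 0.1, seed = 99)
  list(
    duplicate_support = list(
      support = dup,
      expect = "initial_z()/fieldshot() raise fieldshot_degenerate_support"),
    exact_tie = list(
      support = tie$support, query = tie$query,
      expect = paste0("scale_adapt_predict() exhausts max_iter and falls ",
                      "back to the nearest class, ties to smallest index ('a')")),
    single_class = list(
      support = tibble(x1 = c(-0.3, 0.1, 0.7), label = "a"),
      expect = "fieldshot() errors: at least two classes required"),
    disconnected_graph = list(
      bank = island, n_neighbors = 3,
      expect = "laplacian_eigenmap() raises fieldshot_disconnected_graph")
  )
}
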