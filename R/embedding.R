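the_extractors <- new.env(parent = emptyenv())

#' Frozen feature-extractor plugins
#'
#' The classifier consumes numeric feature vectors produced by a frozen
#' extractor (in the full vision pipeline this would be the front part of
#' a pretrained Vision Transformer; it is never trained here).
#' Extractors are registered by name; the contract is a deterministic
#' function mapping an input table to one fixed-length numeric row per
#' input row.  The built-in `"identity"` extractor passes numeric
#' feature columns through unchanged and is what every test and the
#' synthetic pipeline use.
#'
#' @param name Plugin name.
#' @param fun Function taking the input data frame and returning a
#'   numeric matrix (or a list of equal-length numeric vectors) with one
#'   row per input row.
#' @return `register_extractor()` returns `name` invisibly;
#'   `extract_features()` returns a tibble of feature columns `f1..fD`
#'   with any `label`/`role` metadata columns carried over.
#' @param data Input data frame.
#' @param extractor Name of a registered plugin.
#' @examples
#' extract_features(tibble::tibble(x = 1:3, label = "a"))
#' @export
register_extractor <- function(name, fun) {
  if (!is.character(name) || length(name) != 1L) abort("`name` must be a string.")
  if (!is.function(fun)) abort("`fun` must be a function.")
  assign(name, fun, envir = the_extractors)
  invisible(name)
}

#' @rdname register_extractor
#' @export
extract_features <- function(data, extractor = "identity") {
  if (!exists(extractor, envir = the_extractors, inherits = FALSE)) {
    abort(sprintf("unknown extractor plugin '%s'.", extractor))
  }
  fun <- get(extractor, envir = the_extractors)
  out <- fun(data)
  if (is.list(out) && !is.data.frame(out)) {
    lens <- lengths(out)
    if (length(unique(lens)) != 1L) {
      abort("extractor returned ragged outputs (rows of different lengths).")
    }
    out <- do.call(rbind, out)
  }
  out <- as.matrix(out)
  if (!is.numeric(out) || nrow(out) != nrow(data)) {
    abort("extractor must return one numeric row per input row.")
  }
  check_finite(as.vector(out), "extracted features")
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  res <- as_tibble(out)
  for (col in intersect(fs_meta_cols, names(data))) res[[col]] <- data[[col]]
  res
}

register_extractor("identity", function(data) fs_feature_matrix(data))

#' Laplacian Eigenmaps spectral embedding
#'
#' Embeds a point set into `target_dim` dimensions using the bottom
#' non-trivial generalized eigenvectors of the graph Laplacian of a
#' symmetrized k-nearest-neighbour graph.  Affinities are binary (0/1):
#' an edge exists when either endpoint is among the other's `n_neighbors`
#' nearest points under `metric`.  The trivial constant eigenvector is
#' discarded; each returned column is sign-fixed so that its
#' largest-magnitude entry is positive, making the embedding reproducible
#' and invariant (up to that sign rule) to input row order.
#'
#' `n_neighbors` is capped at `n - 1`.  A disconnected neighbour graph is
#' an error: the spectral problem then mixes arbitrary per-component
#' constants, so the caller is asked to raise `n_neighbors`.
#'
#' @param features Numeric matrix (or data frame of numeric columns),
#'   one row per point.
#' @param target_dim Embedding dimension (default 4).
#' @param n_neighbors Neighbourhood size for the graph (default 99,
#'   capped at `n - 1`).
#' @param metric,p Distance metric for the neighbour graph (see
#'   [pairwise_distance()]).
#' @return An `n x target_dim` matrix with columns `dim1..dimK`; the
#'   effective (capped) neighbour count is attached as attribute
#'   `n_neighbors`.
#' @export
laplacian_eigenmap <- function(features, target_dim = 4, n_neighbors = 99,
                               metric = "cosine", p = 2) {
  x <- if (is.data.frame(features)) fs_feature_matrix(features) else as.matrix(features)
  n <- nrow(x)
  if (target_dim < 1 || target_dim >= n - 1) {
    abort("`target_dim` must satisfy 1 <= target_dim < n - 1.")
  }
  if (n_neighbors < 1) abort("`n_neighbors` must be at least 1.")
  k <- as.integer(min(n_neighbors, n - 1L))
  D <- cross_distance(x, x, metric, p)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]  # skip self (distance 0 sorts first)
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))  # union symmetrization
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
  if (comp$no > 1L) {
    abort(sprintf(
      "neighbour graph is disconnected (%d components); increase `n_neighbors`.",
      comp$no), class = "fieldshot_disconnected_graph")
  }
  deg <- rowSums(A)
  dhalf <- 1 / sqrt(deg)
  # symmetric normalized Laplacian; generalized eigenvectors recovered
  # as y = D^{-1/2} w
  S <- diag(n) - (dhalf * A) * rep(dhalf, each = n)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  idx <- order(es$values)                 # ascending
  take <- idx[2:(target_dim + 1L)]        # drop the trivial eigenvector
  Y <- dhalf * es$vectors[, take, drop = FALSE]
  for (jj in seq_len(ncol(Y))) {
    if (Y[which.max(abs(Y[, jj])), jj] < 0) Y[, jj] <- -Y[, jj]
  }
  colnames(Y) <- paste0("dim", seq_len(ncol(Y)))
  attr(Y, "n_neighbors") <- k
  Y
}

#' Embed a feature table with Laplacian Eigenmaps
#'
#' Data-frame front end to [laplacian_eigenmap()]: embeds the numeric
#' feature columns and returns a tibble of embedding coordinates with
#' `label`/`role` metadata carried over.
#'
#' @inheritParams laplacian_eigenmap
#' @param data Data frame with numeric feature columns and optional
#'   `label` / `role` columns.
#' @return Tibble with columns `dim1..dimK` plus carried-over metadata.
#' @export
embed_features <- function(data, target_dim = 4, n_neighbors = 99,
                           metric = "cosine", p = 2) {
  Y <- laplacian_eigenmap(fs_feature_matrix(data), target_dim, n_neighbors,
                          metric, p)
  res <- as_tibble(unclass(Y)[, , drop = FALSE])
  colnames(res) <- colnames(Y)
  for (col in intersect(fs_meta_cols, names(data))) res[[col]] <- data[[col]]
  attr(res, "n_neighbors") <- attr(Y, "n_neighbors")
  res
}

#' Jointly embed the support and query sets of an episode
#'
#' The spectral embedding is transductive: support and query features are
#' pooled, embedded together, and split back by role.  (With a
#' neighbourhood size of 99 and only a handful of support points, the
#' graph is only meaningful when queries join it; there is deliberately
#' no out-of-sample extension.)  The neighbour cap `min(n_neighbors,
#' total - 1)` applies to the pooled set.
#'
#' @inheritParams embed_features
#' @param support,query Data frames of raw features; `support` must carry
#'   a `label` column.
#' @return List with tibbles `support` (embedding + `label`) and `query`
#'   (embedding, plus `label` if the query table had one).
#' @export
embed_episode <- function(support, query, target_dim = 4, n_neighbors = 99,
                          metric = "cosine", p = 2) {
  if (nrow(support) == 0L || nrow(query) == 0L) {
    abort("`support` and `query` must both be non-empty.")
  }
  xs <- fs_feature_matrix(support, "support")
  xq <- fs_feature_matrix(query, "query")
  if (ncol(xs) != ncol(xq)) abort("support and query feature dimensions differ.")
  Y <- laplacian_eigenmap(rbind(xs, xq), target_dim, n_neighbors, metric, p)
  mk <- function(rows, src) {
    res <- as_tibble(unclass(Y)[rows, , drop = FALSE])
    colnames(res) <- colnames(Y)
    if ("label" %in% names(src)) res$label <- src$label
    res
  }
  list(support = mk(seq_len(nrow(xs)), support),
       query = mk(nrow(xs) + seq_len(nrow(xq)), query),
       n_neighbors = attr(Y, "n_neighbors"))
}
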