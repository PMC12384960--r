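#' Sample an N-way K-shot episode from a labeled bank
#'
#' Draws `n_way` classes without replacement, then per class `k_shot`
#' support and `n_query` query samples without replacement, so support
#' and query rows are disjoint.
#'
#' @param bank Data frame with numeric feature columns and a `label`
#'   column.
#' @param n_way Number of classes per episode (N).
#' @param k_shot Labeled samples per class (K).
#' @param n_query Query samples per class.
#' @param seed Optional integer seed; when given, sampling is wrapped in
#'   a local RNG state so the caller's stream is untouched.
#' @return List of tibbles `support` and `query`, both with `label`.
#' @examples
#' bank <- generate_clusters(n_classes = 5, per_class = 20, seed = 1)
#' ep <- sample_episode(bank, n_way = 5, k_shot = 1, n_query = 15, seed = 2)
#' nrow(ep$support); nrow(ep$query)  # 5, 75
#' @export
sample_episode <- function(bank, n_way, k_shot, n_query, seed = NULL) {
  if (n_way < 2 || k_shot < 1 || n_query < 1) {
    abort("need n_way >= 2, k_shot >= 1, n_query >= 1.")
  }
  lab <- as.character(fs_labels(bank, arg = "bank"))
  classes <- sort(unique(lab))
  if (length(classes) < n_way) {
    abort(sprintf("bank has %d classes; %d requested.", length(classes), n_way))
  }
  counts <- table(lab)
  if (any(counts < k_shot + n_query)) {
    abort("every class needs at least k_shot + n_query samples.")
  }
  draw <- function() {
    chosen <- sample(classes, n_way)
    idx <- purrr::map(chosen, function(cl) {
      rows <- which(lab == cl)
      picked <- sample(rows, k_shot + n_query)
      list(sup = picked[seq_len(k_shot)], qry = picked[k_shot + seq_len(n_query)])
    })
    list(support = bank[unlist(purrr::map(idx, "sup")), , drop = FALSE],
         query = bank[unlist(purrr::map(idx, "qry")), , drop = FALSE])
  }
  ep <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ep$support <- as_tibble(ep$support)
  ep$query <- as_tibble(ep$query)
  ep
}

#' k-nearest-neighbour baseline classifier
#'
#' Majority vote over the `k` nearest support samples under the chosen
#' metric; vote ties (and distance ties) break to the smallest class
#' index in sorted-label order.  With `k = 1` this is the brute-force
#' nearest-neighbour oracle that the adapted neural-field classifier is
#' expected to reproduce on generic inputs.
#'
#' @param support Data frame of embedded support samples with `label`.
#' @param query Data frame of embedded queries.
#' @param k Number of neighbours (>= 1, at most the support size).
#' @param metric,p Distance metric.
#' @return Factor of predicted labels, one per query row.
#' @export
predict_knn <- function(support, query, k = 1, metric = "euclidean", p = 2) {
  y <- fs_labels(support, arg = "support")
  xs <- fs_feature_matrix(support, "support")
  xq <- fs_feature_matrix(query, "query")
  if (k < 1) abort("`k` must be at least 1.")
  if (k > nrow(xs)) abort("`k` exceeds the number of support samples.")
  D <- cross_distance(xq, xs, metric, p)
  idx <- apply(D, 1, function(d) order(d)[seq_len(k)])
  idx <- matrix(idx, nrow = k)
  pred <- apply(idx, 2, function(nb) {
    votes <- tabulate(as.integer(y)[nb], nbins = nlevels(y))
    which.max(votes)  # first max = smallest class index on ties
  })
  factor(levels(y)[pred], levels = levels(y))
}

#' Evaluate the classifier over many episodes
#'
#' Runs the full per-episode pipeline — sample an episode, jointly embed
#' support and queries with Laplacian Eigenmaps (optional), fit the
#' neural-field model on the support, predict every query with
#' independent scale adaptation — and aggregates accuracy over
#' `n_episodes` episodes (600 by default, the standard averaging
#' protocol).  A 1-nearest-neighbour baseline is scored in the same
#' embedded space for comparison, together with its per-query agreement
#' with the field classifier.
#'
#' Episode `i` uses seed `seed + i`, so the whole evaluation is
#' reproducible from the single master seed.
#'
#' @param bank Labeled feature bank (numeric columns + `label`).
#' @param n_way,k_shot,n_query Episode shape (defaults 5-way, 1-shot,
#'   15 queries per class).
#' @param n_episodes Number of episodes to average (default 600).
#' @param reduce Embed each episode with [embed_episode()] first
#'   (default `TRUE`); set `FALSE` to classify in the raw feature space.
#' @param target_dim,n_neighbors Laplacian-Eigenmaps settings.  The
#'   neighbour count must exceed the episode's per-class size (or the
#'   graph disconnects when classes are compact) and stay well below the
#'   episode size (or the graph is complete and carries no geometry).
#'   The default `NULL` uses `k_shot + n_query + 1`, the smallest
#'   neighbourhood that is guaranteed to bridge compact classes.
#' @param metric,p Distance metric used for the embedding graph and,
#'   enforced to be identical, for the classifier.
#' @param lambda,max_iter,eps Scale-adaptation settings (see
#'   [fieldshot()]).
#' @param compare_knn Also score the 1-NN baseline (default `TRUE`).
#' @param seed Master seed (episode `i` runs at `seed + i`).
#' @return A `fieldshot_eval` object: per-episode tibble in `$episodes`
#'   (accuracy, baseline accuracy and agreement, mean adaptation
#'   iterations, seed) and the configuration snapshot in `$config`.
#'   Use [tidy()], [glance()], [autoplot()] on it.
#' @export
evaluate_episodes <- function(bank, n_way = 5, k_shot = 1, n_query = 15,
                              n_episodes = 600, reduce = TRUE, target_dim = 4,
                              n_neighbors = NULL, metric = "cosine", p = 2,
                              lambda = 0.5, max_iter = 100L, eps = 0,
                              compare_knn = TRUE, seed = 1) {
  if (n_episodes < 1) abort("`n_episodes` must be at least 1.")
  metric <- match.arg(metric, fs_metrics)
  n_neighbors <- n_neighbors %||% (k_shot + n_query + 1L)
  rows <- vector("list", n_episodes)
  for (i in seq_len(n_episodes)) {
    ep_seed <- seed + i
    ep <- sample_episode(bank, n_way, k_shot, n_query, seed = ep_seed)
    if (reduce) {
      emb <- embed_episode(ep$support, ep$query, target_dim = target_dim,
                           n_neighbors = n_neighbors, metric = metric, p = p)
      sup <- emb$support; qry <- emb$query
    } else {
      sup <- ep$support; qry <- ep$query
    }
    # the classifier inherits the embedding-graph metric by construction
    model <- fieldshot(sup, metric = metric, p = p, lambda = lambda,
                       max_iter = max_iter, eps = eps)
    pred <- predict(model, qry)
    truth <- as.character(ep$query$label)
    acc <- mean(as.character(pred$.pred) == truth)
    knn_acc <- NA_real_; knn_agree <- NA_real_
    if (compare_knn) {
      knn <- predict_knn(sup, qry, k = 1, metric = metric, p = p)
      knn_acc <- mean(as.character(knn) == truth)
      knn_agree <- mean(as.character(knn) == as.character(pred$.pred))
    }
    rows[[i]] <- tibble(episode = i, seed = ep_seed, accuracy = acc,
                        knn_accuracy = knn_acc, knn_agreement = knn_agree,
                        mean_iterations = mean(pred$iterations),
                        max_iterations = max(pred$iterations))
  }
  structure(
    list(episodes = dplyr::bind_rows(rows),
         config = list(n_way = n_way, k_shot = k_shot, n_query = n_query,
                       n_episodes = n_episodes, reduce = reduce,
                       target_dim = target_dim, n_neighbors = n_neighbors,
                       metric = metric, p = p, lambda = lambda,
                       max_iter = max_iter, eps = eps, seed = seed)),
    class = "fieldshot_eval"
  )
}

#' @export
print.fieldshot_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fieldshot_eval> %d-way %d-shot, %d episodes (metric: %s)\n",
    x$config$n_way, x$config$k_shot, x$config$n_episodes, x$config$metric))
  cat(sprintf("  mean accuracy %.4f (se %.4f)", g$mean_accuracy, g$se_accuracy))
  if (!is.na(g$knn_accuracy)) {
    cat(sprintf(" | 1-NN baseline %.4f | agreement %.4f",
                g$knn_accuracy, g$knn_agreement))
  }
  cat("\n")
  invisible(x)
}
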