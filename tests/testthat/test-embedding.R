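test_that("identity extractor passes numeric features through; contract violations error", {
  dat <- tibble::tibble(a = 1:10, b = rnorm(10), label = rep(c("x", "y"), 5))
  f1 <- extract_features(dat)
  expect_identical(dim(as.matrix(f1[c("f1", "f2")])), c(10L, 2L))
  expect_equal(unname(as.matrix(f1[c("f1", "f2")])),
               unname(as.matrix(dat[c("a", "b")])))
  expect_identical(f1$label, dat$label)
  expect_identical(extract_features(dat), f1)  # deterministic
  expect_error(extract_features(dat, "no_such_plugin"), "unknown extractor")
  register_extractor("ragged", function(d) lapply(seq_len(nrow(d)), seq_len))
  expect_error(extract_features(dat, "ragged"), "ragged")
})

test_that("pairwise distances satisfy the metric identities", {
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance(c(1, 0), c(0, 1), "cosine"), 1)
  expect_equal(pairwise_distance(c(1, 2, 3), c(2, 4, 6), "cosine"), 0)
  expect_equal(pairwise_distance(c(1, 2, 3), c(5, 7, 9), "correlation"), 0)
  expect_equal(pairwise_distance(c(0, 0), c(2, 2), "minkowski", p = 1), 4)
  set.seed(9)
  for (i in 1:25) {
    x <- rnorm(5); y <- rnorm(5); z <- rnorm(5)
    for (mtr in c("euclidean", "cosine", "correlation", "minkowski")) {
      expect_equal(pairwise_distance(x, x, mtr), 0, tolerance = 1e-7)
      expect_equal(pairwise_distance(x, y, mtr), pairwise_distance(y, x, mtr))
      expect_gte(pairwise_distance(x, y, mtr), 0)
    }
    # triangle inequality for the norm-induced metrics only
    for (mtr in c("euclidean", "minkowski")) {
      expect_lte(pairwise_distance(x, z, mtr),
                 pairwise_distance(x, y, mtr) + pairwise_distance(y, z, mtr) + 1e-12)
    }
  }
  expect_error(pairwise_distance(c(0, 0), c(1, 1), "cosine"), "zero")
  expect_error(pairwise_distance(c(2, 2), c(1, 3), "correlation"), "constant")
  expect_error(pairwise_distance(1, c(1, 2)), "equal length")
})

test_that("a three-point path embeds monotonically in one dimension", {
  Y <- laplacian_eigenmap(matrix(c(0, 1, 2)), target_dim = 1, n_neighbors = 1,
                          metric = "euclidean")
  expect_identical(dim(Y), c(3L, 1L))
  expect_true(all(diff(Y[, 1]) > 0) || all(diff(Y[, 1]) < 0))
  # sign fixing: largest-magnitude entry is positive
  expect_gt(Y[which.max(abs(Y[, 1])), 1], 0)
})

test_that("embedding has the right shape, caps the neighbour count, and drops the constant eigenvector", {
  set.seed(14)
  x <- matrix(rnorm(30 * 6), ncol = 6)
  Y <- laplacian_eigenmap(x, target_dim = 4, n_neighbors = 99,
                          metric = "euclidean")
  expect_identical(dim(Y), c(30L, 4L))
  expect_identical(attr(Y, "n_neighbors"), 29L)      # min(99, n - 1)
  expect_true(all(apply(Y, 2, stats::sd) > 1e-10))   # no constant column
})

test_that("two far clusters bipartition cleanly along the first spectral coordinate", {
  for (s in c(4, 5, 6)) {
    bank <- generate_clusters(n_classes = 2, per_class = 20, dim = 3,
                              separation = 30, spread = 1, seed = s)
    bank <- bank[-(1:5), ]   # unequal sizes: 15 vs 20
    y <- laplacian_eigenmap(fieldshot:::fs_feature_matrix(bank),
                            target_dim = 1, n_neighbors = 16,
                            metric = "euclidean")[, 1]
    lab <- as.integer(bank$label)
    # strict bipartition: the clusters occupy disjoint intervals
    expect_true(max(y[lab == 1]) < min(y[lab == 2]) ||
                  max(y[lab == 2]) < min(y[lab == 1]))
    # and leave-one-out 1-NN in the embedding is perfect
    D <- abs(outer(y, y, "-")); diag(D) <- Inf
    expect_identical(mean(lab[apply(D, 1, which.min)] == lab), 1)
  }
})

test_that("embedding is invariant to row order up to the sign rule", {
  set.seed(8)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  perm <- sample(40)
  Y1 <- laplacian_eigenmap(x, target_dim = 3, n_neighbors = 8, metric = "euclidean")
  Y2 <- laplacian_eigenmap(x[perm, ], target_dim = 3, n_neighbors = 8,
                           metric = "euclidean")
  expect_equal(unclass(Y2)[order(perm), ], unclass(Y1), tolerance = 1e-6,
               ignore_attr = TRUE)
  # and identical on re-run
  Y3 <- laplacian_eigenmap(x, target_dim = 3, n_neighbors = 8, metric = "euclidean")
  expect_identical(Y1, Y3)
})

test_that("a disconnected neighbour graph is rejected with advice", {
  fix <- degenerate_cases()$disconnected_graph
  expect_error(
    laplacian_eigenmap(fieldshot:::fs_feature_matrix(fix$bank),
                       target_dim = 2, n_neighbors = fix$n_neighbors,
                       metric = "euclidean"),
    "increase `n_neighbors`",
    class = "fieldshot_disconnected_graph")
})

test_that("episodes are embedded jointly and split by role", {
  bank <- generate_clusters(n_classes = 5, per_class = 20, dim = 4,
                            separation = 10, spread = 0.5, seed = 2)
  ep <- sample_episode(bank, 5, 1, 15, seed = 3)
  emb <- embed_episode(ep$support, ep$query, target_dim = 4, n_neighbors = 17,
                       metric = "cosine")
  expect_identical(dim(as.matrix(emb$support[paste0("dim", 1:4)])), c(5L, 4L))
  expect_identical(nrow(emb$support), 5L)
  expect_identical(nrow(emb$query), 75L)
  expect_identical(emb$support$label, ep$support$label)
  # neighbour cap applies to the pooled set
  emb2 <- embed_episode(ep$support, ep$query, target_dim = 2, n_neighbors = 99)
  expect_identical(emb2$n_neighbors, 79L)
  # deterministic
  emb3 <- embed_episode(ep$support, ep$query, target_dim = 4, n_neighbors = 17,
                        metric = "cosine")
  expect_identical(emb3$support, emb$support)
  expect_error(embed_episode(ep$support[0, ], ep$query), "non-empty")
})
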