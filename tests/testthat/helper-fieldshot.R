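# Random few-shot instances used across property tests.  All generators
# draw from the session RNG; callers fix the seed.

# Random embedded support set: n_classes clusters of k_shot points with
# continuous coordinates, so all pairwise distances are distinct almost
# surely ("generic" instances).
random_support <- function(n_classes = sample(2:10, 1),
                           k_shot = sample(1:5, 1),
                           dim = sample(2:8, 1),
                           scale = 3) {
  centers <- matrix(rnorm(n_classes * dim, sd = scale), ncol = dim)
  x <- centers[rep(seq_len(n_classes), each = k_shot), , drop = FALSE] +
    matrix(rnorm(n_classes * k_shot * dim, sd = 0.5), ncol = dim)
  list(positions = x,
       labels = rep(seq_len(n_classes), each = k_shot),
       n_classes = n_classes, k_shot = k_shot, dim = dim)
}

support_tibble <- function(inst) {
  out <- tibble::as_tibble(inst$positions, .name_repair = ~ paste0("x", seq_along(.x)))
  out$label <- sprintf("c%02d", inst$labels)
  out
}

# Brute-force oracle: index of the class with the smallest minimum
# distance from the query to its supports (ties to smallest index).
nearest_class <- function(positions, labels, query, metric = "euclidean", p = 2) {
  d <- vapply(seq_len(nrow(positions)), function(i) {
    pairwise_distance(positions[i, ], query, metric, p)
  }, numeric(1))
  cmin <- vapply(sort(unique(labels)), function(j) min(d[labels == j]), numeric(1))
  which.min(cmin)
}

# Brute-force radius rule: classes with at least one support strictly
# inside the kernel's zero-crossing radius of the query.
classes_in_radius <- function(positions, labels, query, sigma1,
                              metric = "euclidean", p = 2) {
  r <- zero_crossing_radius(sigma1)
  d <- vapply(seq_len(nrow(positions)), function(i) {
    pairwise_distance(positions[i, ], query, metric, p)
  }, numeric(1))
  which(vapply(sort(unique(labels)), function(j) min(d[labels == j]) < r,
               logical(1)))
}

# Well-separated one-shot instance with a probe near class 1, the regime
# in which the static approximation is derived (distant classes).
separated_probe_instance <- function() {
  n <- sample(3:6, 1)
  d <- sample(2:4, 1)
  X <- fieldshot:::random_means(n, d, 8)
  dir <- rnorm(d); dir <- dir / sqrt(sum(dir^2))
  probe <- X[1, ] + dir * runif(1, 0.2, 1.2)
  sigma <- sigma_from_z(runif(1, 1.5, 2.5))
  list(X = X, probe = probe, sigma = sigma, n = n, dim = d)
}
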