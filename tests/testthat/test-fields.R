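test_that("Hebbian connections have the label-indicator structure", {
  expect_equal(hebbian_connections(c(1, 1, 2), 2),
               rbind(c(1, 1, 0), c(0, 0, 1)))
  expect_equal(hebbian_connections(rep(1, 4), 1), matrix(1, 1, 4))
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    lab <- sample(n, n * sample(1:5, 1), replace = TRUE)
    lab[seq_len(n)] <- seq_len(n)  # no empty classes
    W <- hebbian_connections(lab, n)
    expect_equal(colSums(W), rep(1, length(lab)))
    expect_equal(rowSums(W), as.vector(tabulate(lab, n)))
  }
  expect_error(hebbian_connections(c(1, 3), 2), "out of range")
  expect_error(hebbian_connections(c(1, 1), 2), "no samples")
})

test_that("static elementary response composes kernel and nonlinearities", {
  kp <- kernel_params(1)
  X <- rbind(c(0, 0), c(10, 0))
  u <- static_elementary_response(X, c(0, 0), kp)
  expect_equal(u[1], eta(phi(1)))                       # ~0.4686 at the probe
  expect_equal(u[1], 0.4686, tolerance = 1e-3)
  expect_equal(u[2], eta(kernel_profile(10, kp) * phi(1)))
  expect_equal(u[2], -0.0012, tolerance = 5e-2)
  # zero exactly at the detection radius
  r <- zero_crossing_radius(1)
  u0 <- static_elementary_response(rbind(c(r, 0)), c(0, 0), kp)
  expect_equal(u0, 0, tolerance = 1e-9)
  expect_error(static_elementary_response(X, c(0, 0, 0), kp), "dimension")
})

test_that("static high-level response gates classes through phi", {
  W <- hebbian_connections(c(1, 1, 2), 2)
  v <- static_highlevel_response(c(0.47, -0.001, 0), W)
  expect_equal(v, c(phi(phi(0.47)), 0))
  expect_equal(v[1], 0.312, tolerance = 5e-3)
  expect_equal(static_highlevel_response(c(-1, 0, -0.2), W), c(0, 0))
  # two in-radius samples of one class drive the class harder than one
  W1 <- hebbian_connections(c(1, 2), 2)
  W2 <- hebbian_connections(c(1, 1, 2), 2)
  v1 <- static_highlevel_response(c(0.4, -0.1), W1)
  v2 <- static_highlevel_response(c(0.4, 0.4, -0.1), W2)
  expect_gt(v2[1], v1[1])
})

test_that("lateral high-level fixed point converges and reduces to the feedforward answer for distant classes", {
  kp <- kernel_params(0.5)
  pos <- rbind(c(0, 0), c(50, 0))       # far apart: lateral term negligible
  W <- hebbian_connections(c(1, 2), 2)
  u <- c(0.5, -0.2)
  ff <- static_highlevel_response(u, W)
  vl <- static_highlevel_response(u, W, class_positions = pos, params_v = kp,
                                  lateral = TRUE)
  # self-excitation raises the active class; the inactive one stays near 0
  expect_gt(vl[1], ff[1])
  expect_equal(vl[2], ff[2], tolerance = 1e-6)
  expect_error(static_highlevel_response(u, W, lateral = TRUE), "required")
})

test_that("activated set is the strictly-positive-drive set", {
  expect_identical(activated_classes(c(0.4, 0)), 1L)
  expect_identical(activated_classes(c(0, 0)), integer(0))
  expect_identical(activated_classes(c(0.2, 0.1)), c(1L, 2L))
  expect_identical(activated_classes(c(0.2, 0.1), eps = 0.15), 1L)
  expect_error(activated_classes(c(0.1), eps = -1), "non-negative")
})

test_that("zero input is a fixed point and a lateral-free neuron relaxes to its input", {
  kp <- kernel_params(1)
  X <- matrix(rnorm(6), ncol = 2)
  elem <- elementary_field(X, 0, kp)
  high <- highlevel_field(matrix(rnorm(4), ncol = 2), 0, kp)
  sol <- integrate_fields(elem, high, matrix(1 / 3, 2, 3))
  expect_true(sol$converged)
  expect_equal(sol$u, rep(0, 3), tolerance = 1e-7)
  expect_equal(sol$v, rep(0, 2), tolerance = 1e-7)
  # single driven neuron without lateral interaction: tau u' = e - u, u* = e = 1
  elem1 <- elementary_field(matrix(0, 1, 1), 1, params = NULL)
  high1 <- highlevel_field(matrix(0, 1, 1), 0, params = NULL)
  sol1 <- integrate_fields(elem1, high1, matrix(0, 1, 1), tol = 1e-10)
  expect_true(sol1$converged)
  expect_equal(sol1$u, 1, tolerance = 1e-8)
})

test_that("Euler integration guards its preconditions", {
  kp <- kernel_params(1)
  elem <- elementary_field(matrix(0, 1, 1), 1, kp, tau = 1)
  high <- highlevel_field(matrix(0, 1, 1), 0, kp, tau = 1)
  expect_error(integrate_fields(elem, high, matrix(0, 1, 1), dt = 1.5), "dt")
  expect_error(integrate_fields(elem, high, matrix(0, 2, 1)), "n x m")
  expect_error(elementary_field(matrix(0, 1, 1), 2, kp), "binary")
  expect_error(elementary_field(matrix(0, 1, 1), 1, kp, tau = -1), "positive")
})

test_that("dynamic steady state reproduces the static activation ranking for distant classes", {
  set.seed(11)
  for (i in 1:10) {
    inst <- separated_probe_instance()
    kp <- kernel_params(inst$sigma)
    W <- hebbian_connections(seq_len(inst$n), inst$n)
    u_s <- static_elementary_response(inst$X, inst$probe, kp)
    v_s <- static_highlevel_response(u_s, W)
    elem <- elementary_field(rbind(inst$X, inst$probe),
                             c(rep(0, inst$n), 1), kp)
    high <- highlevel_field(inst$X, 0, kp, lateral_enabled = TRUE)
    sol <- integrate_fields(elem, high, cbind(W, 0))
    expect_true(sol$converged)
    expect_lt(sol$residual, 1e-8)
    act_s <- which(v_s > 0)
    act_d <- which(sol$v > 1e-6)
    expect_setequal(act_d, act_s)
    expect_identical(act_d[order(-sol$v[act_d])], act_s[order(-v_s[act_s])])
  }
})
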