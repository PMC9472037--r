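test_that("acyclicity value matches closed forms", {
  expect_equal(acyclicity_value(matrix(0, 3, 3)), 0)
  # strictly upper-triangular support is nilpotent under the Hadamard square
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- runif(6, -2, 2)
  expect_equal(acyclicity_value(W), 0, tolerance = 1e-12)
  # 2-cycle with unit weights: trace(exp([[0,1],[1,0]])) = 2 cosh(1)
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(acyclicity_value(W2), 2 * cosh(1) - 2, tolerance = 1e-10)
  expect_error(acyclicity_value(matrix(0, 2, 3)), "square")
})

test_that("a fully forbidden mask returns an exactly zero matrix", {
  set.seed(31)
  X <- matrix(rnorm(100 * 3), 100, 3)
  mask <- matrix(TRUE, 3, 3)
  W <- notears_fit(X, notears_options(forbidden_mask = mask))
  expect_identical(unname(W[, ]), matrix(0, 3, 3))
})

test_that("a masked 2-node problem recovers the OLS coefficient", {
  labs <- c("A", "B")
  Wt <- matrix(0, 2, 2, dimnames = list(labs, labs))
  Wt["A", "B"] <- 0.8
  spec <- sem_spec(Wt)
  X <- as.matrix(simulate_trips(spec, 2000, seed = 32))
  mask <- matrix(FALSE, 2, 2); mask[2, 1] <- TRUE  # forbid B -> A
  # small L1 so the free entry tracks the least-squares solution
  W <- notears_fit(X, notears_options(lambda1 = 0.01,
                                      forbidden_mask = mask))
  ols <- unname(coef(lm(X[, "B"] ~ X[, "A"]))[2])
  expect_identical(W["B", "A"], 0)            # mask is exact
  expect_equal(W["A", "B"], 0.8, tolerance = 0.05 / 0.8)
  expect_equal(W["A", "B"], ols, tolerance = 0.03 / ols)
})

test_that("independent data yield an empty thresholded graph", {
  W0 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  spec <- sem_spec(W0)
  for (s in 1:10) {
    X <- as.matrix(simulate_trips(spec, 1000, seed = 300 + s))
    W <- notears_fit(X, notears_options(lambda1 = 0.1))
    expect_lt(max(abs(W)), 0.3)
    expect_equal(n_edges(threshold_graph(W, 0.3)), 0)
  }
})

test_that("the fit satisfies the constraint and respects the mask bitwise", {
  spec <- generate_sem_spec(list(preset = "random", n_nodes = 6,
                                 n_edges = 6), seed = 33)
  X <- as.matrix(simulate_trips(spec, 1000, seed = 34))
  mask <- matrix(FALSE, 6, 6)
  mask[1, ] <- TRUE   # node 1 may have no outgoing edges
  W <- notears_fit(X, notears_options(forbidden_mask = mask))
  expect_lte(attr(W, "h"), 1e-8)
  expect_true(all(W[1, ] == 0))
  expect_true(all(diag(W) == 0))
  # the thresholded support is acyclic by construction
  expect_s3_class(threshold_graph(W, 0.3), "causal_dag")
})

test_that("threshold_graph prunes exactly the sub-threshold weights", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  W["x", "y"] <- 0.5; W["y", "z"] <- 0.2
  g <- threshold_graph(W, 0.3)
  expect_equal(n_edges(g), 1)
  expect_equal(dag_edges(g)$weight, 0.5)
  expect_equal(n_edges(threshold_graph(W, 0.6)), 0)
  g0 <- threshold_graph(W, 0)
  expect_equal(n_edges(g0), 2)
})

test_that("structural Hamming distance counts flips, gains and losses once", {
  A <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  A[1, 2] <- 1; B[2, 1] <- 1          # reversal: 1
  A[1, 3] <- 1                        # extra edge: 1
  B[2, 3] <- 1                        # missing edge: 1
  expect_equal(structural_hamming_distance(A, B), 3)
  expect_equal(structural_hamming_distance(A, A), 0)
})

test_that("nonconvergence raises a typed error carrying the best iterate", {
  set.seed(35)
  X <- matrix(rnorm(200 * 3), 200, 3)
  X[, 2] <- X[, 1] + rnorm(200, sd = 0.3)
  cnd <- tryCatch(
    notears_fit(X, notears_options(rho_max = 1, h_tol = 1e-14,
                                   max_outer = 2)),
    tripcausal_nonconvergence = function(c) c)
  expect_s3_class(cnd, "tripcausal_nonconvergence")
  expect_true(is.matrix(cnd$W))
})

test_that("temporal forbidden set implements the stage ordering", {
  cats <- c(after_arousal = "emotion_after",
            before_arousal = "emotion_before",
            sun = "predetermined", steering = "behavior",
            weekend = "predetermined", length = "trip_factor")
  forb <- temporal_forbidden_set(cats)
  key <- paste(forb$from, forb$to)
  expect_true("after_arousal before_arousal" %in% key)
  expect_false("sun before_arousal" %in% key)
  expect_true("steering weekend" %in% key)       # nothing causes predetermined
  expect_true("steering before_arousal" %in% key)
  expect_true("length before_arousal" %in% key)
  expect_false("before_arousal steering" %in% key)
  expect_error(temporal_forbidden_set(c(a = "nope")), "unknown categories")
})
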