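test_that("k-NN graph on collinear points matches hand enumeration and symmetrizes by union", {
  X <- matrix(c(0, 1, 3, 6), ncol = 1)
  W <- unclass(build_knn_graph(X, 1))
  # nearest neighbours: 0->1, 1->0, 3->1, 6->3; union keeps 1-3 and 3-6
  expected <- matrix(Inf, 4, 4)
  diag(expected) <- 0
  expected[1, 2] <- expected[2, 1] <- 1
  expected[2, 3] <- expected[3, 2] <- 2
  expected[3, 4] <- expected[4, 3] <- 3
  expect_equal(W, expected)
})

test_that("k = n-1 yields the complete graph with Euclidean weights", {
  set.seed(5)
  X <- matrix(rnorm(24), 8, 3)
  W <- unclass(build_knn_graph(X, 7))
  expect_equal(W, as.matrix(dist(X)), ignore_attr = TRUE)
  expect_error(build_knn_graph(X, 8), "k must lie")
  expect_error(build_knn_graph(X, 0), "k must lie")
})

test_that("duplicate points create zero-weight edges but no self-loops", {
  X <- matrix(c(0, 0, 5), ncol = 1)
  W <- unclass(build_knn_graph(X, 1))
  expect_equal(W[1, 2], 0)
  expect_equal(diag(W), rep(0, 3))
  expect_false(any(is.infinite(diag(W))))
})

test_that("shortest paths accumulate along a path graph and flag disconnection", {
  W <- matrix(Inf, 4, 4); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 2; W[3, 4] <- W[4, 3] <- 3
  D <- shortest_paths(W)
  expect_equal(D[1, 4], 6)
  expect_true(attr(D, "connected"))
  W2 <- matrix(Inf, 4, 4); diag(W2) <- 0
  W2[1, 2] <- W2[2, 1] <- 1; W2[3, 4] <- W2[4, 3] <- 1
  D2 <- shortest_paths(W2)
  expect_false(attr(D2, "connected"))
  expect_true(is.infinite(D2[1, 3]))
})

test_that("Floyd-Warshall agrees with exhaustive path enumeration on small graphs", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(3:7, 1)
    W <- random_graph(n)
    expect_equal(unclass(shortest_paths(W)), bf_shortest_paths(W),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("classical MDS reproduces the two-point hand case with the sign convention", {
  D <- matrix(c(0, 2, 2, 0), 2, 2)
  emb <- classical_mds(D, 1)
  expect_equal(drop(emb$points), c(1, -1))
  expect_equal(emb$eigenvalues[1], 2)
})

test_that("classical MDS is exact on Euclidean distances and matches cmdscale", {
  set.seed(6)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  emb <- classical_mds(D, 2)
  expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(colMeans(emb$points), c(0, 0), tolerance = 1e-9)
  # independent implementation: distances must agree with stats::cmdscale
  ref <- stats::cmdscale(D, k = 2)
  expect_equal(as.matrix(dist(emb$points)), as.matrix(dist(ref)),
               tolerance = 1e-8)
  # equilateral triangle, side 1
  tri <- matrix(1, 3, 3) - diag(3)
  emb3 <- classical_mds(tri, 2)
  expect_equal(as.vector(dist(emb3$points)), rep(1, 3), tolerance = 1e-8)
})

test_that("requesting more dimensions than positive eigenvalues pads with zeros", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  expect_warning(emb <- classical_mds(as.matrix(dist(X)), 2), "positive")
  expect_equal(emb$points[, 2], rep(0, 3))
})

test_that("Isomap preserves gaps on collinear data and geodesics bound Euclidean distances", {
  X <- matrix(c(0, 1, 3, 6), ncol = 1)
  emb <- isomap(X, 2, 1)
  expect_equal(as.matrix(dist(emb$points)), as.matrix(dist(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  roll <- fixture_suite()$swissroll200
  er <- isomap(roll, 8, 2)
  expect_true(all(er$geodesic - as.matrix(dist(roll)) >= -1e-9))
})

test_that("Isomap raises a typed condition on disconnected graphs", {
  tc <- fixture_suite()$twoclusters
  err <- tryCatch(isomap(tc$points, 1, 2), isoga_disconnected = function(e) e)
  expect_s3_class(err, "isoga_disconnected")
  expect_equal(sort(err$component_sizes, decreasing = TRUE)[1:2] >= 1,
               c(TRUE, TRUE))
})

test_that("embedding distances are invariant to translating the input", {
  set.seed(9)
  X <- matrix(rnorm(30), 15, 2)
  d1 <- dist(isomap(X, 4, 2)$points)
  d2 <- dist(isomap(X + 100, 4, 2)$points)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-8)
})

test_that("intrinsic-dimension estimates recover planted dimension", {
  set.seed(3)
  square <- matrix(runif(1000), 500, 2)
  expect_equal(estimate_intrinsic_dim(square), 2L)
  line <- cbind(runif(300), matrix(0, 300, 9))
  expect_equal(estimate_intrinsic_dim(line), 1L)
  tiny <- matrix(rnorm(20), 10, 2)
  d <- estimate_intrinsic_dim(tiny, neighbor_range = c(3, 3))
  expect_true(is.numeric(d) && d >= 1)
  expect_lte(estimate_intrinsic_dim(square, max_dim = 1), 1L)
  dup <- matrix(1, 10, 2)
  expect_error(suppressWarnings(estimate_intrinsic_dim(dup)), "duplicates")
})

test_that("k tuning returns the feasible argmin and clips the grid", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
  y <- rep(1:2, each = 20)
  k <- tune_k(X, y, d = 2)
  scores <- attr(k, "scores")
  feasible <- scores[scores$connected & is.finite(scores$db), ]
  expect_true(as.integer(k) %in% 5:20)
  expect_equal(min(feasible$db), feasible$db[feasible$k == as.integer(k)])
  # n = 15: the default 5..20 grid must clip to 5..14
  X15 <- matrix(rnorm(30), 15, 2)
  k15 <- tune_k(X15, rep(1:3, each = 5), d = 1)
  expect_equal(range(attr(k15, "scores")$k), c(5, 14))
  # widely separated clusters: every small k disconnected -> error
  tc <- fixture_suite()$twoclusters
  expect_error(tune_k(tc$points, tc$labels, d = 2, k_range = 5:14),
               "disconnected")
})
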