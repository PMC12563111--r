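test_that("neighbour search matches hand cases and the brute-force oracle", {
  pts <- cbind(c(0, 1, 3), 0)
  g <- find_neighbors(pts, 2)
  expect_equal(g[2, ], c(1L, 3L))   # distances 1 and 2
  expect_equal(g[1, ], c(2L, 3L))

  # duplicated points are nearest at distance zero
  dup <- rbind(c(1, 1), c(1, 1), c(5, 5), c(9, 9))
  expect_equal(find_neighbors(dup, 2)[1, 1], 2L)
  expect_equal(find_neighbors(dup, 2)[2, 1], 1L)

  set.seed(21)
  cloud <- matrix(rnorm(150), 50, 3)
  for (p in c(2, 5, 10))
    expect_equal(unname(find_neighbors(cloud, p)),
                 unname(oracle_knn(cloud, p)))

  expect_error(find_neighbors(cloud, 50), "more points")
  expect_error(find_neighbors(cloud, 1), ">= 2")
})

test_that("reconstruction weights are row-stochastic and optimal", {
  # midway point: equal weights
  pts <- rbind(c(0, 0), c(2, 0), c(1, 0.5), c(10, 10), c(-10, 10))
  g <- find_neighbors(pts, 2)
  W <- solve_weights(pts, g)
  expect_equal(as.numeric(W[3, 1:2]), c(0.5, 0.5), tolerance = 1e-6)

  # coincident with one neighbour: that weight ~1
  pts2 <- rbind(c(1, 1), c(1, 1), c(4, 0), c(0, 4), c(8, 8))
  W2 <- solve_weights(pts2, find_neighbors(pts2, 3))
  expect_gt(W2[1, 2], 0.99)

  set.seed(22)
  cloud <- matrix(rnorm(90), 30, 3)
  g <- find_neighbors(cloud, 5)
  W <- solve_weights(cloud, g)
  expect_lt(max(abs(Matrix::rowSums(W) - 1)), 1e-8)
  expect_lte(max(tabulate(Matrix::which(W != 0, arr.ind = TRUE)[, 1])), 5)

  # optimality: no random feasible affine combination does better
  re_opt <- reconstruction_error(cloud, W)
  for (rep in 1:20) {
    Wr <- Matrix::sparseMatrix(
      i = rep(1:30, each = 5), j = as.vector(t(g)),
      x = as.vector(apply(matrix(runif(150), 30), 1, function(r) r / sum(r))),
      dims = c(30, 30))
    expect_gte(reconstruction_error(cloud, Wr) + 1e-9, re_opt)
  }
})

test_that("the embedding matrix is PSD with a near-null constant mode", {
  set.seed(23)
  cloud <- matrix(rnorm(240), 80, 3)
  W <- solve_weights(cloud, find_neighbors(cloud, 5))
  M <- crossprod(diag(80) - as.matrix(W))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  expect_gt(min(ev$values), -1e-10)              # PSD
  expect_lt(abs(ev$values[80]), 1e-8)            # ~0 eigenvalue
  v1 <- ev$vectors[, 80]
  expect_lt(sd(v1) / abs(mean(v1)), 1e-4)        # near-constant mode
})

test_that("planar embedding matches a dense eigendecomposition oracle", {
  pc <- generate_known_system("plane_cloud", list(n = 150, jitter = 0.02),
                              seed = 5)
  W <- solve_weights(pc$points, find_neighbors(pc$points, 6))
  emb <- embed_2d(W)
  M <- crossprod(diag(150) - as.matrix(W))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  for (j in 1:2) {
    v <- ev$vectors[, 150 - j]
    v <- v - mean(v); v <- v / sqrt(sum(v^2))
    if (v[which(abs(v) > 0)[1]] < 0) v <- -v
    expect_lt(max(abs(emb$points[, j] - v)), 1e-8)
    expect_equal(emb$eigenvalues_used[j], ev$values[150 - j], tolerance = 1e-8)
  }
  # structural invariants of the embedding
  expect_lt(max(abs(colMeans(emb$points))), 1e-10)
  expect_equal(colSums(emb$points^2), c(1, 1), tolerance = 1e-10)
})

test_that("dense and sparse eigen paths agree on a separated spectrum", {
  pc <- generate_known_system("plane_cloud", list(n = 300, jitter = 0.01),
                              seed = 3)
  W <- solve_weights(pc$points, find_neighbors(pc$points, 6))
  dense <- embed_2d(W, dense_cutoff = 512)
  sparse <- embed_2d(W, dense_cutoff = 100)
  expect_lt(max(abs(dense$points - sparse$points)), 1e-7)
})

test_that("a planar cloud is recovered up to an affine map", {
  pc <- generate_known_system("plane_cloud", list(n = 200, jitter = 1e-6),
                              seed = 2)
  emb <- lle_embed(pc$points, p = 6)
  expect_lt(procrustes_residual(emb$points, pc$uv), 0.05)
})

test_that("weights are invariant to rigid motions and runs are deterministic", {
  set.seed(24)
  cloud <- matrix(rnorm(180), 60, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- cloud %*% Q + matrix(rep(c(5, -3, 2), each = 60), 60)
  W1 <- solve_weights(cloud, find_neighbors(cloud, 5))
  W2 <- solve_weights(moved, find_neighbors(moved, 5))
  expect_lt(max(abs(W1 - W2)), 1e-8)

  e1 <- lle_embed(cloud, p = 5)
  e2 <- lle_embed(cloud, p = 5)
  expect_identical(e1$points, e2$points)   # bit-identical reruns
  e3 <- lle_embed(moved, p = 5)
  agree <- abs(colSums(e1$points * e3$points))
  expect_equal(agree, c(1, 1), tolerance = 1e-5)  # same axes up to sign
})

test_that("neighbour-count scan reports consistent errors and exact plane data", {
  set.seed(25)
  cloud <- matrix(rnorm(120), 40, 3)
  scan <- select_neighbor_count(cloud, p_range = 2:8)
  expect_identical(scan$re_curve$p, 2:8)
  # the curve is reproducible from the returned weights
  for (p in c(3, 6)) {
    W <- solve_weights(cloud, find_neighbors(cloud, p))
    expect_equal(scan$re_curve$re[scan$re_curve$p == p],
                 reconstruction_error(cloud, W), tolerance = 1e-10)
  }
  expect_identical(scan$best_p, scan$re_curve$p[which.min(scan$re_curve$re)])

  # exact plane data are affine-reconstructible: RE hits the numerical
  # floor once the ridge is negligible, and even at the default ridge it
  # sits far below that of a generic 3-D cloud
  pc <- generate_known_system("plane_cloud", list(n = 60, jitter = 0), seed = 9)
  scan2 <- select_neighbor_count(pc$points, p_range = 3:8, reg = 1e-8)
  expect_lt(max(scan2$re_curve$re), 1e-9)
  scan3 <- select_neighbor_count(pc$points, p_range = 3:8)
  cloud_re <- reconstruction_error(cloud,
                                   solve_weights(cloud, find_neighbors(cloud, 4)))
  expect_lt(max(scan3$re_curve$re), 0.1 * cloud_re)
  expect_error(select_neighbor_count(cloud, p_range = 2:40), "more points")
})
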