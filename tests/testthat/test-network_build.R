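test_that("streamline containers validate input and measure arc length", {
  expect_error(streamline_set(list(matrix(0, 1, 3))), ">= 2 points")
  expect_error(streamline_set(list(matrix(c(0, 0, 0, 1, 1, Inf), 2,
                                          byrow = TRUE))), "finite")
  sl <- streamline_set(list(rbind(c(0, 0, 0), c(0, 0, 4)),
                            rbind(c(0, 0, 0), c(1, 1, 0), c(1, 1, 2))))
  expect_equal(streamline_lengths(sl), c(4, sqrt(2) + 2))
})

test_that("fibers are tallied per parcel pair exactly as hand-enumerated", {
  tal <- count_fibers(toy_streamlines(), three_parcel_fixture())
  expect_equal(tal$n_discarded, 1L)
  expect_equal(tal$n_intra, 1L)
  expect_equal(nrow(tal$fibers), 12L)
  cnt <- table(paste(tal$fibers$i, tal$fibers$j))
  expect_equal(as.vector(cnt[c("1 2", "1 3", "2 3")]), c(10L, 1L, 1L))
  expect_equal(sort(tal$fibers$length[tal$fibers$i == 1 & tal$fibers$j == 2]),
               c(3, 3, 3, 3, 4, 4, 4, 4, 5, 5))
})

test_that("edge weights reproduce the hand-computed values and the fiber cutoff", {
  tal <- count_fibers(toy_streamlines(), three_parcel_fixture())
  sizes <- c(3, 3, 3)
  # threshold 10: only pair (1,2), with 10 fibers, survives
  C10 <- structural_network(tal, sizes, threshold = 10)
  w12 <- 2 / 6 * (4 / 3 + 4 / 4 + 2 / 5)
  expect_equal(C10$W[1, 2], w12)
  expect_equal(C10$W[1, 3], 0)  # 1 fiber < 10
  expect_equal(C10$W[2, 3], 0)
  # threshold 1: every pair weighted by the displayed formula
  C1 <- structural_network(tal, sizes, threshold = 1)
  expect_equal(C1$W[1, 2], w12)
  expect_equal(C1$W[1, 3], 2 / 6 * (1 / 8))
  expect_equal(C1$W[2, 3], 2 / 6 * 1)
  expect_equal(C1$W, t(C1$W))
  expect_equal(diag(C1$W), rep(0, 3))
  # alternative normalization: count / (mean size x mean length)
  Cm <- structural_network(tal, sizes, threshold = 1,
                           normalization = "mean_length")
  expect_equal(Cm$W[1, 2], 10 / (3 * 3.8))
  expect_equal(Cm$W[2, 3], 1 / (3 * 1))
})

test_that("a single fiber produces the textbook weight", {
  p <- fake_parcellation(rep(1:2, each = 2), dim = c(4, 1, 1), idx0 = 0:3)
  sl <- streamline_set(list(rbind(c(0, 0, 0), c(2, 0, 0))))
  tal <- count_fibers(sl, p)
  C <- structural_network(tal, c(10, 10), threshold = 1)
  expect_equal(C$W[1, 2], (2 / 20) * (1 / 2))  # = 0.05
})

test_that("structural weights scale as the formula dictates", {
  tal <- count_fibers(toy_streamlines(), three_parcel_fixture())
  sizes <- c(3, 3, 3)
  C <- structural_network(tal, sizes, threshold = 1)
  tal2 <- tal; tal2$fibers$length <- 2 * tal$fibers$length
  expect_equal(structural_network(tal2, sizes, threshold = 1)$W, C$W / 2)
  expect_equal(structural_network(tal, 2 * sizes, threshold = 1)$W, C$W / 2)
  # raising the threshold never adds edges
  nz <- vapply(1:12, function(th)
    sum(structural_network(tal, sizes, threshold = th)$W > 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
  expect_error(structural_network(tal, c(0, 3, 3)), "zero-size")
})

test_that("no fibers gives the zero matrix", {
  p <- three_parcel_fixture()
  sl <- streamline_set(list(rbind(c(6, 0, 0), c(8, 0, 0))))  # intra only
  C <- structural_network(count_fibers(sl, p), c(3, 3, 3))
  expect_true(all(C$W == 0))
})

test_that("confound regression matches the normal-equations oracle", {
  set.seed(42)
  ts <- matrix(rnorm(200 * 5), 200)
  conf <- matrix(rnorm(200 * 3), 200)
  res <- regress_confounds(ts, conf)
  X <- cbind(1, conf)
  beta <- solve(t(X) %*% X, t(X) %*% ts)
  expect_equal(res, ts - X %*% beta, ignore_attr = TRUE,
               tolerance = 1e-10)
  # residuals orthogonal to every standardized confound column
  orth <- crossprod(scale(X[, -1]), res) / nrow(res)
  expect_lt(max(abs(orth)), 1e-8)
})

test_that("confound regression handles edge cases", {
  set.seed(1)
  ts <- matrix(rnorm(60 * 2), 60)
  centered <- regress_confounds(ts)
  expect_equal(colMeans(centered), c(0, 0), tolerance = 1e-12)
  expect_equal(centered, sweep(ts, 2, colMeans(ts)), ignore_attr = TRUE)
  conf <- matrix(rnorm(60), 60)
  expect_lt(max(abs(regress_confounds(conf, conf))), 1e-10)
  expect_error(regress_confounds(ts, cbind(conf, conf)), "rank deficient")
  expect_error(regress_confounds(ts[1:4, ], conf[1:4, , drop = FALSE]),
               "too few timepoints")
})

test_that("functional networks equal a direct covariance/sd oracle", {
  set.seed(7)
  node_ts <- matrix(rnorm(100 * 4), 100)
  C <- functional_network(node_ts, voxelwise = FALSE)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    ref[i, j] <- cov(node_ts[, i], node_ts[, j]) /
      (sd(node_ts[, i]) * sd(node_ts[, j]))
  diag(ref) <- 0
  expect_equal(C$W, ref, tolerance = 1e-12)
  expect_equal(diag(C$W), rep(0, 4))
})

test_that("perfect correlation and anticorrelation are recovered", {
  x <- rnorm(50)
  C <- functional_network(cbind(x, 2 * x + 3, -x), voxelwise = FALSE)
  expect_equal(C$W[1, 2], 1)
  expect_equal(C$W[1, 3], -1)
})

test_that("voxelwise FC averages parcels and is affine-invariant", {
  p <- fake_parcellation(rep(1:3, each = 3), dim = c(9, 1, 1), idx0 = 0:8)
  set.seed(11)
  ts <- matrix(rnorm(80 * 9), 80)
  C <- functional_network(ts, p)
  # oracle: average member voxels, then correlate
  node_ts <- sapply(1:3, function(k) rowMeans(ts[, p$labels == k]))
  ref <- cor(node_ts); diag(ref) <- 0
  expect_equal(C$W, ref, tolerance = 1e-12)
  expect_equal(C$node_sizes, rep(3L, 3))
  # per-voxel affine rescaling of the time series leaves Pearson FC unchanged
  ts2 <- sweep(sweep(ts, 2, runif(9, 0.5, 2), `*`), 2, rnorm(9), `+`)
  node_ts2 <- sapply(1:3, function(k) rowMeans(ts2[, p$labels == k]))
  ref2 <- cor(node_ts2); diag(ref2) <- 0
  expect_equal(functional_network(ts2, p)$W, ref2, tolerance = 1e-12)
})

test_that("zero-variance node series raise an informative error", {
  p <- fake_parcellation(rep(1:2, each = 2), dim = c(4, 1, 1), idx0 = 0:3)
  ts <- cbind(rnorm(30), rnorm(30), 1, 1)
  expect_error(functional_network(ts, p), "zero-variance.*2")
})
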