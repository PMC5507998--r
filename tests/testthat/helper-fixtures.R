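# Shared fixtures and independent oracles, all built in code.

# straight line of n face-adjacent voxels along x
line_mask <- function(n) {
  a <- array(FALSE, dim = c(n, 1, 1))
  a[] <- TRUE
  gm_mask(a)
}

# solid block mask
block_mask <- function(nx, ny = nx, nz = nx) {
  gm_mask(array(TRUE, dim = c(nx, ny, nz)))
}

# random connected sub-mask of a block, <= 300 voxels
random_small_mask <- function(seed, p = 0.6, dims = c(6, 6, 6)) {
  set.seed(seed)
  a <- array(runif(prod(dims)) < p, dim = dims)
  suppressWarnings(gm_mask(a))
}

# Floyd-Warshall all-pairs oracle on the identical weighted graph
fw_oracle <- function(graph) {
  V <- graph$n_voxels
  D <- matrix(Inf, V, V)
  diag(D) <- 0
  for (v in seq_len(V)) {
    idx <- (graph$ptr[v] + 1L):graph$ptr[v + 1L]
    D[v, graph$nbr[idx] + 1L] <- graph$wt[idx]
  }
  for (k in seq_len(V))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# number of 26-connected components of a voxel index set (1-based R linear)
n_components <- function(dim, idx1) {
  max(pbsnet:::cpp_components(dim, sort(as.integer(idx1)) - 1L))
}

# hand-made parcellation object (for stats and fiber-counting fixtures)
fake_parcellation <- function(labels, dim, idx0, seeds = NULL) {
  N <- max(labels)
  structure(list(labels = as.integer(labels),
                 seeds = if (is.null(seeds)) rep(NA_integer_, N) else seeds,
                 N = N, dim = dim, idx0 = as.integer(idx0),
                 rng_seed = NA_integer_),
            class = "parcellation")
}

# shared small shell (computed once per test run)
.fixture_env <- new.env(parent = emptyenv())
shared_shell <- function() {
  if (is.null(.fixture_env$shell)) {
    m <- synth_mask(2500, rng_seed = 5)
    g <- build_adjacency(m)
    .fixture_env$shell <- list(mask = m, graph = g)
  }
  .fixture_env$shell
}

# 3-parcel line fixture: 9 mask voxels at x = 0..8 on a 12-voxel row,
# parcels {0,1,2}, {3,4,5}, {6,7,8}, each of size 3
three_parcel_fixture <- function() {
  fake_parcellation(rep(1:3, each = 3), dim = c(12, 1, 1), idx0 = 0:8)
}

# 12 connecting streamlines with hand-enumerated pair assignments:
# 10 on pair (1,2) (lengths 3,3,3,3,4,4,4,4,5,5), one on (1,3) (length 8),
# one on (2,3) (length 1); plus one intra-parcel and one off-mask line
toy_streamlines <- function() {
  seg <- function(x1, x2) rbind(c(x1, 0, 0), c(x2, 0, 0))
  sl <- c(
    lapply(c(0, 1, 2, 0), function(x) seg(x, x + 3)),   # lengths 3
    lapply(c(0, 1, 0, 1), function(x) seg(x, x + 4)),   # lengths 4
    lapply(c(0, 0), function(x) seg(x, x + 5)),         # lengths 5
    list(seg(0, 8)),                                    # pair (1,3), length 8
    list(seg(5, 6)),                                    # pair (2,3), length 1
    list(seg(6, 8)),                                    # intra parcel 3
    list(seg(0, 10)))                                   # endpoint off mask
  streamline_set(sl, frame = "voxel")
}

# exhaustive best-modularity oracle: all set partitions of n <= 8 nodes
best_partition_Q <- function(W) {
  n <- nrow(W)
  stopifnot(n <= 8)
  k <- colSums(W); m2 <- sum(W)
  B <- W - outer(k, k) / m2
  bestQ <- -Inf
  rec <- function(i, memb, nblocks) {
    if (i > n) {
      same <- outer(memb, memb, `==`)
      q <- sum(B[same]) / m2
      if (q > bestQ) bestQ <<- q
      return(invisible())
    }
    for (b in seq_len(nblocks + 1L)) {
      memb[i] <- b
      rec(i + 1L, memb, max(nblocks, b))
    }
  }
  rec(1L, integer(n), 0L)
  bestQ
}
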