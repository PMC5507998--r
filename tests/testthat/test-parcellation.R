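test_that("farthest-point placement matches an exhaustive argmax oracle", {
  g <- build_adjacency(line_mask(10))
  L <- rep(1, 10)  # uniform density
  D <- pbs_distance(g, L, 1:10, 1:10)
  for (seed in 1:5) {
    seeds <- place_seeds(g, L, 3, rng_seed = seed)
    # oracle: recompute each subsequent seed by brute-force argmax of min D
    expect_equal(seeds[2], {
      cand <- setdiff(1:10, seeds[1])
      cand[which.max(D[seeds[1], cand])]
    })
    expect_equal(seeds[3], {
      cand <- setdiff(1:10, seeds[1:2])
      cand[which.max(pmin(D[seeds[1], cand], D[seeds[2], cand]))]
    })
  }
  # a first seed at one end sends the second seed to the opposite end
  s <- vapply(1:20, function(sd) place_seeds(g, L, 2, rng_seed = sd)[1],
              integer(1))
  first_at_end <- which(s == 1)[1]
  skip_if(is.na(first_at_end))
  expect_equal(place_seeds(g, L, 2, rng_seed = first_at_end)[2], 10)
})

test_that("seed placement is deterministic and bounded", {
  g <- build_adjacency(line_mask(10))
  L <- rep(1, 10)
  expect_identical(place_seeds(g, L, 4, 7), place_seeds(g, L, 4, 7))
  expect_error(place_seeds(g, L, 11, 1), "exceeds")
  expect_equal(sort(place_seeds(g, L, 10, 1)), 1:10)
})

test_that("growth from end seeds on a line splits it in half under both schedules", {
  g <- build_adjacency(line_mask(10))
  L <- rep(1, 10)
  for (method in c("balanced", "dijkstra")) {
    p <- grow_parcels(g, L, c(1, 10), method = method)
    expect_equal(unname(tabulate(p$labels)), c(5, 5))
    # brute-force nearest-seed oracle (ties to lower label)
    D <- pbs_distance(g, L, 1:10, c(1, 10))
    expect_equal(p$labels, apply(D, 1, which.min))
  }
})

test_that("a single seed yields one parcel covering the mask", {
  g <- build_adjacency(line_mask(6))
  L <- rep(1, 6)
  p <- grow_parcels(g, L, 3)
  expect_equal(p$labels, rep(1L, 6))
})

test_that("parcellations partition the mask into exactly N 26-connected parcels", {
  sh <- shared_shell()
  for (seed in 1:3) {
    p <- random_parcellation(sh$mask, 25, rng_seed = seed, graph = sh$graph)
    expect_equal(sort(unique(p$labels)), 1:25)
    expect_equal(length(p$labels), sh$graph$n_voxels)
    sizes <- tabulate(p$labels, nbins = 25)
    expect_equal(sum(sizes), sh$graph$n_voxels)
    for (k in seq_len(25))
      expect_equal(n_components(p$dim, p$idx0[p$labels == k] + 1L), 1L)
    expect_equal(p$labels[p$seeds], 1:25)  # each parcel contains its seed
  }
})

test_that("identical inputs reproduce a parcellation exactly; different seeds differ", {
  sh <- shared_shell()
  p1 <- random_parcellation(sh$mask, 20, rng_seed = 9, graph = sh$graph)
  p2 <- random_parcellation(sh$mask, 20, rng_seed = 9, graph = sh$graph)
  p3 <- random_parcellation(sh$mask, 20, rng_seed = 10, graph = sh$graph)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$seeds, p2$seeds)
  expect_gt(sum(p1$labels != p3$labels), 0)
})

test_that("N equal to the voxel count makes every voxel a seed", {
  m <- line_mask(8)
  p <- random_parcellation(m, 8, rng_seed = 1)
  expect_equal(sort(unique(p$labels)), 1:8)
  expect_equal(tabulate(p$labels), rep(1L, 8))
})

test_that("pbs_sample is reproducible and uses consecutive seeds", {
  m <- line_mask(30)
  e1 <- pbs_sample(m, 4, 3, base_seed = 11)
  e2 <- pbs_sample(m, 4, 3, base_seed = 11)
  expect_length(e1, 3)
  for (i in 1:3) {
    expect_identical(e1[[i]]$labels, e2[[i]]$labels)
    expect_equal(e1[[i]]$rng_seed, 11L + i - 1L)
  }
})

test_that("parcel-size statistics match direct computations", {
  p <- fake_parcellation(rep(1:3, c(100, 120, 150)), dim = c(370, 1, 1),
                         idx0 = 0:369)
  st <- parcel_size_stats(p)
  expect_equal(st$nmv_pct, 50)   # (150 - 100) / 100
  expect_equal(st$mean, mean(c(100, 120, 150)))
  p_eq <- fake_parcellation(rep(1:3, each = 10), dim = c(30, 1, 1),
                            idx0 = 0:29)
  st_eq <- parcel_size_stats(p_eq)
  expect_equal(st_eq$sd_mean_pct, 0)
  expect_equal(st_eq$nmv_pct, 0)
  # IQR/median against an independent sort-based quantile oracle
  sizes <- 1:100
  p100 <- fake_parcellation(rep(seq_along(sizes), sizes),
                            dim = c(sum(sizes), 1, 1),
                            idx0 = seq_len(sum(sizes)) - 1L)
  st100 <- parcel_size_stats(p100)
  qs <- sort(sizes)
  qat <- function(prob) {  # type-7 linear interpolation, written out
    h <- (length(qs) - 1) * prob
    lo <- floor(h)
    qs[lo + 1] + (h - lo) * (qs[lo + 2] - qs[lo + 1])
  }
  expect_equal(st100$iqr_median, (qat(0.75) - qat(0.25)) / qat(0.5))
})

test_that("parcel sizes stay homogeneous on a smooth shell", {
  sh <- shared_shell()
  L <- local_density(sh$graph, sh$graph$n_voxels %/% 50L)
  ratios <- vapply(1:5, function(seed) {
    p <- random_parcellation(sh$mask, 50, rng_seed = seed,
                             graph = sh$graph, density = L)
    parcel_size_stats(p)$sd_mean_pct
  }, numeric(1))
  expect_lt(median(ratios), 15)
})
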