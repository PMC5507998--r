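#' Place parcellation seeds by farthest-point sampling
#'
#' The first seed is drawn uniformly from the mask voxels using
#' `rng_seed`; every subsequent seed is placed deterministically at the
#' voxel maximising the minimum density-weighted distance D to all seeds
#' already placed (farthest-point sampling under D). Argmax ties are
#' broken toward the lowest linear voxel index so that a given
#' (mask, N, rng_seed) always yields the same seed list.
#'
#' @param graph a [build_adjacency()] graph.
#' @param density a [local_density()] field for `graph`.
#' @param N number of seeds (2 <= N <= number of voxels; N = 1 allowed
#'   for the trivial single-parcel case).
#' @param rng_seed integer seed for the first-voxel draw.
#' @return integer vector of N distinct 1-based node indices in
#'   placement order.
#' @export
place_seeds <- function(graph, density, N, rng_seed) {
  stopifnot(inherits(graph, "voxel_graph"),
            length(density) == graph$n_voxels)
  N <- as.integer(N)
  if (N < 1L) stop("N must be at least 1")
  if (N > graph$n_voxels) stop("N exceeds the number of mask voxels")
  set.seed(as.integer(rng_seed))
  first <- sample.int(graph$n_voxels, 1L)
  cpp_place_seeds(graph$ptr, graph$nbr, graph$wt, density,
                  first - 1L, N) + 1L
}

#' Grow parcels around seeds
#'
#' Iterative growing of voxel neighbourhoods around the seeds, in the
#' density-weighted distance D. Two schedules are available:
#' \describe{
#'   \item{`"balanced"` (default)}{regions take turns in label order;
#'     on its turn a region claims the unassigned frontier voxel with
#'     the smallest D from its seed (accumulated along the growth
#'     tree). Growing by equal voxel increments keeps parcel sizes
#'     nearly equal; the residual size variation comes from regions
#'     that get walled in by their neighbours and stop early.}
#'   \item{`"dijkstra"`}{all fronts propagate simultaneously ordered by
#'     D; each voxel joins the first front that reaches it (ties to the
#'     lower seed label). On a uniform density field this is exact
#'     multi-source Dijkstra, i.e. nearest-seed assignment under D;
#'     parcel sizes then vary with the local geometry of the seed
#'     configuration.}
#' }
#' Under both schedules every voxel attaches through an
#' already-labelled 26-neighbour, so each parcel is 26-connected and
#' contains its seed, and the labels partition the mask.
#'
#' @inheritParams place_seeds
#' @param seeds distinct 1-based node indices (from [place_seeds()]).
#' @param method growth schedule, `"balanced"` or `"dijkstra"`.
#' @param rng_seed optional, recorded in the result for provenance.
#' @return an object of class `parcellation`: integer `labels` (one per
#'   mask voxel, values 1..N in seed placement order), `seeds`, `N`,
#'   `dim`, `idx0`, `rng_seed`.
#' @export
grow_parcels <- function(graph, density, seeds,
                         method = c("balanced", "dijkstra"),
                         rng_seed = NA_integer_) {
  stopifnot(inherits(graph, "voxel_graph"),
            length(density) == graph$n_voxels)
  method <- match.arg(method)
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (any(seeds < 1L | seeds > graph$n_voxels)) stop("seed index out of range")
  labels <- if (method == "balanced")
    cpp_grow_balanced(graph$ptr, graph$nbr, graph$wt, density, seeds - 1L)
  else
    cpp_grow(graph$ptr, graph$nbr, graph$wt, density, seeds - 1L)
  new_parcellation(labels, seeds, graph, rng_seed)
}

new_parcellation <- function(labels, seeds, graph, rng_seed) {
  structure(
    list(labels = labels, seeds = seeds, N = length(seeds),
         dim = graph$dim, idx0 = graph$idx0,
         rng_seed = as.integer(rng_seed)),
    class = "parcellation")
}

#' Generate one random parcellation of a mask
#'
#' Full pipeline for a single pseudo-bootstrap sample: build the voxel
#' adjacency graph, compute the local-density field with M = floor(V/N)
#' (the expected parcel size), place N seeds by randomized-first
#' farthest-point sampling, and grow parcels. Pass a precomputed `graph`
#' and `density` when generating many parcellations of the same mask at
#' the same N; only seed placement and growth are then repeated.
#'
#' @param mask a [gm_mask()].
#' @param N number of parcels.
#' @param rng_seed integer seed; identical (mask, N, rng_seed) gives an
#'   identical parcellation.
#' @param graph optional precomputed [build_adjacency()] graph.
#' @param density optional precomputed [local_density()] field at
#'   M = floor(V/N).
#' @param method growth schedule, see [grow_parcels()].
#' @return a `parcellation` (see [grow_parcels()]).
#' @export
random_parcellation <- function(mask, N, rng_seed, graph = NULL,
                                density = NULL,
                                method = c("balanced", "dijkstra")) {
  if (is.null(graph)) graph <- build_adjacency(mask)
  N <- as.integer(N)
  if (N < 1L) stop("N must be at least 1")
  if (N > graph$n_voxels) stop("N exceeds the number of mask voxels")
  if (N == graph$n_voxels) {
    # every voxel its own parcel: seeds in random order, labels by seed rank
    set.seed(as.integer(rng_seed))
    seeds <- sample.int(graph$n_voxels)
    labels <- integer(graph$n_voxels)
    labels[seeds] <- seq_len(N)
    return(new_parcellation(labels, seeds, graph, rng_seed))
  }
  if (is.null(density)) {
    M <- max(1L, graph$n_voxels %/% N)
    density <- local_density(graph, M)
  }
  seeds <- place_seeds(graph, density, N, rng_seed)
  grow_parcels(graph, density, seeds, method = method, rng_seed = rng_seed)
}

#' Pseudo-bootstrap parcellation ensemble
#'
#' `count` independent random parcellations of one mask with RNG seeds
#' `base_seed, base_seed + 1, ...` — the PBS sampling scheme: each
#' parcellation is one resample of the same underlying data. The graph
#' and density field are computed once and shared.
#'
#' @inheritParams random_parcellation
#' @param count ensemble size (the reference analyses use 400).
#' @param base_seed integer; the i-th parcellation uses rng_seed
#'   `base_seed + i - 1`.
#' @param method growth schedule, see [grow_parcels()].
#' @return list of `parcellation` objects, class `pbs_ensemble`.
#' @export
pbs_sample <- function(mask, N, count, base_seed,
                       method = c("balanced", "dijkstra")) {
  count <- as.integer(count)
  if (count < 1L) stop("count must be at least 1")
  graph <- build_adjacency(mask)
  N <- as.integer(N)
  density <- if (N < graph$n_voxels)
    local_density(graph, max(1L, graph$n_voxels %/% N)) else NULL
  method <- match.arg(method)
  out <- vector("list", count)
  for (i in seq_len(count))
    out[[i]] <- random_parcellation(mask, N, rng_seed = base_seed + i - 1L,
                                    graph = graph, density = density,
                                    method = method)
  class(out) <- "pbs_ensemble"
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels over %d voxels (rng_seed %s)\n",
              x$N, length(x$labels),
              ifelse(is.na(x$rng_seed), "unset", x$rng_seed)))
  invisible(x)
}

#' Convert a parcellation to a 3D label array
#' @param x a `parcellation`.
#' @param ... unused.
#' @return integer 3D array; background voxels are 0.
#' @export
as.array.parcellation <- function(x, ...) {
  vol <- array(0L, dim = x$dim)
  vol[x$idx0 + 1L] <- x$labels
  vol
}

#' Parcel-size homogeneity statistics
#'
#' Summaries of the parcel-size multiset used to judge how equal-sized a
#' random parcellation is: SD-to-mean ratio (in %), inter-quartile range
#' to median ratio (quartiles by linear interpolation, quantile type 7),
#' and the normalized maximum variation NMV = (max - min)/min x 100%.
#'
#' @param p a `parcellation`.
#' @return list of class `parcel_size_stats`: `sizes`, `mean`, `sd`,
#'   `sd_mean_pct`, `median`, `iqr`, `iqr_median`, `nmv_pct`.
#' @export
parcel_size_stats <- function(p) {
  stopifnot(inherits(p, "parcellation"))
  sizes <- tabulate(p$labels, nbins = p$N)
  if (any(sizes == 0L)) stop("parcellation has empty labels")
  q <- quantile(sizes, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(sizes = sizes,
         mean = mean(sizes), sd = sd(sizes),
         sd_mean_pct = 100 * sd(sizes) / mean(sizes),
         median = q[2], iqr = q[3] - q[1],
         iqr_median = (q[3] - q[1]) / q[2],
         nmv_pct = 100 * (max(sizes) - min(sizes)) / min(sizes)),
    class = "parcel_size_stats")
}

#' @export
print.parcel_size_stats <- function(x, ...) {
  cat(sprintf(
    "parcel sizes: mean %.1f +/- %.1f voxels (sd/mean %.2f%%), IQR/median %.3f, NMV %.1f%%\n",
    x$mean, x$sd, x$sd_mean_pct, x$iqr_median, x$nmv_pct))
  invisible(x)
}
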