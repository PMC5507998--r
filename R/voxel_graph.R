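#' Build the weighted voxel adjacency graph of a mask
#'
#' Mask voxels become graph nodes (ordered by ascending linear index);
#' every pair of 26-adjacent voxels is joined by an edge whose weight is
#' the lattice step length: 1 for a shared face, sqrt(2) for a shared
#' edge ("side"), sqrt(3) for a shared vertex. Geodesic distances on this
#' graph are the shortest-path lengths restricted to the gray matter,
#' measured in voxel-edge units.
#'
#' @param mask a [gm_mask()].
#' @return an object of class `voxel_graph`: compressed sparse row
#'   adjacency (`ptr`, `nbr`, `wt`; `ptr`/`nbr` 0-based for the compiled
#'   backend), `n_voxels`, the mask `dim`, `idx0` and 0-based voxel
#'   `coords`.
#' @export
build_adjacency <- function(mask) {
  stopifnot(inherits(mask, "gm_mask"))
  if (length(mask$idx0) == 0L) stop("empty mask")
  adj <- cpp_build_adjacency(mask$dim, mask$idx0)
  structure(
    list(ptr = adj$ptr, nbr = adj$nbr, wt = adj$wt,
         n_voxels = length(mask$idx0), dim = mask$dim,
         idx0 = mask$idx0, coords = mask_coords(mask)),
    class = "voxel_graph")
}

#' @export
print.voxel_graph <- function(x, ...) {
  cat(sprintf("voxel_graph: %d voxels, %d undirected edges\n",
              x$n_voxels, length(x$nbr) %/% 2L))
  invisible(x)
}

#' Geodesic distances between mask voxels
#'
#' Exact single-source shortest-path (Dijkstra) lengths in the weighted
#' voxel graph, i.e. geodesic distances G(i,j) restricted to the mask.
#'
#' @param graph a [build_adjacency()] graph.
#' @param sources integer vector of 1-based node indices (mask voxels in
#'   `idx0` order).
#' @param targets 1-based node indices, or `NULL` for all voxels.
#' @return numeric matrix `length(sources)` x `length(targets)`;
#'   unreachable targets are `Inf` (with a warning).
#' @export
geodesic_distance <- function(graph, sources, targets = NULL) {
  stopifnot(inherits(graph, "voxel_graph"))
  sources <- as.integer(sources)
  if (length(sources) == 0L) stop("sources must be nonempty")
  if (any(sources < 1L | sources > graph$n_voxels))
    stop("source index out of range")
  d <- cpp_geodesic_rows(graph$ptr, graph$nbr, graph$wt, sources - 1L)
  if (!is.null(targets)) {
    targets <- as.integer(targets)
    if (any(targets < 1L | targets > graph$n_voxels))
      stop("target index out of range")
    d <- d[, targets, drop = FALSE]
  }
  if (any(is.infinite(d)))
    warning("some targets are unreachable from the sources; distance Inf")
  dimnames(d) <- NULL
  d
}

#' Local density field L(i)
#'
#' For every mask voxel i, L(i) is the sum of the geodesic distances to
#' its M nearest mask voxels (the M smallest nonzero shortest-path
#' lengths, computed exactly by truncated Dijkstra; ties at the M-th
#' distance are resolved toward the lowest linear voxel index). M is
#' normally the expected parcel size floor(V/N). Densely packed cortex
#' has small L; thin strands and mask boundaries have large L. L divides
#' the geodesic distance in the parcellation metric so that growth is
#' slowed where voxels are crowded and sped up where they are sparse,
#' equalising parcel sizes.
#'
#' @param graph a [build_adjacency()] graph.
#' @param M positive integer, number of nearest voxels summed.
#' @return numeric vector of length `n_voxels`, all entries > 0.
#' @export
local_density <- function(graph, M) {
  stopifnot(inherits(graph, "voxel_graph"))
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M <= 0L) stop("M must be a positive integer")
  if (M >= graph$n_voxels) stop("mask must contain more than M voxels")
  cpp_local_density(graph$ptr, graph$nbr, graph$wt, M)
}

#' Density-weighted parcellation distance D(i,j)
#'
#' D(i,j) = 2 G(i,j) / (L(i) + L(j)): the geodesic distance between two
#' voxels divided by the mean of their local path-length sums. Pairs in
#' dense cortex (small L) are effectively farther apart, so seeds spread
#' into dense regions and fronts grow more slowly there.
#'
#' @param graph a [build_adjacency()] graph.
#' @param density a [local_density()] field for `graph`.
#' @param i,j 1-based node indices (vectors allowed).
#' @return numeric matrix `length(i)` x `length(j)` of D values.
#' @export
pbs_distance <- function(graph, density, i, j) {
  stopifnot(inherits(graph, "voxel_graph"),
            length(density) == graph$n_voxels)
  if (any(density <= 0)) stop("density values must be positive")
  G <- geodesic_distance(graph, i, j)
  Lsum <- outer(density[as.integer(i)], density[as.integer(j)], `+`)
  2 * G / Lsum
}
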