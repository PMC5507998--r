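#' Streamline sets
#'
#' A `streamline_set` is a list of polylines (numeric matrices with 3
#' columns, one row per point, at least 2 points each) tagged with the
#' coordinate frame they live in. The package consumes tractography; it
#' does not compute it. Structural-network construction requires
#' streamlines co-registered with the parcellation, in continuous voxel
#' coordinates (0-based, so that a point at a voxel's grid coordinate is
#' at that voxel's centre).
#'
#' @param points list of n_m x 3 numeric matrices.
#' @param frame coordinate frame tag, `"voxel"` or `"mm"`.
#' @return an object of class `streamline_set`.
#' @export
streamline_set <- function(points, frame = c("voxel", "mm")) {
  frame <- match.arg(frame)
  points <- lapply(points, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L || nrow(p) < 2L)
      stop("each streamline needs >= 2 points with 3 coordinates")
    if (!all(is.finite(p))) stop("streamline coordinates must be finite")
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  # endpoints and arc lengths cached once; reused for every parcellation
  ends <- t(vapply(points, function(p) c(p[1, ], p[nrow(p), ]), numeric(6)))
  lens <- vapply(points, function(p) {
    seg <- diff(p)
    sum(sqrt(rowSums(seg^2)))
  }, numeric(1))
  structure(list(points = points, frame = frame,
                 endpoints = ends, lengths = lens),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("streamline_set: %d streamlines (%s frame)\n",
              length(x$points), x$frame))
  invisible(x)
}

#' Polyline arc lengths of streamlines
#' @param sl a [streamline_set()].
#' @return numeric vector, one arc length per streamline.
#' @export
streamline_lengths <- function(sl) {
  stopifnot(inherits(sl, "streamline_set"))
  sl$lengths
}

#' Assign streamlines to parcel pairs and tally fibers
#'
#' A streamline connects parcels (i, j), i != j, iff its two terminal
#' points fall in parcels i and j (endpoint rule: nearest-voxel lookup of
#' the two ends only). Streamlines with an endpoint outside the mask are
#' discarded and counted; streamlines with both ends in the same parcel
#' connect no pair. Fiber length is the polyline arc length.
#'
#' @param sl a [streamline_set()] in voxel coordinates, co-registered
#'   with `p` (alignment is the caller's job).
#' @param p a `parcellation`.
#' @return object of class `fiber_tally`: data.frame `fibers` with
#'   columns `i`, `j` (parcel pair, i < j) and `length`; `n_nodes`;
#'   `n_discarded` (endpoint off mask); `n_intra` (both ends in one
#'   parcel).
#' @export
count_fibers <- function(sl, p) {
  stopifnot(inherits(sl, "streamline_set"), inherits(p, "parcellation"))
  if (sl$frame != "voxel")
    stop("streamlines must be in voxel coordinates co-registered with the parcellation")
  vol <- as.array(p)
  ends <- sl$endpoints
  lab_at <- function(xyz) {
    ijk <- round(xyz) + 1  # nearest voxel, 0-based coords -> R index
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= p$dim[1] &
          ijk[, 2] >= 1 & ijk[, 2] <= p$dim[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= p$dim[3]
    lab <- integer(nrow(ijk))
    lab[ok] <- vol[ijk[ok, , drop = FALSE]]
    lab
  }
  la <- lab_at(ends[, 1:3, drop = FALSE])
  lb <- lab_at(ends[, 4:6, drop = FALSE])
  off  <- la == 0L | lb == 0L
  intra <- !off & la == lb
  keep <- !off & !intra
  len <- streamline_lengths(sl)
  fibers <- data.frame(i = pmin(la[keep], lb[keep]),
                       j = pmax(la[keep], lb[keep]),
                       length = len[keep])
  structure(list(fibers = fibers, n_nodes = p$N,
                 n_discarded = sum(off), n_intra = sum(intra)),
            class = "fiber_tally")
}

#' Structural connectivity matrix from fiber tallies
#'
#' Edge weight between nodes i and j:
#' \deqn{w_{ij} = \frac{2}{n_i + n_j} \sum_m \frac{1}{L_{ij}^m}}
#' where n_i is the voxel count of node i and L_ij^m the arc length of
#' the m-th fiber connecting the pair — fiber count normalized by node
#' volume and penalised by fiber length. Pairs connected by fewer than
#' `threshold` fibers (default 10) are set to 0 to suppress spurious
#' fibers. `normalization = "mean_length"` instead divides the fiber
#' count by the mean node volume and the mean fiber length of the pair,
#' an alternative reading of the same normalization.
#'
#' @param fibers a [count_fibers()] tally.
#' @param node_sizes integer vector of voxel counts per node (all > 0).
#' @param threshold minimum fiber count for a nonzero edge.
#' @param normalization `"harmonic"` (the displayed formula above,
#'   default) or `"mean_length"`.
#' @return a `connectivity_matrix` of kind `"structural"`: symmetric,
#'   nonnegative, zero diagonal.
#' @export
structural_network <- function(fibers, node_sizes, threshold = 10,
                               normalization = c("harmonic", "mean_length")) {
  stopifnot(inherits(fibers, "fiber_tally"))
  normalization <- match.arg(normalization)
  N <- fibers$n_nodes
  node_sizes <- as.numeric(node_sizes)
  if (length(node_sizes) != N) stop("node_sizes length must equal node count")
  if (any(node_sizes <= 0)) stop("zero-size node")
  W <- matrix(0, N, N)
  f <- fibers$fibers
  if (nrow(f) > 0) {
    grp <- split(f$length, list(i = f$i, j = f$j), drop = TRUE)
    cnt <- lengths(grp)
    grp <- grp[cnt >= threshold]
    if (length(grp) > 0) {
      ij <- do.call(rbind, lapply(strsplit(names(grp), ".", fixed = TRUE),
                                  as.integer))
      w <- if (normalization == "harmonic")
        2 / (node_sizes[ij[, 1]] + node_sizes[ij[, 2]]) *
          vapply(grp, function(l) sum(1 / l), numeric(1))
      else
        lengths(grp) / ((node_sizes[ij[, 1]] + node_sizes[ij[, 2]]) / 2 *
                          vapply(grp, mean, numeric(1)))
      W[ij] <- w
      W[ij[, c(2, 1), drop = FALSE]] <- w
    }
  }
  connectivity_matrix(W, node_sizes, kind = "structural")
}

#' Connectivity matrix container
#'
#' @param W symmetric numeric matrix with zero diagonal (structural
#'   weights >= 0; functional weights in \[-1, 1\]).
#' @param node_sizes voxel counts of the nodes.
#' @param kind `"structural"` or `"functional"`.
#' @param parcellation_id optional identifier of the generating
#'   parcellation.
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(W, node_sizes = NULL,
                                kind = c("structural", "functional"),
                                parcellation_id = NA) {
  kind <- match.arg(kind)
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("connectivity matrix must be square")
  if (max(abs(W - t(W))) > 1e-8) stop("connectivity matrix must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- NULL
  structure(list(W = W, node_sizes = node_sizes, kind = kind,
                 parcellation_id = parcellation_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix (%s): %d nodes, %d nonzero edges\n",
              x$kind, nrow(x$W), sum(x$W[upper.tri(x$W)] != 0)))
  invisible(x)
}

#' Regress confounds out of time series
#'
#' Least-squares residuals of every column of `ts` on an intercept plus
#' the confound columns (e.g. motion parameters, white-matter and CSF
#' signals). Residuals are orthogonal to every confound. With no
#' confounds the result is the mean-centred input.
#'
#' @param ts T x V numeric matrix (time by voxels or nodes).
#' @param confounds T x C numeric matrix, or `NULL` for intercept-only.
#' @return matrix of residuals, same shape as `ts`.
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  ts <- as.matrix(ts)
  if (!is.null(confounds) && nrow(as.matrix(confounds)) != nrow(ts))
    stop("confounds and time series disagree on T")
  X <- cbind(intercept = rep(1, nrow(ts)), confounds)
  if (nrow(ts) <= ncol(X) + 2L)
    stop("too few timepoints for the confound model")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    if (is.null(bad)) bad <- qx$pivot[(qx$rank + 1):ncol(X)]
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qx, ts)
}

#' Functional connectivity matrix for one parcellation
#'
#' Node time series are the means of the member-voxel series; edges are
#' Pearson correlations between node series. The diagonal is stored as 0
#' so that downstream averages run over distinct pairs only. Negative
#' correlations are retained; no Fisher transform is applied. Confounds
#' should be regressed from the voxel series first
#' (see [regress_confounds()]).
#'
#' @param ts T x V matrix of voxel series, columns in mask-voxel
#'   (`idx0`) order; or T x N of node series with `voxelwise = FALSE`.
#' @param p a `parcellation` (required when `voxelwise = TRUE`).
#' @param voxelwise whether columns of `ts` are voxels to be averaged
#'   into parcels.
#' @param parcellation_id stored in the result.
#' @return a `connectivity_matrix` of kind `"functional"`.
#' @export
functional_network <- function(ts, p = NULL, voxelwise = TRUE,
                               parcellation_id = NA) {
  ts <- as.matrix(ts)
  if (voxelwise) {
    stopifnot(inherits(p, "parcellation"))
    if (ncol(ts) != length(p$labels))
      stop("ts columns must match mask voxels")
    node_ts <- parcel_mean_series(ts, p)
    node_sizes <- tabulate(p$labels, nbins = p$N)
  } else {
    node_ts <- ts
    node_sizes <- NULL
  }
  v <- apply(node_ts, 2, sd)
  if (any(v == 0))
    stop("zero-variance node series for node(s): ",
         paste(which(v == 0), collapse = ", "))
  W <- cor(node_ts)
  connectivity_matrix(W, node_sizes, kind = "functional",
                      parcellation_id = parcellation_id)
}

# parcel-mean time series: T x V -> T x N
parcel_mean_series <- function(ts, p) {
  sums <- t(rowsum(t(ts), group = p$labels, reorder = TRUE))
  sweep(sums, 2, tabulate(p$labels, nbins = p$N), `/`)
}
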