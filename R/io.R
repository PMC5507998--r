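#' Write / read a parcellation as a NIfTI label volume
#'
#' Labels are stored as an integer volume (background 0); seeds and the
#' RNG seed travel in a JSON sidecar `<path>.json` so the round trip is
#' exact.
#'
#' @param p a `parcellation`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(p, path) {
  stopifnot(inherits(p, "parcellation"))
  RNifti::writeNifti(RNifti::asNifti(as.array(p)), path)
  side <- list(N = p$N, seeds = p$seeds, rng_seed = p$rng_seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parcellation
#' @param path NIfTI label volume written by [write_parcellation()].
#' @return for `read_parcellation`, a `parcellation`.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vol <- RNifti::readNifti(path)
  vol <- array(as.integer(round(vol)), dim = dim(vol)[1:3])
  idx0 <- which(vol > 0L) - 1L
  labels <- vol[idx0 + 1L]
  sidecar <- paste0(path, ".json")
  seeds <- NULL; rng_seed <- NA_integer_
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seeds <- as.integer(side$seeds)
    rng_seed <- as.integer(side$rng_seed)
  }
  N <- max(labels)
  if (is.null(seeds)) seeds <- rep(NA_integer_, N)
  structure(list(labels = labels, seeds = seeds, N = N,
                 dim = dim(vol), idx0 = idx0, rng_seed = rng_seed),
            class = "parcellation")
}

#' Write / read streamlines in a plain JSON point-list dialect
#'
#' Each streamline is an array of `[x, y, z]` points; the file carries
#' the coordinate frame tag. Intended for fixtures and synthetic
#' cohorts; co-registered tractography from standard tools should be
#' converted to this dialect (or to the same in-memory structure) by the
#' caller.
#'
#' @param sl a [streamline_set()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_streamlines_json <- function(sl, path) {
  stopifnot(inherits(sl, "streamline_set"))
  jsonlite::write_json(
    list(frame = sl$frame, streamlines = sl$points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_streamlines_json
#' @export
read_streamlines_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$streamlines
  if (is.array(pts)) pts <- lapply(seq_len(dim(pts)[1]),
                                   function(i) pts[i, , ])
  streamline_set(pts, frame = obj$frame)
}

#' Write / read a numeric matrix as TSV
#'
#' Plain tab-separated values without row names; a JSON sidecar records
#' connectivity-matrix metadata (kind, node sizes, parcellation id) when
#' a `connectivity_matrix` is written.
#'
#' @param x matrix or `connectivity_matrix`.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "connectivity_matrix")) {
    jsonlite::write_json(
      list(kind = x$kind, node_sizes = x$node_sizes,
           parcellation_id = x$parcellation_id),
      paste0(path, ".json"), auto_unbox = TRUE, null = "null")
    x <- x$W
  }
  write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) > 1L)
    stop("ragged TSV: line ", which(nf != nf[1])[1], " has ",
         nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  M <- matrix(as.numeric(unlist(fields)), nrow = length(lines),
              byrow = TRUE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    return(connectivity_matrix(M, node_sizes = side$node_sizes,
                               kind = side$kind,
                               parcellation_id = side$parcellation_id))
  }
  M
}

#' Write a tidy metrics table as TSV
#' @param df data.frame (e.g. from [cohort_metrics()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
read_metrics_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path)
}

#' Run manifest
#'
#' Records tool version, configuration snapshot, RNG seeds, input file
#' hashes, per-stage timings and output paths, so any result artifact is
#' regenerable from its manifest alone. Written even on failure (with an
#' error record) by the command-line driver.
#'
#' @param config named list snapshot of the run configuration.
#' @param seeds named list of RNG seeds used.
#' @param inputs character vector of input paths (hashed if readable).
#' @param outputs character vector of output paths.
#' @param timings named numeric vector of per-stage seconds.
#' @param error optional error message.
#' @param path output `.json` path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           inputs = character(), outputs = character(),
                           timings = numeric(), error = NULL) {
  hash_file <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    unname(tools::md5sum(f))
  }
  man <- list(
    tool = "pbsnet",
    version = as.character(utils::packageVersion("pbsnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = seeds,
    inputs = lapply(setNames(inputs, inputs), hash_file),
    outputs = as.list(outputs),
    timings_sec = as.list(timings),
    error = error)
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(man)
}
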