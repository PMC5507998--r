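#' Gray-matter voxel mask
#'
#' A `gm_mask` is a binary 3D volume marking the gray-matter voxels that
#' form the spatial domain of random parcellation. Parcellation requires a
#' single 26-connected voxel set, so by default construction keeps only the
#' largest 26-connected component and warns about discarded voxels
#' (seed placement and region growing are undefined across components).
#'
#' @param flags logical (or coercible) 3D array; `TRUE` marks mask voxels.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (metadata
#'   only: geodesic distances are measured in lattice units with voxel
#'   edge = 1).
#' @param connect if `TRUE` (default), reduce to the largest 26-connected
#'   component.
#' @return an object of class `gm_mask` with fields `flags` (logical array),
#'   `dim`, `voxel_size` and `idx0` (0-based linear indices of mask voxels
#'   in ascending order; linear index = x + sx*(y + sy*z) with 0-based
#'   x, y, z).
#' @export
gm_mask <- function(flags, voxel_size = c(1, 1, 1), connect = TRUE) {
  if (length(dim(flags)) != 3L)
    stop("mask must be a 3D array")
  flags <- array(as.logical(flags) & !is.na(flags), dim = dim(flags))
  idx0 <- which(flags) - 1L
  if (length(idx0) == 0L)
    stop("empty mask")
  if (connect) {
    comp <- cpp_components(dim(flags), idx0)
    if (max(comp) > 1L) {
      keep <- which.max(tabulate(comp))
      dropped <- sum(comp != keep)
      warning(sprintf(
        "mask has %d 26-connected components; keeping the largest, discarding %d voxel(s)",
        max(comp), dropped))
      idx0 <- idx0[comp == keep]
      flags[] <- FALSE
      flags[idx0 + 1L] <- TRUE
    }
  }
  structure(
    list(flags = flags, dim = dim(flags),
         voxel_size = as.numeric(voxel_size), idx0 = idx0),
    class = "gm_mask")
}

#' Read a gray-matter mask from a NIfTI volume
#'
#' Probabilistic gray-matter maps are binarised at `threshold` (default 0.5,
#' the conventional cutoff for probabilistic segmentations); already-binary
#' label volumes pass through unchanged.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param threshold probability cutoff; voxels with value > threshold enter
#'   the mask.
#' @inheritParams gm_mask
#' @return a [gm_mask()] object.
#' @export
read_gm_mask <- function(path, threshold = 0.5, connect = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  gm_mask(array(img > threshold, dim = dim(img)[1:3]),
          voxel_size = vs, connect = connect)
}

#' Write a mask as a NIfTI volume
#' @param mask a [gm_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_gm_mask <- function(mask, path) {
  stopifnot(inherits(mask, "gm_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$flags), dim = mask$dim),
                         pixdim = mask$voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.gm_mask <- function(x, ...) {
  cat(sprintf("gm_mask: %d voxels on a %s grid (voxel %s mm)\n",
              length(x$idx0), paste(x$dim, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

# 0-based (x,y,z) grid coordinates of mask voxels, in idx0 order
mask_coords <- function(mask) {
  lin <- mask$idx0
  sx <- mask$dim[1]; sy <- mask$dim[2]
  cbind(x = lin %% sx,
        y = (lin %/% sx) %% sy,
        z = lin %/% (sx * sy))
}
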