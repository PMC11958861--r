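#' Create a volume
#'
#' A volume is a 3D numeric array carrying its voxel spacing (mm per axis) as
#' an attribute. All image-valued quantities in the package (T1-like
#' intensities, BPND, DVR, tissue probabilities, masks, atlas labels,
#' predictions) are volumes on axis-aligned grids; world coordinates are
#' `index * voxel_size` with 0-based indices.
#'
#' @param values 3D numeric array.
#' @param voxel_size Numeric length-3 (or scalar, recycled), mm per axis.
#' @return A `volume` (3D array with a `voxel_size` attribute).
#' @export
as_volume <- function(values, voxel_size = c(1, 1, 1)) {
  if (is.null(dim(values))) stop("`values` must be an array", call. = FALSE)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be positive and finite on all axes", call. = FALSE)
  }
  structure(values, voxel_size = voxel_size, class = c("volume", class(values)))
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  vs <- voxel_size(x)
  cat(sprintf("<volume> %d x %d x %d voxels, %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  rng <- range(x)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Voxel spacing of a volume
#'
#' @param v A volume (or plain array, in which case spacing 1 is assumed).
#' @return Numeric length-3 vector of mm per axis.
#' @export
voxel_size <- function(v) {
  vs <- attr(v, "voxel_size")
  if (is.null(vs)) c(1, 1, 1) else vs
}

# Wrap `values` on the same grid as `v`
vol_like <- function(values, v) as_volume(values, voxel_size(v))

# strip volume class/attrs down to a plain array
vol_values <- function(v) {
  a <- unclass(v)
  attr(a, "voxel_size") <- NULL
  a
}

check_same_grid <- function(..., .what = "volumes") {
  vols <- list(...)
  d0 <- dim(vols[[1]])
  vs0 <- voxel_size(vols[[1]])
  for (v in vols[-1]) {
    if (!identical(dim(v), d0)) {
      stop(sprintf("%s must share the same grid: shapes %s vs %s", .what,
                   paste(d0, collapse = "x"), paste(dim(v), collapse = "x")),
           call. = FALSE)
    }
    if (max(abs(voxel_size(v) - vs0)) > 1e-8) {
      stop(sprintf("%s must share the same voxel size", .what), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a volume to NIfTI
#'
#' Volumes are written as double-precision NIfTI so that write/read
#' round-trips are bit-exact.
#'
#' @param v A volume.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(vol_values(v))
  RNifti::pixdim(img) <- voxel_size(v)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path Path to a NIfTI file.
#' @return A `volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[seq_len(3)]
  a <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  as_volume(a, vs)
}
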