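#' Combine tissue segments into a brain mask
#'
#' The mask is 1 where the summed gray-matter, white-matter and CSF
#' probabilities exceed `threshold`, 0 elsewhere.
#'
#' @param gm,wm,csf Tissue-probability volumes on a shared grid.
#' @param threshold Probability threshold in (0, 1); default 0.5.
#' @return Binary volume.
#' @export
combine_brain_mask <- function(gm, wm, csf, threshold = 0.5) {
  check_same_grid(gm, wm, csf, .what = "tissue segments")
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  vol_like((vol_values(gm) + vol_values(wm) + vol_values(csf) > threshold) * 1, gm)
}

# dense per-axis interpolation matrix mapping n source samples to the target
# grid: world position of target index i0 (0-based) is i0 * tv; source
# continuous index is world / sv, clamped to the source extent.
.axis_weights <- function(n, sv, m, tv, order) {
  f <- (seq_len(m) - 1) * tv / sv
  f <- pmin(pmax(f, 0), n - 1)
  W <- matrix(0, m, n)
  if (order == 0L) {
    j <- pmin(pmax(round(f), 0), n - 1) + 1
    W[cbind(seq_len(m), j)] <- 1
  } else {
    i0 <- pmin(floor(f), n - 2)
    i0 <- pmax(i0, 0)
    wfrac <- f - i0
    W[cbind(seq_len(m), i0 + 1)] <- W[cbind(seq_len(m), i0 + 1)] + (1 - wfrac)
    W[cbind(seq_len(m), i0 + 2)] <- W[cbind(seq_len(m), i0 + 2)] + wfrac
  }
  W
}

.apply_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  res <- W %*% matrix(a, d[axis], prod(d[-axis]))
  dim(res) <- c(nrow(W), d[perm[2]], d[perm[3]])
  aperm(res, order(perm))
}

#' Resample a volume to a target grid
#'
#' Separable nearest-neighbour (`order = 0`, for label volumes) or trilinear
#' (`order = 1`, for intensities) interpolation onto the grid with the given
#' voxel size and shape; world-space alignment follows the package convention
#' `world = index * voxel_size` (0-based indices), so the origin corner is
#' shared and extent is preserved up to the half-voxel border.
#'
#' @param v Source volume.
#' @param target_voxel_size Numeric length-3, mm per axis (> 0).
#' @param target_shape Integer length-3, voxels per axis (> 0).
#' @param order Interpolation degree: 0 (nearest) or 1 (trilinear).
#' @return Volume with exactly `target_shape` and `target_voxel_size`.
#' @export
resample_to_grid <- function(v, target_voxel_size, target_shape, order = 1L) {
  target_voxel_size <- rep_len(as.numeric(target_voxel_size), 3L)
  target_shape <- as.integer(rep_len(target_shape, 3L))
  if (any(target_voxel_size <= 0)) stop("`target_voxel_size` must be positive", call. = FALSE)
  if (any(target_shape <= 0)) stop("`target_shape` must be positive", call. = FALSE)
  if (!order %in% c(0L, 1L)) stop("`order` must be 0 (nearest) or 1 (trilinear)", call. = FALSE)
  sv <- voxel_size(v)
  d <- dim(v)
  out <- vol_values(v)
  for (ax in 1:3) {
    W <- .axis_weights(d[ax], sv[ax], target_shape[ax], target_voxel_size[ax], order)
    out <- .apply_axis(out, W, ax)
  }
  as_volume(out, target_voxel_size)
}

#' Compute the distribution volume ratio (DVR)
#'
#' `DVR = (BPND + 1) / (BPND[ref] + 1)`, where `BPND[ref]` is the arithmetic
#' mean of BPND over the voxels of the reference region (the cerebellum-analog
#' atlas label). The reference region has mean DVR 1 by construction when BPND
#' is constant over it.
#'
#' @param bpnd BPND volume.
#' @param atlas Integer-label volume on the same grid.
#' @param reference_label Reference-region label (default 1, the
#'   cerebellum-analog of the toy atlas).
#' @return DVR volume.
#' @export
compute_dvr <- function(bpnd, atlas, reference_label = 1L) {
  check_same_grid(bpnd, atlas, .what = "bpnd and atlas")
  ref <- vol_values(atlas) == reference_label
  if (!any(ref)) {
    stop(sprintf("reference region (label %d) is empty in the atlas", reference_label),
         call. = FALSE)
  }
  ref_mean <- mean(vol_values(bpnd)[ref])
  vol_like((vol_values(bpnd) + 1) / (ref_mean + 1), bpnd)
}

#' Apply a binary mask to a volume
#'
#' Voxels where the mask is zero are set to 0; others are unchanged.
#'
#' @param v Volume.
#' @param mask Binary volume on the same grid.
#' @return Masked volume.
#' @export
apply_mask <- function(v, mask) {
  check_same_grid(v, mask, .what = "volume and mask")
  vol_like(vol_values(v) * (vol_values(mask) != 0), v)
}

#' Normalize a T1-like volume for network input
#'
#' Divides by the `q` quantile of the within-mask intensities so inputs are
#' bounded near 1; the divisor is returned as an attribute for provenance.
#'
#' @param t1 T1-like volume.
#' @param mask Binary brain mask.
#' @param q Quantile (default 0.99).
#' @return Normalized volume with attribute `norm_divisor`.
#' @export
normalize_t1 <- function(t1, mask, q = 0.99) {
  check_same_grid(t1, mask, .what = "t1 and mask")
  vals <- vol_values(t1)[vol_values(mask) != 0]
  if (!length(vals)) stop("mask is empty", call. = FALSE)
  divisor <- stats::quantile(vals, q, names = FALSE)
  if (divisor <= 0) divisor <- 1
  out <- vol_like(vol_values(t1) / divisor, t1)
  attr(out, "norm_divisor") <- divisor
  out
}
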