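# map arbitrary integer indices onto [1, n] by mirror reflection
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- ((i - 1L) %% p + p) %% p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

#' Pad a 3D array by mirror reflection (or zeros)
#'
#' @param x 3D array or volume.
#' @param pad_lo,pad_hi Integer length-3 pad amounts per axis.
#' @param mode `"mirror"` (reflect without repeating the edge sample) or
#'   `"zero"`.
#' @return Padded plain array.
#' @export
pad_volume <- function(x, pad_lo, pad_hi, mode = c("mirror", "zero")) {
  mode <- match.arg(mode)
  d <- dim(x)
  xv <- vol_values(x)
  if (mode == "zero") {
    out <- array(0, d + pad_lo + pad_hi)
    out[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]), pad_lo[3] + seq_len(d[3])] <- xv
    return(out)
  }
  i1 <- .reflect_index(seq_len(d[1] + pad_lo[1] + pad_hi[1]) - pad_lo[1], d[1])
  i2 <- .reflect_index(seq_len(d[2] + pad_lo[2] + pad_hi[2]) - pad_lo[2], d[2])
  i3 <- .reflect_index(seq_len(d[3] + pad_lo[3] + pad_hi[3]) - pad_lo[3], d[3])
  xv[i1, i2, i3]
}

#' Plan non-overlapping output tiles for whole-volume inference
#'
#' Output windows are pairwise disjoint and exactly cover the volume grid:
#' the tile count per axis is `ceiling(axis_len / tile_output_len)` and the
#' trailing tile's output is cropped to the remainder. Input windows supply
#' the valid-padding margin with real image context: the volume is padded
#' only by the margin itself (`offset` on the low side, the rest on the high
#' side), and each tile's input window is shifted, where necessary, to lie
#' inside the padded grid — input windows may therefore overlap near the
#' trailing edge while output windows never do. This keeps inference inputs
#' inside the distribution the network was trained on (windows of actual
#' image content), rather than feeding it wide bands of synthetic padding.
#'
#' @param volume_shape Integer length-3.
#' @param tile_input_shape Integer length-3 (must be admissible for
#'   `net_cfg`); the full-scale analog is 240 x 240 x 160.
#' @param net_cfg A [network_config()].
#' @param margin Non-negative integer: trim this many voxels from each side
#'   of every tile's output and step the tiles by the trimmed length (the
#'   overlap-tile strategy for valid-padding networks, whose outputs are
#'   least reliable near the window border). Output windows remain pairwise
#'   disjoint with exact coverage; only the input windows overlap. Default 0
#'   (full network outputs are kept).
#' @return A `tile_plan`: list with `volume_shape`, `tile_input_shape`,
#'   `tile_output_shape`, `offset`, `margin`, `pad_lo`, `pad_hi` and `tiles`
#'   (tibble with 1-based `in_start_*` in the padded grid, `out_start_*` in
#'   the original grid, `crop_start_*` within the tile output, and `keep_*`
#'   output lengths).
#' @export
plan_tiles <- function(volume_shape, tile_input_shape, net_cfg, margin = 0L) {
  volume_shape <- as.integer(rep_len(volume_shape, 3L))
  tile_input_shape <- as.integer(rep_len(tile_input_shape, 3L))
  margin <- as.integer(rep_len(margin, 3L))
  os <- output_shape(net_cfg, tile_input_shape)  # errors if inadmissible
  tout <- os$output
  if (any(margin < 0) || any(2L * margin >= tout))
    stop("`margin` must be >= 0 and leave a positive kept output length", call. = FALSE)
  eff <- tout - 2L * margin          # output voxels kept per tile and axis
  offset <- (tile_input_shape - tout) %/% 2L
  ntiles <- ceiling(volume_shape / eff)
  pad_lo <- offset
  # high pad: the remaining valid margin, extended if the padded volume would
  # not admit even a single tile input window
  pad_hi <- pmax(tile_input_shape - tout - offset,
                 tile_input_shape - offset - volume_shape)
  padded <- volume_shape + pad_lo + pad_hi
  max_start <- padded - tile_input_shape + 1L
  grid <- expand.grid(t1 = seq_len(ntiles[1]) - 1L,
                      t2 = seq_len(ntiles[2]) - 1L,
                      t3 = seq_len(ntiles[3]) - 1L)
  out_start <- function(t, ax) t * eff[ax] + 1L
  # natural input start places the kept crop at the output centre; clamp the
  # window inside the padded grid so the network always sees image content
  in_start <- function(t, ax) {
    pmax(1L, pmin(out_start(t, ax) - margin[ax], max_start[ax]))
  }
  tiles <- tibble::tibble(
    tile = seq_len(nrow(grid)),
    in_start_1 = in_start(grid$t1, 1), in_start_2 = in_start(grid$t2, 2),
    in_start_3 = in_start(grid$t3, 3),
    out_start_1 = out_start(grid$t1, 1), out_start_2 = out_start(grid$t2, 2),
    out_start_3 = out_start(grid$t3, 3),
    keep_1 = pmin(eff[1], volume_shape[1] - grid$t1 * eff[1]),
    keep_2 = pmin(eff[2], volume_shape[2] - grid$t2 * eff[2]),
    keep_3 = pmin(eff[3], volume_shape[3] - grid$t3 * eff[3]))
  tiles$crop_start_1 <- tiles$out_start_1 - tiles$in_start_1 + 1L
  tiles$crop_start_2 <- tiles$out_start_2 - tiles$in_start_2 + 1L
  tiles$crop_start_3 <- tiles$out_start_3 - tiles$in_start_3 + 1L
  stopifnot(all(tiles$crop_start_1 >= 1), all(tiles$crop_start_1 + tiles$keep_1 - 1L <= tout[1]),
            all(tiles$crop_start_2 >= 1), all(tiles$crop_start_2 + tiles$keep_2 - 1L <= tout[2]),
            all(tiles$crop_start_3 >= 1), all(tiles$crop_start_3 + tiles$keep_3 - 1L <= tout[3]))
  structure(list(volume_shape = volume_shape, tile_input_shape = tile_input_shape,
                 tile_output_shape = tout, offset = offset, margin = margin,
                 pad_lo = pad_lo, pad_hi = as.integer(pad_hi),
                 n_tiles = nrow(tiles), tiles = tiles),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %s volume, %d tiles of input %s -> output %s\n",
              paste(x$volume_shape, collapse = "x"), x$n_tiles,
              paste(x$tile_input_shape, collapse = "x"),
              paste(x$tile_output_shape, collapse = "x")))
  invisible(x)
}

#' Predict a whole volume by non-overlapping tiling
#'
#' @param model A `dvr_network`.
#' @param t1 Input volume matching `plan$volume_shape`.
#' @param plan A [plan_tiles()] result for this volume shape and model config.
#' @param pad Border handling for the valid-padding margin: `"mirror"`
#'   (default) or `"zero"`.
#' @return Predicted volume on the same grid as `t1`.
#' @export
predict_volume <- function(model, t1, plan, pad = c("mirror", "zero")) {
  pad <- match.arg(pad)
  stopifnot(inherits(model, "dvr_network"), inherits(plan, "tile_plan"))
  if (!identical(as.integer(dim(t1)), plan$volume_shape))
    stop(sprintf("volume shape %s does not match plan (%s)",
                 paste(dim(t1), collapse = "x"),
                 paste(plan$volume_shape, collapse = "x")), call. = FALSE)
  padded <- pad_volume(t1, plan$pad_lo, plan$pad_hi, pad)
  tin <- plan$tile_input_shape
  out <- array(0, plan$volume_shape)
  for (i in seq_len(plan$n_tiles)) {
    tl <- plan$tiles[i, ]
    xw <- padded[tl$in_start_1:(tl$in_start_1 + tin[1] - 1L),
                 tl$in_start_2:(tl$in_start_2 + tin[2] - 1L),
                 tl$in_start_3:(tl$in_start_3 + tin[3] - 1L)]
    y <- forward(model, xw)
    out[tl$out_start_1:(tl$out_start_1 + tl$keep_1 - 1L),
        tl$out_start_2:(tl$out_start_2 + tl$keep_2 - 1L),
        tl$out_start_3:(tl$out_start_3 + tl$keep_3 - 1L)] <-
      y[tl$crop_start_1:(tl$crop_start_1 + tl$keep_1 - 1L),
        tl$crop_start_2:(tl$crop_start_2 + tl$keep_2 - 1L),
        tl$crop_start_3:(tl$crop_start_3 + tl$keep_3 - 1L)]
  }
  as_volume(out, voxel_size(t1))
}

#' Choose a tile input shape for a volume
#'
#' Per axis, picks the smallest admissible input edge whose valid-padding
#' output covers the axis in one tile; if none exists below `cap`, uses the
#' largest admissible edge not exceeding `cap` and tiles.
#'
#' @param net_cfg A [network_config()].
#' @param volume_shape Integer length-3.
#' @param cap Largest tile input edge to consider (default 96).
#' @return Integer length-3 tile input shape.
#' @export
auto_tile_input <- function(net_cfg, volume_shape, cap = 96L) {
  volume_shape <- as.integer(rep_len(volume_shape, 3L))
  cand <- integer(0); outs <- integer(0)
  for (n in seq_len(cap)) {
    if (admissible_input(net_cfg, rep(n, 3L))) {
      cand <- c(cand, n)
      outs <- c(outs, output_shape(net_cfg, rep(n, 3L))$output[1])
    }
  }
  if (!length(cand)) stop(sprintf("no admissible tile input <= %d", cap), call. = FALSE)
  vapply(volume_shape, function(L) {
    ok <- cand[outs >= L]
    if (length(ok)) min(ok) else cand[which.max(outs)]
  }, integer(1))
}

#' Predict the DVR volume of one case
#'
#' Full inference path: mask construction, T1 normalization, tile planning
#' and tiled prediction, with the brain mask applied to the output.
#'
#' @param model A `dvr_network`.
#' @param case A `phantom_case` (or externally loaded case in the same
#'   layout).
#' @param tile_input Optional tile input shape. Defaults to the patch size
#'   the model was trained with (recorded on the model by [train()]), which
#'   keeps inference windows inside the input distribution the network has
#'   seen; for untrained or externally built models, [auto_tile_input()] is
#'   used.
#' @param tile_margin Overlap-tile margin passed to [plan_tiles()]; `NULL`
#'   (default) keeps the central half of each tile output (a quarter of the
#'   output length trimmed per side), discarding the less reliable
#'   window-border outputs of the valid-padding network.
#' @param mask_threshold,normalize_quantile Preprocessing parameters (see
#'   [prepare_case()]).
#' @param pad Border handling passed to [predict_volume()].
#' @return Predicted DVR volume.
#' @export
predict_case <- function(model, case, tile_input = NULL, tile_margin = NULL,
                         mask_threshold = 0.5, normalize_quantile = 0.99,
                         pad = "mirror") {
  mask <- combine_brain_mask(case$segments$gm, case$segments$wm,
                             case$segments$csf, mask_threshold)
  t1 <- normalize_t1(apply_mask(case$t1, mask), mask, normalize_quantile)
  if (is.null(tile_input)) {
    tile_input <- if (!is.null(model$trained_patch)) {
      rep(model$trained_patch, 3L)
    } else {
      auto_tile_input(model$cfg, dim(t1))
    }
  }
  if (is.null(tile_margin)) {
    tout <- output_shape(model$cfg, tile_input)$output
    tile_margin <- tout %/% 4L
  }
  plan <- plan_tiles(dim(t1), tile_input, model$cfg, margin = tile_margin)
  apply_mask(predict_volume(model, t1, plan, pad), mask)
}
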