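#' Configuration of the 3D convolutional encoder-decoder
#'
#' A symmetric design: four valid-padding 3D convolutional layers
#' (channel ladder `encoder_filters`, stride `stride` for downsampling),
#' four transposed convolutional layers mirroring the ladder for upsampling,
#' and a final stride-1 single-channel convolutional output layer. A rectifier
#' follows every convolutional operation; `final_relu` controls whether the
#' output layer is rectified too (on by default since DVR is non-negative).
#'
#' @param encoder_filters Channel counts of the encoder layers
#'   (default 32, 64, 128, 256).
#' @param decoder_filters Channel counts of the decoder layers; must be the
#'   reverse of `encoder_filters`.
#' @param kernel Cubic kernel edge length; odd, >= 3 (default 3).
#' @param stride Down/upsampling stride of encoder/decoder layers (default 2).
#' @param in_channels Input channels (default 1, the T1 volume).
#' @param final_relu Apply the rectifier to the output layer (default TRUE).
#' @return A `network_config`.
#' @export
network_config <- function(encoder_filters = c(32, 64, 128, 256),
                           decoder_filters = rev(encoder_filters),
                           kernel = 3L, stride = 2L, in_channels = 1L,
                           final_relu = TRUE) {
  encoder_filters <- as.integer(encoder_filters)
  decoder_filters <- as.integer(decoder_filters)
  if (any(encoder_filters <= 0)) stop("filter counts must be positive", call. = FALSE)
  if (!identical(decoder_filters, rev(encoder_filters)))
    stop("`decoder_filters` must be the reverse of `encoder_filters` (symmetric design)",
         call. = FALSE)
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) stop("`kernel` must be odd and >= 3", call. = FALSE)
  stride <- as.integer(stride)
  if (stride < 1L) stop("`stride` must be >= 1", call. = FALSE)
  structure(list(encoder_filters = encoder_filters,
                 decoder_filters = decoder_filters,
                 kernel = kernel, stride = stride,
                 in_channels = as.integer(in_channels),
                 output_channels = 1L, final_relu = isTRUE(final_relu)),
            class = "network_config")
}

#' Per-layer specification of a network config
#'
#' @param cfg A [network_config()].
#' @return Tibble with one row per layer: `layer`, `type` (`conv`/`tconv`),
#'   `stride`, `c_in`, `c_out`.
#' @export
layer_spec <- function(cfg) {
  ne <- length(cfg$encoder_filters)
  c_in <- c(cfg$in_channels, cfg$encoder_filters[-ne],      # encoder
            cfg$encoder_filters[ne], cfg$decoder_filters[-length(cfg$decoder_filters)], # decoder
            cfg$decoder_filters[length(cfg$decoder_filters)])                           # output
  c_out <- c(cfg$encoder_filters, cfg$decoder_filters, cfg$output_channels)
  tibble::tibble(
    layer = seq_along(c_in),
    type = c(rep("conv", ne), rep("tconv", length(cfg$decoder_filters)), "conv"),
    stride = c(rep(cfg$stride, ne + length(cfg$decoder_filters)), 1L),
    c_in = c_in, c_out = c_out)
}

#' Trainable parameter count
#'
#' Closed form: `sum(k^3 * c_in * c_out + c_out)` over all layers.
#'
#' @param x A [network_config()] or a built network.
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  cfg <- if (inherits(x, "dvr_network")) x$cfg else x
  ls <- layer_spec(cfg)
  sum(cfg$kernel^3 * ls$c_in * ls$c_out + ls$c_out)
}

#' Valid-padding output shape arithmetic
#'
#' Propagates an input spatial shape through all layers using valid-convolution
#' arithmetic: `floor((n - k)/s) + 1` per strided convolution,
#' `(n - 1)*s + k` per transposed convolution, and `n - k + 1` for the
#' stride-1 output layer. Errors (naming the failing layer and axis) if any
#' intermediate dimension would fall below 1 voxel, i.e. the input shape is
#' inadmissible.
#'
#' @param cfg A [network_config()].
#' @param input_shape Integer length-3 spatial shape.
#' @return List with `output` (integer length-3) and `trace` (tibble with
#'   per-layer input/output dimensions).
#' @export
output_shape <- function(cfg, input_shape) {
  input_shape <- as.integer(rep_len(input_shape, 3L))
  if (any(input_shape < 1)) stop("input shape must be >= 1 on all axes", call. = FALSE)
  ls <- layer_spec(cfg)
  k <- cfg$kernel
  n <- input_shape
  rows <- vector("list", nrow(ls))
  for (i in seq_len(nrow(ls))) {
    s <- ls$stride[i]
    if (ls$type[i] == "conv") {
      if (any(n < k)) {
        ax <- which(n < k)[1]
        stop(sprintf("input shape inadmissible: layer %d (%s) needs >= %d voxels on axis %d, has %d",
                     i, ls$type[i], k, ax, n[ax]), call. = FALSE)
      }
      out <- (n - k) %/% s + 1L
    } else {
      out <- (n - 1L) * s + k
    }
    rows[[i]] <- tibble::tibble(layer = i, type = ls$type[i], stride = s,
                                in_1 = n[1], in_2 = n[2], in_3 = n[3],
                                out_1 = out[1], out_2 = out[2], out_3 = out[3])
    n <- out
  }
  list(output = as.integer(n), trace = dplyr::bind_rows(rows))
}

#' Is an input shape admissible?
#'
#' @param cfg A [network_config()].
#' @param input_shape Integer length-3.
#' @return Logical.
#' @export
admissible_input <- function(cfg, input_shape) {
  !inherits(try(output_shape(cfg, input_shape), silent = TRUE), "try-error")
}

#' Build a network with randomly initialized weights
#'
#' Fan-in-scaled Gaussian initialization (`sd = sqrt(2 / (k^3 * c_in))`),
#' zero biases; deterministic given `seed`.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed.
#' @return A `dvr_network`: list with `cfg`, `layers` (each `W`, `b`), `seed`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  ls <- layer_spec(cfg)
  k <- cfg$kernel
  layers <- with_seed(as.integer(seed), {
    purrr::pmap(ls, function(layer, type, stride, c_in, c_out) {
      sdw <- sqrt(2 / (k^3 * c_in))
      wdim <- if (type == "conv") c(k, k, k, c_in, c_out) else c(k, k, k, c_out, c_in)
      list(type = type, stride = stride, c_in = c_in, c_out = c_out,
           W = array(stats::rnorm(prod(wdim), 0, sdw), dim = wdim),
           b = numeric(c_out))
    })
  })
  structure(list(cfg = cfg, layers = layers, seed = as.integer(seed)),
            class = "dvr_network")
}

#' @export
print.dvr_network <- function(x, ...) {
  ls <- layer_spec(x$cfg)
  cat(sprintf("<dvr_network> %d layers (%d conv, %d tconv), kernel %d^3, stride %d, %s parameters\n",
              nrow(ls), sum(ls$type == "conv"), sum(ls$type == "tconv"),
              x$cfg$kernel, x$cfg$stride, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

.relu <- function(x) .relu_inplace(x)  # x is always a fresh intermediate here

# Valid 3D convolution via im2col + GEMM; chunks along axis 3 when the
# lowered matrix would be large (whole-volume inference).
conv3d_fwd <- function(x4, W, b, stride, chunk_limit = 4e7) {
  d <- dim(x4); k <- dim(W)[1]; c_out <- dim(W)[5]
  o <- (d[1:3] - k) %/% stride + 1L
  K <- k^3 * d[4]
  Wm <- matrix(W, ncol = c_out)
  if (as.double(K) * prod(o) <= chunk_limit) {
    y <- crossprod(Wm, .im2col3d(x4, k, stride)) + b
    return(aperm(array(y, c(c_out, o)), c(2, 3, 4, 1)))
  }
  out <- array(0, c(o, c_out))
  cz <- max(1L, as.integer(chunk_limit / (K * o[1] * o[2])))
  z0 <- 1L
  while (z0 <= o[3]) {
    z1 <- min(z0 + cz - 1L, o[3])
    zin <- ((z0 - 1L) * stride + 1L):((z1 - 1L) * stride + k)
    xs <- x4[, , zin, , drop = FALSE]
    y <- crossprod(Wm, .im2col3d(xs, k, stride)) + b
    out[, , z0:z1, ] <- aperm(array(y, c(c_out, o[1], o[2], z1 - z0 + 1L)), c(2, 3, 4, 1))
    z0 <- z1 + 1L
  }
  out
}

# Transposed 3D convolution (adjoint of a stride-s valid convolution).
tconv3d_fwd <- function(x4, W, b, stride) {
  d <- dim(x4); k <- dim(W)[1]; c_out <- dim(W)[4]; c_in <- dim(W)[5]
  P <- prod(d[1:3])
  Wm <- matrix(W, ncol = c_in)                    # [k^3*c_out, c_in]
  cols <- Wm %*% t(matrix(x4, P, c_in))           # [k^3*c_out, P]
  od <- (d[1:3] - 1L) * stride + k
  y <- .col2im3d(cols, as.integer(od), c_out, k, stride)
  y + rep(b, each = prod(od))
}

# forward pass through all layers; optionally keep per-layer inputs/outputs
# (and, for conv layers, the lowered im2col matrices for reuse in backward)
net_forward <- function(model, x4, keep_cache = FALSE) {
  cfg <- model$cfg
  nl <- length(model$layers)
  cache <- if (keep_cache) list(input = vector("list", nl),
                                output = vector("list", nl),
                                cols = vector("list", nl))
  for (i in seq_len(nl)) {
    ly <- model$layers[[i]]
    if (keep_cache) cache$input[[i]] <- x4
    if (ly$type == "conv") {
      if (keep_cache) {
        k <- dim(ly$W)[1]; c_out <- dim(ly$W)[5]
        o <- (dim(x4)[1:3] - k) %/% ly$stride + 1L
        cols <- .im2col3d(x4, k, ly$stride)
        cache$cols[[i]] <- cols
        y <- aperm(array(crossprod(matrix(ly$W, ncol = c_out), cols) + ly$b,
                         c(c_out, o)), c(2, 3, 4, 1))
      } else {
        y <- conv3d_fwd(x4, ly$W, ly$b, ly$stride)
      }
    } else {
      y <- tconv3d_fwd(x4, ly$W, ly$b, ly$stride)
    }
    if (i < nl || cfg$final_relu) y <- .relu(y)
    if (keep_cache) cache$output[[i]] <- y
    x4 <- y
  }
  if (keep_cache) list(out = x4, cache = cache) else x4
}

#' Run the network on an input patch
#'
#' The patch shape is validated against the valid-padding arithmetic before
#' any compute; the output spatial shape always equals
#' `output_shape(cfg, dim(patch))$output`.
#'
#' @param model A `dvr_network`.
#' @param patch 3D numeric array (or volume), the normalized T1 patch.
#' @return 3D array of predicted DVR values.
#' @export
forward <- function(model, patch) {
  stopifnot(inherits(model, "dvr_network"))
  d <- dim(patch)
  if (length(d) != 3L) stop("`patch` must be a 3D array", call. = FALSE)
  output_shape(model$cfg, d)  # errors on inadmissible shapes before compute
  x4 <- array(vol_values(patch), c(d, model$cfg$in_channels))
  y <- net_forward(model, x4)
  array(y, dim = dim(y)[1:3])
}

# Backward pass: returns list of per-layer grads (dW, db) and the loss
# gradient w.r.t. the input. `dY` is dLoss/dOutput as a 4D array.
net_backward <- function(model, cache, dY) {
  cfg <- model$cfg
  nl <- length(model$layers)
  grads <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    ly <- model$layers[[i]]
    if (i < nl || cfg$final_relu) dY <- dY * (cache$output[[i]] > 0)
    x4 <- cache$input[[i]]
    k <- cfg$kernel; s <- ly$stride
    if (ly$type == "conv") {
      P <- prod(dim(dY)[1:3])
      dYm <- matrix(dY, P, ly$c_out)                       # [P, c_out]
      cols <- cache$cols[[i]] %||% .im2col3d(x4, k, s)
      dW <- cols %*% dYm                                   # [K, c_out]
      db <- colSums(dYm)
      dX <- .col2im3d(matrix(ly$W, ncol = ly$c_out) %*% t(dYm),
                      dim(x4)[1:3], ly$c_in, k, s)
    } else {
      Pin <- prod(dim(x4)[1:3])
      dcols <- .im2col3d(dY, k, s)                         # [k^3*c_out, Pin]
      dW <- dcols %*% matrix(x4, Pin, ly$c_in)             # [k^3*c_out, c_in]
      db <- colSums(matrix(dY, prod(dim(dY)[1:3]), ly$c_out))
      dX <- array(t(crossprod(matrix(ly$W, ncol = ly$c_in), dcols)),
                  c(dim(x4)[1:3], ly$c_in))
    }
    grads[[i]] <- list(dW = array(dW, dim = dim(ly$W)), db = db)
    dY <- dX
  }
  list(grads = grads, dInput = dY)
}
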