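#' Training hyperparameters
#'
#' Defaults follow the full-scale schedule: 64^3 patches, batch 4, 100 steps
#' per epoch (400 patches per epoch), 150 epochs, Adam with initial learning
#' rate 0.001 decayed by 0.99 every 100 steps.
#'
#' @param patch_size Cubic training patch edge (voxels).
#' @param batch_size Patches per optimizer step.
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param epochs Number of epochs.
#' @param lr0 Initial learning rate.
#' @param lr_decay Staircase decay factor in (0, 1].
#' @param lr_decay_every Steps between decays.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param n_val_patches Fixed validation patches drawn once before training.
#' @param seed Integer seed governing sampling and initialization.
#' @return A `training_config`.
#' @export
training_config <- function(patch_size = 64L, batch_size = 4L,
                            steps_per_epoch = 100L, epochs = 150L,
                            lr0 = 0.001, lr_decay = 0.99, lr_decay_every = 100L,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                            n_val_patches = 16L, seed = 1L) {
  stopifnot(patch_size >= 1, batch_size >= 1, steps_per_epoch >= 1, epochs >= 1,
            lr0 > 0, lr_decay > 0, lr_decay <= 1, lr_decay_every >= 1)
  structure(list(patch_size = as.integer(patch_size), batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch), epochs = as.integer(epochs),
                 lr0 = lr0, lr_decay = lr_decay, lr_decay_every = as.integer(lr_decay_every),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 n_val_patches = as.integer(n_val_patches), seed = as.integer(seed)),
            class = "training_config")
}

#' Learning rate at a global step
#'
#' Staircase exponential decay:
#' `lr0 * lr_decay^floor(step / lr_decay_every)`.
#'
#' @param step Global step index (>= 0); vectorized.
#' @param cfg A [training_config()].
#' @return Learning rate(s).
#' @export
lr_at <- function(step, cfg) {
  if (any(step < 0)) stop("`step` must be >= 0", call. = FALSE)
  cfg$lr0 * cfg$lr_decay^(step %/% cfg$lr_decay_every)
}

#' Draw uniform patch corners
#'
#' Corners are drawn uniformly over all positions where a cubic patch of the
#' given size fits inside the volume.
#'
#' @param volume_shape Integer length-3.
#' @param size Patch edge length.
#' @param n Number of draws.
#' @return Tibble with 1-based corner columns `c1`, `c2`, `c3`.
#' @export
sample_patch_corners <- function(volume_shape, size, n = 1L) {
  volume_shape <- as.integer(rep_len(volume_shape, 3L))
  if (any(volume_shape < size))
    stop(sprintf("volume (%s) smaller than patch size %d",
                 paste(volume_shape, collapse = "x"), size), call. = FALSE)
  m <- volume_shape - size + 1L
  tibble::tibble(c1 = sample.int(m[1], n, replace = TRUE),
                 c2 = sample.int(m[2], n, replace = TRUE),
                 c3 = sample.int(m[3], n, replace = TRUE))
}

#' Sample a paired training patch
#'
#' Crops the same uniformly drawn window from the input and target volumes;
#' if a network config is supplied, the target is centre-cropped to the
#' network's valid-padding output shape (offset `floor((in - out)/2)` per
#' axis).
#'
#' @param input,target Volumes (or 3D arrays) on a shared grid.
#' @param size Patch edge length.
#' @param net_cfg Optional [network_config()] used to centre-crop the target.
#' @return List with `input`, `target`, `corner` (1-based).
#' @export
sample_patch <- function(input, target, size, net_cfg = NULL) {
  d <- dim(input)
  if (!identical(d, dim(target))) stop("input and target must share a grid", call. = FALSE)
  corner <- sample_patch_corners(d, size, 1L)
  c0 <- c(corner$c1, corner$c2, corner$c3)
  ip <- vol_values(input)[c0[1]:(c0[1] + size - 1L),
                          c0[2]:(c0[2] + size - 1L),
                          c0[3]:(c0[3] + size - 1L)]
  tp <- vol_values(target)[c0[1]:(c0[1] + size - 1L),
                           c0[2]:(c0[2] + size - 1L),
                           c0[3]:(c0[3] + size - 1L)]
  if (!is.null(net_cfg)) {
    out <- output_shape(net_cfg, rep(size, 3L))$output
    off <- (size - out) %/% 2L
    tp <- tp[(off[1] + 1L):(off[1] + out[1]),
             (off[2] + 1L):(off[2] + out[2]),
             (off[3] + 1L):(off[3] + out[3])]
  }
  list(input = ip, target = tp, corner = c0)
}

#' Mean squared (L2) loss
#'
#' @param pred,target Arrays of identical shape.
#' @return Mean of squared voxel differences.
#' @export
l2_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("`pred` and `target` must have identical shapes", call. = FALSE)
  mean((pred - target)^2)
}

#' Prepare a phantom case for training or evaluation
#'
#' Builds the brain mask from the tissue segments, computes the DVR target
#' from the noisy (measured analog) or clean BPND, masks both volumes and
#' normalizes the T1 by its within-mask 99th-percentile intensity.
#'
#' @param case A `phantom_case`.
#' @param reference_label Atlas label of the reference region.
#' @param truth `"noisy"` (training target, real-data analog) or `"clean"`.
#' @param mask_threshold Brain-mask probability threshold.
#' @param normalize_quantile T1 normalization quantile.
#' @return List with `id`, `input` (normalized masked T1), `target` (masked
#'   DVR), `mask`.
#' @export
prepare_case <- function(case, reference_label = 1L, truth = c("noisy", "clean"),
                         mask_threshold = 0.5, normalize_quantile = 0.99) {
  truth <- match.arg(truth)
  mask <- combine_brain_mask(case$segments$gm, case$segments$wm, case$segments$csf,
                             mask_threshold)
  bpnd <- if (truth == "noisy") case$bpnd_noisy else case$bpnd_clean
  if (is.null(bpnd)) stop("case lacks the requested bpnd volume", call. = FALSE)
  dvr <- apply_mask(compute_dvr(bpnd, case$atlas, reference_label), mask)
  t1 <- normalize_t1(apply_mask(case$t1, mask), mask, normalize_quantile)
  list(id = case$id, input = t1, target = dvr, mask = mask)
}

# flatten/unflatten helpers for Adam state
.adam_init <- function(layers) {
  lapply(layers, function(ly) list(mW = array(0, dim(ly$W)), vW = array(0, dim(ly$W)),
                                   mb = numeric(length(ly$b)), vb = numeric(length(ly$b))))
}

#' Train the encoder-decoder on paired volumes
#'
#' Patch-based Adam optimization of the L2 loss. Each step draws
#' `batch_size` source participants uniformly with replacement, crops one
#' random patch from each, and averages the gradients; the learning rate
#' follows [lr_at()]. Per-epoch mean training loss and the loss over a fixed
#' set of validation patches are recorded. Fully reproducible from
#' `cfg$seed`.
#'
#' @param pairs List of training pairs as returned by [prepare_case()] (each
#'   with `input` and `target` volumes).
#' @param net_cfg A [network_config()].
#' @param cfg A [training_config()].
#' @param val_pairs Optional list of validation pairs (loss monitoring only;
#'   no model selection is performed — final-epoch weights are returned).
#' @param model Optional pre-built/pre-trained `dvr_network` to continue from.
#' @param verbose Print per-epoch losses.
#' @return A `dvr_fit`: list with `model`, `history` (tibble `epoch`,
#'   `train_loss`, `val_loss`), `patches_consumed`, `net_cfg`, `cfg`.
#' @export
train <- function(pairs, net_cfg, cfg, val_pairs = NULL, model = NULL,
                  verbose = FALSE) {
  if (!length(pairs)) stop("training set is empty", call. = FALSE)
  for (p in pairs) {
    if (any(dim(p$input) < cfg$patch_size))
      stop(sprintf("volume %s (%s) smaller than patch size %d",
                   p$id %||% "?", paste(dim(p$input), collapse = "x"),
                   cfg$patch_size), call. = FALSE)
  }
  output_shape(net_cfg, rep(cfg$patch_size, 3L))  # patch admissibility
  if (is.null(model)) model <- build_network(net_cfg, seed = cfg$seed)
  opt <- .adam_init(model$layers)

  # validation patches draw from their own derived seed so that monitoring
  # settings never perturb the training sample stream
  val_patches <- NULL
  if (length(val_pairs)) {
    val_patches <- with_seed(cfg$seed + 2L, {
      idx <- rep_len(seq_along(val_pairs), cfg$n_val_patches)
      lapply(idx, function(i)
        sample_patch(val_pairs[[i]]$input, val_pairs[[i]]$target,
                     cfg$patch_size, net_cfg))
    })
  }

  with_seed(cfg$seed + 1L, {
    nl <- length(model$layers)
    gstep <- 0L
    patches_consumed <- 0L
    t_adam <- 0L
    history <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- numeric(cfg$steps_per_epoch)
      for (st in seq_len(cfg$steps_per_epoch)) {
        gacc <- NULL
        bl <- 0
        for (b in seq_len(cfg$batch_size)) {
          i <- sample.int(length(pairs), 1L)
          pt <- sample_patch(pairs[[i]]$input, pairs[[i]]$target,
                             cfg$patch_size, net_cfg)
          patches_consumed <- patches_consumed + 1L
          x4 <- array(pt$input, c(dim(pt$input), 1L))
          fw <- net_forward(model, x4, keep_cache = TRUE)
          pred <- array(fw$out, dim = dim(fw$out)[1:3])
          res <- pred - pt$target
          bl <- bl + mean(res^2)
          dY <- array(2 * res / length(res), dim = dim(fw$out))
          bw <- net_backward(model, fw$cache, dY)
          if (is.null(gacc)) gacc <- bw$grads
          else for (j in seq_len(nl)) {
            gacc[[j]]$dW <- gacc[[j]]$dW + bw$grads[[j]]$dW
            gacc[[j]]$db <- gacc[[j]]$db + bw$grads[[j]]$db
          }
        }
        if (!is.finite(bl)) {
          stop(sprintf("non-finite loss at epoch %d step %d; aborting", ep, st), call. = FALSE)
        }
        ep_loss[st] <- bl / cfg$batch_size
        lr <- lr_at(gstep, cfg)
        t_adam <- t_adam + 1L
        bc1 <- 1 - cfg$beta1^t_adam
        bc2 <- 1 - cfg$beta2^t_adam
        for (j in seq_len(nl)) {
          gW <- gacc[[j]]$dW / cfg$batch_size
          gb <- gacc[[j]]$db / cfg$batch_size
          opt[[j]]$mW <- cfg$beta1 * opt[[j]]$mW + (1 - cfg$beta1) * gW
          opt[[j]]$vW <- cfg$beta2 * opt[[j]]$vW + (1 - cfg$beta2) * gW^2
          opt[[j]]$mb <- cfg$beta1 * opt[[j]]$mb + (1 - cfg$beta1) * gb
          opt[[j]]$vb <- cfg$beta2 * opt[[j]]$vb + (1 - cfg$beta2) * gb^2
          model$layers[[j]]$W <- model$layers[[j]]$W -
            lr * (opt[[j]]$mW / bc1) / (sqrt(opt[[j]]$vW / bc2) + cfg$eps)
          model$layers[[j]]$b <- model$layers[[j]]$b -
            lr * (opt[[j]]$mb / bc1) / (sqrt(opt[[j]]$vb / bc2) + cfg$eps)
        }
        gstep <- gstep + 1L
      }
      val_loss <- NA_real_
      if (length(val_patches)) {
        vl <- vapply(val_patches, function(pt) {
          pred <- forward(model, pt$input)
          l2_loss(pred, pt$target)
        }, numeric(1))
        val_loss <- mean(vl)
      }
      history[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(ep_loss),
                                      val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %s", ep, mean(ep_loss),
                        ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
      }
    }
    model$trained_patch <- cfg$patch_size
    structure(list(model = model, history = dplyr::bind_rows(history),
                   patches_consumed = patches_consumed,
                   net_cfg = net_cfg, cfg = cfg),
              class = "dvr_fit")
  })
}

#' @export
print.dvr_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<dvr_fit> %d epochs x %d steps, %d patches; final train loss %.5g%s\n",
              nrow(h), x$cfg$steps_per_epoch, x$patches_consumed,
              h$train_loss[nrow(h)],
              if (!is.na(h$val_loss[nrow(h)])) sprintf(", val %.5g", h$val_loss[nrow(h)]) else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname train
#' @param x A `dvr_fit`.
#' @param ... Unused.
#' @export
tidy.dvr_fit <- function(x, ...) x$history

#' @rdname train
#' @export
glance.dvr_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_train_loss = h$train_loss[nrow(h)],
                 final_val_loss = h$val_loss[nrow(h)],
                 patches_consumed = x$patches_consumed,
                 n_parameters = n_parameters(x$model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
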