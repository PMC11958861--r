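.mask_vectors <- function(x, y, mask) {
  check_same_grid(x, y, .what = "volumes")
  if (!is.null(mask)) {
    check_same_grid(x, mask, .what = "volume and mask")
    keep <- vol_values(mask) != 0
    if (!any(keep)) stop("evaluation mask is empty", call. = FALSE)
    list(x = vol_values(x)[keep], y = vol_values(y)[keep])
  } else {
    list(x = as.vector(vol_values(x)), y = as.vector(vol_values(y)))
  }
}

#' Mean squared error over a mask
#'
#' @param x Ground-truth volume.
#' @param y Predicted volume.
#' @param mask Binary evaluation mask (NULL for the whole grid).
#' @return Scalar MSE.
#' @export
vol_mse <- function(x, y, mask = NULL) {
  v <- .mask_vectors(x, y, mask)
  mean((v$x - v$y)^2)
}

#' Global-moment structural similarity index
#'
#' The single-window SSIM computed from the masked means, variances
#' (population, i.e. divided by n) and covariance:
#' `((2*mx*my + c1) * (2*sxy + c2)) / ((mx^2 + my^2 + c1) * (sx^2 + sy^2 + c2))`
#' with `c1 = (k1*L)^2`, `c2 = (k2*L)^2` and `L` the dynamic range of the
#' ground truth within the mask (falling back to 1 when the truth is
#' constant, so the constants still stabilize the degenerate case). This is
#' the global variant, not the windowed local-SSIM average; a windowed
#' variant is available via `window`.
#'
#' @param x Ground-truth volume.
#' @param y Predicted volume.
#' @param mask Binary evaluation mask (NULL for the whole grid).
#' @param k1,k2 Proportionality factors for the regularization constants
#'   (defaults 0.01, 0.03).
#' @param L Dynamic range; computed from `x` within the mask when NULL.
#' @param window Optional odd cubic window edge; when given, the mean of
#'   local SSIM over windows centred on mask voxels is returned instead of
#'   the global form.
#' @return SSIM in \[-1, 1\].
#' @export
ssim_global <- function(x, y, mask = NULL, k1 = 0.01, k2 = 0.03, L = NULL,
                        window = NULL) {
  if (!is.null(window)) return(.ssim_windowed(x, y, mask, k1, k2, L, window))
  v <- .mask_vectors(x, y, mask)
  if (is.null(L)) L <- diff(range(v$x))
  if (L <= 0) L <- 1
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  n <- length(v$x)
  mx <- mean(v$x); my <- mean(v$y)
  sx2 <- mean((v$x - mx)^2); sy2 <- mean((v$y - my)^2)
  sxy <- mean((v$x - mx) * (v$y - my))
  ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sx2 + sy2 + c2))
}

# windowed local SSIM (comparison variant): mean over cubic windows fully
# inside the grid whose centre voxel is in the mask
.ssim_windowed <- function(x, y, mask, k1, k2, L, window) {
  stopifnot(window %% 2 == 1, window >= 3)
  check_same_grid(x, y, .what = "volumes")
  xv <- vol_values(x); yv <- vol_values(y)
  if (is.null(L)) {
    v <- .mask_vectors(x, y, mask)
    L <- diff(range(v$x))
  }
  if (L <= 0) L <- 1
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  d <- dim(xv); h <- (window - 1L) %/% 2L
  mv <- if (is.null(mask)) array(1, d) else vol_values(mask)
  centres <- which(mv != 0, arr.ind = TRUE)
  centres <- centres[centres[, 1] > h & centres[, 1] <= d[1] - h &
                     centres[, 2] > h & centres[, 2] <= d[2] - h &
                     centres[, 3] > h & centres[, 3] <= d[3] - h, , drop = FALSE]
  if (!nrow(centres)) stop("no complete windows inside the mask", call. = FALSE)
  ssims <- apply(centres, 1, function(cc) {
    xs <- xv[(cc[1] - h):(cc[1] + h), (cc[2] - h):(cc[2] + h), (cc[3] - h):(cc[3] + h)]
    ys <- yv[(cc[1] - h):(cc[1] + h), (cc[2] - h):(cc[2] + h), (cc[3] - h):(cc[3] + h)]
    mx <- mean(xs); my <- mean(ys)
    sx2 <- mean((xs - mx)^2); sy2 <- mean((ys - my)^2)
    sxy <- mean((xs - mx) * (ys - my))
    ((2 * mx * my + c1) * (2 * sxy + c2)) / ((mx^2 + my^2 + c1) * (sx2 + sy2 + c2))
  })
  mean(ssims)
}

#' Percentage bias over a region
#'
#' `100 * (mean(x[R]) - mean(y[R])) / mean(x[R])`: positive when the
#' prediction undershoots the ground truth, negative when it overshoots.
#'
#' @param x Ground-truth volume.
#' @param y Predicted volume.
#' @param region_mask Binary region mask (NULL for the whole grid).
#' @return Signed percentage.
#' @export
percent_bias <- function(x, y, region_mask = NULL) {
  v <- .mask_vectors(x, y, region_mask)
  mx <- mean(v$x)
  if (mx == 0) {
    stop("ground-truth region mean is zero; percentage bias undefined", call. = FALSE)
  }
  100 * (mx - mean(v$y)) / mx
}

#' Pearson correlation over a mask
#'
#' @param x Ground-truth volume.
#' @param y Predicted volume.
#' @param mask Binary evaluation mask (NULL for the whole grid).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
vol_pearson <- function(x, y, mask = NULL) {
  v <- .mask_vectors(x, y, mask)
  if (stats::sd(v$x) == 0 || stats::sd(v$y) == 0)
    stop("correlation undefined for a constant volume", call. = FALSE)
  stats::cor(v$x, v$y)
}

#' Joint histogram with least-squares line
#'
#' Bins the masked (truth, prediction) voxel pairs into a 2D histogram and
#' fits the least-squares line of `y` on `x` (closed-form normal equations);
#' the reported correlation is identical to [vol_pearson()].
#'
#' @param x Ground-truth volume.
#' @param y Predicted volume.
#' @param mask Binary evaluation mask (NULL for the whole grid).
#' @param bins Bins per axis (default 64).
#' @return A `joint_fit`: list with `slope`, `intercept`, `rho`, `n` and
#'   `histogram` (tibble `x_mid`, `y_mid`, `count`).
#' @export
joint_histogram_fit <- function(x, y, mask = NULL, bins = 64L) {
  v <- .mask_vectors(x, y, mask)
  if (stats::sd(v$x) == 0) stop("degenerate ground truth: zero variance", call. = FALSE)
  mx <- mean(v$x); my <- mean(v$y)
  slope <- sum((v$x - mx) * (v$y - my)) / sum((v$x - mx)^2)
  intercept <- my - slope * mx
  rho <- stats::cor(v$x, v$y)
  brx <- seq(min(v$x), max(v$x), length.out = bins + 1L)
  bry <- seq(min(v$y), max(v$y), length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(v$x, brx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(v$y, bry, rightmost.closed = TRUE), 1L), bins)
  tab <- table(factor(ix, levels = seq_len(bins)), factor(iy, levels = seq_len(bins)))
  hist <- tibble::tibble(
    x_mid = rep((brx[-1] + brx[-(bins + 1L)]) / 2, times = bins),
    y_mid = rep((bry[-1] + bry[-(bins + 1L)]) / 2, each = bins),
    count = as.vector(tab))
  structure(list(slope = slope, intercept = intercept, rho = rho,
                 n = length(v$x), histogram = hist),
            class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("<joint_fit> y = %.4f x + %.4f, rho = %.4f (n = %d voxels)\n",
              x$slope, x$intercept, x$rho, x$n))
  invisible(x)
}

#' @rdname joint_histogram_fit
#' @param x A `joint_fit`.
#' @param ... Unused.
#' @export
tidy.joint_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @rdname joint_histogram_fit
#' @export
glance.joint_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, rho = x$rho, n = x$n)
}

#' Per-participant global metrics
#'
#' @param truth Ground-truth volume.
#' @param pred Predicted volume.
#' @param mask Binary evaluation mask.
#' @param ... Passed to [ssim_global()].
#' @return One-row tibble: `mse`, `ssim`, `percent_bias`, `pearson`.
#' @export
metrics_report <- function(truth, pred, mask = NULL, ...) {
  tibble::tibble(
    mse = vol_mse(truth, pred, mask),
    ssim = ssim_global(truth, pred, mask, ...),
    percent_bias = percent_bias(truth, pred, mask),
    pearson = vol_pearson(truth, pred, mask))
}

#' Per-ROI bias and SSIM report
#'
#' One row per atlas label: percentage bias and global-moment SSIM with the
#' ROI as the evaluation region. Labels listed in `rois` but absent from the
#' atlas yield a row flagged `empty` with NA metrics rather than being
#' dropped.
#'
#' @param truth Ground-truth volume.
#' @param pred Predicted volume.
#' @param atlas Integer-label volume.
#' @param rois Optional tibble with `label` and `name` (defaults to the
#'   labels present in the atlas).
#' @return Tibble: `label`, `name`, `n_voxels`, `percent_bias`, `ssim`,
#'   `empty`.
#' @export
roi_report <- function(truth, pred, atlas, rois = NULL) {
  check_same_grid(truth, pred, atlas, .what = "volumes and atlas")
  av <- vol_values(atlas)
  if (is.null(rois)) {
    labs <- sort(unique(as.vector(av)))
    labs <- labs[labs > 0]
    rois <- tibble::tibble(label = labs, name = sprintf("roi_%02d", labs))
  }
  purrr::pmap(rois[, c("label", "name")], function(label, name) {
    m <- (av == label) * 1
    nv <- sum(m)
    if (nv == 0) {
      return(tibble::tibble(label = label, name = name, n_voxels = 0L,
                            percent_bias = NA_real_, ssim = NA_real_, empty = TRUE))
    }
    mask <- vol_like(m, truth)
    tibble::tibble(label = label, name = name, n_voxels = as.integer(nv),
                   percent_bias = percent_bias(truth, pred, mask),
                   ssim = ssim_global(truth, pred, mask),
                   empty = FALSE)
  }) |> dplyr::bind_rows()
}

#' Two-sample t-test between groups of ROI means
#'
#' Welch's two-sided two-sample t-test (unequal variances) by default, as
#' used to compare per-participant regional means between diagnostic groups.
#'
#' @param data Data frame with one row per participant.
#' @param value Column of per-participant ROI means (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param groups Character length-2: the two group labels to compare.
#' @param var_equal Use the pooled-variance (Student) variant.
#' @return One-row tibble: group labels and means, `statistic`, `df`,
#'   `p_value`, confidence bounds, `method`.
#' @export
group_ttest <- function(data, value, group, groups, var_equal = FALSE) {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  stopifnot(length(groups) == 2L)
  v <- rlang::eval_tidy(value, data)
  g <- rlang::eval_tidy(group, data)
  v1 <- v[g == groups[1]]; v2 <- v[g == groups[2]]
  if (length(v1) < 2L || length(v2) < 2L)
    stop("each group needs at least 2 participants", call. = FALSE)
  tt <- stats::t.test(v1, v2, var.equal = var_equal)
  tibble::tibble(group1 = groups[1], group2 = groups[2],
                 mean1 = mean(v1), mean2 = mean(v2),
                 n1 = length(v1), n2 = length(v2),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                 method = tt$method)
}

#' Aggregate per-participant metrics to mean +/- SD tables
#'
#' @param per_participant Tibble with metric columns and a grouping column.
#' @param group Grouping column (tidy-eval); an `"All"` row is appended.
#' @param metrics Character vector of metric column names.
#' @return Tibble with `group`, `n`, and `<metric>_mean` / `<metric>_sd`
#'   columns.
#' @export
aggregate_metrics <- function(per_participant, group,
                              metrics = c("percent_bias", "mse", "ssim", "pearson")) {
  group <- rlang::enquo(group)
  metrics <- intersect(metrics, names(per_participant))
  per_group <- per_participant |>
    dplyr::group_by(group = !!group) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(metrics),
                                   list(mean = ~mean(.x), sd = ~stats::sd(.x))),
                     .groups = "drop")
  all_row <- per_participant |>
    dplyr::summarise(group = "All", n = dplyr::n(),
                     dplyr::across(dplyr::all_of(metrics),
                                   list(mean = ~mean(.x), sd = ~stats::sd(.x))))
  dplyr::bind_rows(per_group, all_row)
}
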