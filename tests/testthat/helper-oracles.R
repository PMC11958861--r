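# Independent brute-force oracles: explicit voxel loops, deliberately naive,
# sharing no code with the package implementations.

oracle_mse <- function(x, y, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim(x))
  s <- 0; n <- 0
  for (i in seq_along(x)) {
    if (mask[i] != 0) { s <- s + (x[i] - y[i])^2; n <- n + 1 }
  }
  s / n
}

oracle_bias <- function(x, y, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim(x))
  sx <- 0; sy <- 0; n <- 0
  for (i in seq_along(x)) {
    if (mask[i] != 0) { sx <- sx + x[i]; sy <- sy + y[i]; n <- n + 1 }
  }
  100 * (sx / n - sy / n) / (sx / n)
}

oracle_ssim <- function(x, y, mask = NULL, k1 = 0.01, k2 = 0.03) {
  if (is.null(mask)) mask <- array(1, dim(x))
  xs <- c(); ys <- c()
  for (i in seq_along(x)) if (mask[i] != 0) { xs <- c(xs, x[i]); ys <- c(ys, y[i]) }
  L <- max(xs) - min(xs); if (L <= 0) L <- 1
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  n <- length(xs)
  mx <- sum(xs) / n; my <- sum(ys) / n
  sx2 <- sum((xs - mx)^2) / n; sy2 <- sum((ys - my)^2) / n
  sxy <- sum((xs - mx) * (ys - my)) / n
  ((2 * mx * my + c1) * (2 * sxy + c2)) / ((mx^2 + my^2 + c1) * (sx2 + sy2 + c2))
}

oracle_pearson <- function(x, y, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim(x))
  xs <- c(); ys <- c()
  for (i in seq_along(x)) if (mask[i] != 0) { xs <- c(xs, x[i]); ys <- c(ys, y[i]) }
  n <- length(xs)
  mx <- mean(xs); my <- mean(ys)
  sum((xs - mx) * (ys - my)) / sqrt(sum((xs - mx)^2) * sum((ys - my)^2))
}

oracle_lsfit <- function(x, y, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim(x))
  xs <- c(); ys <- c()
  for (i in seq_along(x)) if (mask[i] != 0) { xs <- c(xs, x[i]); ys <- c(ys, y[i]) }
  n <- length(xs)
  sx <- sum(xs); sy <- sum(ys); sxx <- sum(xs^2); sxy <- sum(xs * ys)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

oracle_dvr <- function(bpnd, atlas, ref_label) {
  s <- 0; n <- 0
  for (i in seq_along(bpnd)) if (atlas[i] == ref_label) { s <- s + bpnd[i]; n <- n + 1 }
  ref_mean <- s / n
  out <- array(0, dim(bpnd))
  for (i in seq_along(bpnd)) out[i] <- (bpnd[i] + 1) / (ref_mean + 1)
  out
}

rand_vol <- function(n = 8, seed = NULL, lo = 0, hi = 1) {
  if (!is.null(seed)) set.seed(seed)
  as_volume(array(runif(n^3, lo, hi), rep(n, 3)))
}

# stride-1 toy config: output edge = input edge - 2, fully shift-covariant
tiny_net_s1 <- function(ch = 2L) {
  network_config(rep(ch, 4), stride = 1L)
}

# array payload only (drop class/voxel_size), for exactness comparisons
strip_vol <- function(v) {
  a <- unclass(v)
  attributes(a) <- list(dim = dim(v))
  a
}

# shared small phantom fixture (computed once per test run)
small_phantom_env <- new.env()
get_small_phantom <- function() {
  if (is.null(small_phantom_env$case)) {
    p <- phantom_params(shape = c(24, 24, 24), voxel_size = c(4, 4, 4), seed = 11)
    small_phantom_env$params <- p
    small_phantom_env$case <- make_phantom(p, disease_effects()$HC, dose = 15, id = "fix-01")
  }
  small_phantom_env$case
}
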