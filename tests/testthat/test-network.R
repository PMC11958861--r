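test_that("parameter counts follow the closed form", {
  cfg <- network_config(c(32, 64, 128, 256))
  ls <- layer_spec(cfg)
  # first encoder layer: 3^3 * 1 * 32 + 32
  expect_equal(3^3 * ls$c_in[1] * ls$c_out[1] + ls$c_out[1], 896)
  closed <- sum(3^3 * ls$c_in * ls$c_out + ls$c_out)
  expect_equal(n_parameters(cfg), closed)

  red <- network_config(c(8, 16, 32, 64))
  lr <- layer_spec(red)
  expect_equal(n_parameters(red), sum(3^3 * lr$c_in * lr$c_out + lr$c_out))

  # the framework's own count: total weight+bias elements of a built model
  m <- build_network(red, seed = 1)
  expect_equal(sum(vapply(m$layers, function(l) length(l$W) + length(l$b), numeric(1))),
               n_parameters(red))

  expect_error(network_config(c(32, 64), decoder_filters = c(32, 64)), "reverse")
  expect_error(network_config(c(8, 16), kernel = 4), "odd")
})

test_that("forward output shapes equal the valid-padding arithmetic on a sweep", {
  cfg <- network_config(c(1, 2, 2, 1), stride = 2)
  m <- build_network(cfg, seed = 7)
  shapes <- list()
  for (n in 31:60) if (admissible_input(cfg, rep(n, 3))) shapes <- c(shapes, list(rep(n, 3)))
  shapes <- c(shapes[seq_len(min(18, length(shapes)))],
              list(c(31, 35, 39), c(33, 47, 31), c(44, 31, 52)))
  expect_gte(length(shapes), 20)
  for (sh in shapes) {
    pred_shape <- output_shape(cfg, sh)$output
    y <- forward(m, array(rnorm(prod(sh)), sh))
    expect_identical(dim(y), as.integer(pred_shape))
  }
  # parameter count does not depend on input shape
  expect_equal(n_parameters(m), n_parameters(cfg))
})

test_that("the full-scale inference patch is admissible with a small margin", {
  cfg <- network_config(c(32, 64, 128, 256))
  os <- output_shape(cfg, c(240, 240, 160))
  expect_identical(os$output, c(237L, 237L, 157L))
  expect_true(all(c(240, 240, 160) - os$output <= 8))
  # encoder trace strictly decreasing, decoder strictly increasing
  tr <- os$trace
  enc <- tr[tr$type == "conv" & tr$layer <= 4, ]
  expect_true(all(enc$out_1 < enc$in_1))
  dec <- tr[tr$type == "tconv", ]
  expect_true(all(dec$out_1 > dec$in_1))
  # inadmissible input identifies the failing layer
  expect_error(output_shape(cfg, c(17, 17, 17)), "layer 4")
})

test_that("forward is deterministic, rejects bad shapes, and zero weights give zero", {
  cfg <- network_config(c(2, 2, 2, 2), stride = 2)
  m <- build_network(cfg, seed = 3)
  x <- array(abs(rnorm(31^3)), c(31, 31, 31))
  expect_identical(forward(m, x), forward(m, x))
  expect_error(forward(m, array(0, c(10, 10, 10))), "inadmissible")

  for (i in seq_along(m$layers)) {
    m$layers[[i]]$W[] <- 0
    m$layers[[i]]$b[] <- 0
  }
  expect_true(all(forward(m, x) == 0))

  # rectified output layer keeps predictions non-negative
  m2 <- build_network(cfg, seed = 4)
  expect_true(all(forward(m2, x) >= 0))
})

test_that("a valid convolution layer matches the hand-computed oracle", {
  set.seed(10)
  k <- 3; cin <- 2; cout <- 2; n <- 5
  W <- array(rnorm(k^3 * cin * cout), c(k, k, k, cin, cout))
  b <- rnorm(cout)
  x <- array(rnorm(n^3 * cin), c(n, n, n, cin))
  got <- dvrnet:::conv3d_fwd(x, W, b, 1L)
  o <- n - k + 1
  ref <- array(0, c(o, o, o, cout))
  for (co in 1:cout) for (i in 1:o) for (j in 1:o) for (l in 1:o) {
    acc <- b[co]
    for (ci in 1:cin) for (a in 1:k) for (bb in 1:k) for (cc in 1:k) {
      acc <- acc + x[i + a - 1, j + bb - 1, l + cc - 1, ci] * W[a, bb, cc, ci, co]
    }
    ref[i, j, l, co] <- acc
  }
  expect_equal(got, ref, tolerance = 1e-12)

  # transposed convolution is the exact adjoint of the strided convolution
  set.seed(11)
  s <- 2; cin <- 2; cout <- 3; n <- 4
  Wt <- array(rnorm(k^3 * cout * cin), c(k, k, k, cout, cin))
  xt <- array(rnorm(n^3 * cin), c(n, n, n, cin))
  yt <- dvrnet:::tconv3d_fwd(xt, Wt, rep(0, cout), s)
  od <- (n - 1) * s + k
  g <- array(rnorm(od^3 * cout), c(od, od, od, cout))
  lhs <- sum(yt * g)
  rhs <- sum(xt * dvrnet:::conv3d_fwd(g, Wt, rep(0, cin), s))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(12)
  cfg <- network_config(c(2, 2, 2, 2), stride = 2, final_relu = FALSE)
  m <- build_network(cfg, seed = 13)
  x <- array(abs(rnorm(31^3, 0.5, 0.3)), c(31, 31, 31))
  os <- output_shape(cfg, dim(x))$output
  tgt <- array(runif(prod(os)), os)
  x4 <- array(x, c(dim(x), 1))
  fw <- dvrnet:::net_forward(m, x4, keep_cache = TRUE)
  pred <- array(fw$out, dim(fw$out)[1:3])
  dY <- array(2 * (pred - tgt) / length(tgt), dim(fw$out))
  bw <- dvrnet:::net_backward(m, fw$cache, dY)
  lossfn <- function(mod) mean((forward(mod, x) - tgt)^2)
  eps <- 1e-5
  for (li in c(1, 4, 6, 9)) {
    idx <- sample(length(m$layers[[li]]$W), 2)
    for (id in idx) {
      m2 <- m; m2$layers[[li]]$W[id] <- m2$layers[[li]]$W[id] + eps
      m3 <- m; m3$layers[[li]]$W[id] <- m3$layers[[li]]$W[id] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      ana <- bw$grads[[li]]$dW[id]
      expect_lt(abs(num - ana), 1e-6 + 1e-4 * (abs(num) + abs(ana)))
    }
  }
})

test_that("a stride-1 network is translation covariant", {
  cfg <- tiny_net_s1()   # output edge = input edge - 2
  m <- build_network(cfg, seed = 21)
  set.seed(22)
  n <- 40
  x <- array(rnorm((n + 1) * n * n), c(n + 1, n, n))
  y_full <- forward(m, x)            # (n - 1) x (n - 2) x (n - 2)
  y_a <- forward(m, x[1:n, , ])      # (n - 2)^3
  y_b <- forward(m, x[2:(n + 1), , ])
  # away from the axis-1 boundaries (receptive radius ~10), shifting the
  # input window by one voxel shifts the valid-region output by one voxel
  core <- 13:26
  expect_equal(y_full[core, , ], y_a[core, , ], tolerance = 1e-12)
  expect_equal(y_full[core + 1, , ], y_b[core, , ], tolerance = 1e-12)
})
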