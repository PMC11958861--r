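test_that("global metrics match brute-force voxel-loop oracles", {
  set.seed(71)
  for (rep in 1:10) {
    x <- rand_vol(8); y <- rand_vol(8)
    mask <- as_volume(array(rbinom(8^3, 1, 0.7), c(8, 8, 8)))
    expect_equal(vol_mse(x, y, mask), oracle_mse(x, y, mask), tolerance = 1e-12)
    expect_equal(ssim_global(x, y, mask), oracle_ssim(x, y, mask), tolerance = 1e-12)
    expect_equal(percent_bias(x, y, mask), oracle_bias(x, y, mask), tolerance = 1e-12)
    expect_equal(vol_pearson(x, y, mask), oracle_pearson(x, y, mask), tolerance = 1e-12)
    fit <- joint_histogram_fit(x, y, mask)
    ref <- oracle_lsfit(x, y, mask)
    expect_equal(fit$slope, unname(ref["slope"]), tolerance = 1e-12)
    expect_equal(fit$intercept, unname(ref["intercept"]), tolerance = 1e-12)
    expect_equal(fit$rho, vol_pearson(x, y, mask))
  }
})

test_that("metric edge cases behave as the formulas dictate", {
  x <- rand_vol(6, seed = 72)
  expect_equal(vol_mse(x, x), 0)
  y2 <- as_volume(strip_vol(x) + 2)
  m3 <- as_volume(array(c(rep(1, 3), rep(0, 6^3 - 3)), c(6, 6, 6)))
  expect_equal(vol_mse(x, y2, m3), 4)

  # ssim identity over many random volumes
  set.seed(73)
  for (rep in 1:100) {
    v <- rand_vol(6)
    expect_equal(ssim_global(v, v), 1, tolerance = 1e-12)
  }
  # both constant: the regularization constants rescue 0/0
  ca <- as_volume(array(0.8, c(6, 6, 6)))
  expect_equal(ssim_global(ca, ca), 1)

  # windowed comparison variant: identity still scores 1
  v6 <- rand_vol(6, seed = 99, lo = 0.5, hi = 2)
  expect_equal(ssim_global(v6, v6, window = 3), 1, tolerance = 1e-12)

  # percent bias direct formula and sign convention
  mu2 <- as_volume(array(2, c(4, 4, 4)))
  mu1 <- as_volume(array(1, c(4, 4, 4)))
  expect_equal(percent_bias(mu2, mu1), 50)      # undershoot -> positive
  expect_equal(percent_bias(mu1, mu2), -100)    # overshoot -> negative
  expect_equal(percent_bias(x, x), 0)
  expect_error(percent_bias(as_volume(array(0, c(4, 4, 4))), mu1), "zero")

  # pearson affine invariance
  expect_equal(vol_pearson(x, as_volume(2 * strip_vol(x) + 3)), 1)
  expect_equal(vol_pearson(x, as_volume(-strip_vol(x))), -1)
  expect_error(vol_pearson(ca, x), "constant")

  # joint fit trivial slopes
  expect_equal(joint_histogram_fit(x, x)$slope, 1, tolerance = 1e-12)
  half <- joint_histogram_fit(x, as_volume(0.5 * strip_vol(x)))
  expect_equal(half$slope, 0.5, tolerance = 1e-12)
  expect_equal(half$intercept, 0, tolerance = 1e-12)
  expect_error(joint_histogram_fit(ca, x), "degenerate")

  # shape mismatches always error, never broadcast
  small <- rand_vol(4)
  expect_error(vol_mse(x, small), "grid")
  expect_error(ssim_global(x, small), "grid")
  expect_error(percent_bias(x, small), "grid")
  expect_error(vol_pearson(x, small), "grid")
})

test_that("roi reports are local, complete, and match per-label recomputation", {
  set.seed(74)
  x <- rand_vol(8, lo = 0.5, hi = 2)
  atlas <- as_volume(array(sample(1:3, 8^3, replace = TRUE), c(8, 8, 8)))
  rois <- tibble::tibble(label = 1:4, name = c("a", "b", "c", "ghost"))

  same <- roi_report(x, x, atlas, rois)
  expect_equal(nrow(same), 4)
  expect_true(same$empty[same$name == "ghost"])
  present <- same[!same$empty, ]
  expect_true(all(abs(present$percent_bias) < 1e-12))
  expect_true(all(abs(present$ssim - 1) < 1e-12))

  # scaling one ROI shows bias only there
  y <- strip_vol(x)
  y[strip_vol(atlas) == 2] <- y[strip_vol(atlas) == 2] * 0.9
  rep2 <- roi_report(x, as_volume(y), atlas, rois[1:3, ])
  expect_equal(rep2$percent_bias[rep2$label == 2], 10, tolerance = 1e-12)
  expect_true(all(abs(rep2$percent_bias[rep2$label != 2]) < 1e-12))

  # random case: every row matches a per-label oracle
  yr <- rand_vol(8, lo = 0.5, hi = 2)
  rep3 <- roi_report(x, yr, atlas, rois[1:3, ])
  for (lb in 1:3) {
    m <- as_volume((strip_vol(atlas) == lb) * 1)
    expect_equal(rep3$percent_bias[rep3$label == lb], oracle_bias(x, yr, m),
                 tolerance = 1e-12)
    expect_equal(rep3$ssim[rep3$label == lb], oracle_ssim(x, yr, m),
                 tolerance = 1e-12)
  }
})

test_that("group t-tests behave under null, shifted, and degenerate designs", {
  d0 <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                       group = rep(c("A", "B"), each = 3))
  tt <- group_ttest(d0, value, group, c("A", "B"))
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  expect_error(group_ttest(tibble::tibble(value = c(1, 2, 3), group = c("A", "A", "B")),
                           value, group, c("A", "B")), "at least 2")

  # power: N(0,1) vs N(5,1), n = 20 each, p < 0.001 essentially always
  set.seed(75)
  hits <- vapply(1:200, function(i) {
    d <- tibble::tibble(value = c(rnorm(20, 0), rnorm(20, 5)),
                        group = rep(c("A", "B"), each = 20))
    group_ttest(d, value, group, c("A", "B"))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # null calibration: p-values uniform under permuted labels
  set.seed(76)
  pv <- vapply(1:300, function(i) {
    d <- tibble::tibble(value = rnorm(24), group = sample(rep(c("A", "B"), 12)))
    group_ttest(d, value, group, c("A", "B"))$p_value
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("group aggregation recomputes exactly from per-participant rows", {
  set.seed(77)
  d <- tibble::tibble(diagnosis = rep(c("HC", "AD"), each = 5),
                      mse = runif(10), ssim = runif(10),
                      percent_bias = rnorm(10), pearson = runif(10))
  agg <- aggregate_metrics(d, diagnosis)
  expect_equal(nrow(agg), 3)
  hc <- d[d$diagnosis == "HC", ]
  expect_equal(agg$ssim_mean[agg$group == "HC"], mean(hc$ssim))
  expect_equal(agg$ssim_sd[agg$group == "HC"], sd(hc$ssim))
  expect_equal(agg$percent_bias_mean[agg$group == "All"], mean(d$percent_bias))
  expect_equal(agg$n[agg$group == "All"], 10)
})
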