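test_that("phantom generation is deterministic and validates inputs", {
  p <- phantom_params(shape = c(20, 20, 20), seed = 5)
  eff <- disease_effects()
  a <- make_phantom(p, eff$HC, dose = 10, id = "s1")
  b <- make_phantom(p, eff$HC, dose = 10, id = "s1")
  expect_identical(strip_vol(a$t1), strip_vol(b$t1))
  expect_identical(strip_vol(a$bpnd_noisy), strip_vol(b$bpnd_noisy))
  cc <- make_phantom(p, eff$HC, dose = 10, id = "s2")
  expect_false(identical(strip_vol(a$t1), strip_vol(cc$t1)))

  expect_error(make_phantom(p, eff$HC, dose = 0, id = "s1"), "positive")
  expect_error(make_phantom(p, eff$HC, dose = -3, id = "s1"), "positive")
  expect_error(phantom_params(shape = c(8, 8, 8)), "too small")
})

test_that("phantom volumes satisfy their structural invariants", {
  case <- get_small_phantom()
  gm <- case$segments$gm; wm <- case$segments$wm; csf <- case$segments$csf
  expect_true(all(gm >= 0 & gm <= 1))
  expect_true(all(wm >= 0 & wm <= 1))
  expect_true(all(csf >= 0 & csf <= 1))
  expect_true(all(gm + wm + csf <= 1 + 1e-12))
  expect_true(all(case$bpnd_clean >= 0))
  expect_true(all(case$bpnd_noisy >= 0))
  # every positive atlas label lies inside the head (where some tissue exists)
  head <- (gm + wm + csf) > 0
  expect_true(all(head[case$atlas > 0]))
  # all 12 labels present, including the reference
  expect_setequal(sort(unique(as.vector(case$atlas))), 0:12)
  # GM-dominant voxels carry higher bpnd than WM-dominant ones (GM-driven gain)
  expect_gt(mean(case$bpnd_clean[gm > 0.5]), mean(case$bpnd_clean[wm > 0.5]))
})

test_that("zero-noise phantoms have bpnd_noisy identical to bpnd_clean", {
  p <- phantom_params(shape = c(20, 20, 20), noise_scale = 0, seed = 5)
  case <- make_phantom(p, disease_effects()$HC, dose = 3, id = "s1")
  expect_identical(strip_vol(case$bpnd_noisy), strip_vol(case$bpnd_clean))
})

test_that("voxel noise follows the noise_scale/sqrt(dose) law", {
  p <- phantom_params(shape = c(16, 16, 16), noise_scale = 0.6, seed = 42)
  eff <- disease_effects()$HC
  centre <- c(8, 8, 8)
  dose <- 16
  diffs <- vapply(seq_len(200), function(i) {
    case <- make_phantom(p, eff, dose = dose, id = sprintf("mc-%03d", i))
    case$bpnd_noisy[centre[1], centre[2], centre[3]] -
      case$bpnd_clean[centre[1], centre[2], centre[3]]
  }, numeric(1))
  expected_sd <- 0.6 / sqrt(dose)
  expect_lt(abs(sd(diffs) - expected_sd) / expected_sd, 0.15)

  # monotonicity: noise SD decreases with dose
  sd_at_dose <- function(d) {
    v <- vapply(seq_len(60), function(i) {
      case <- make_phantom(p, eff, dose = d, id = sprintf("mc%d-%03d", d, i))
      case$bpnd_noisy[8, 8, 8] - case$bpnd_clean[8, 8, 8]
    }, numeric(1))
    sd(v)
  }
  sds <- vapply(c(6, 24, 96), sd_at_dose, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("disease effects lower regional synaptic density as constructed", {
  p <- phantom_params(shape = c(24, 24, 24), seed = 9)
  eff <- disease_effects()
  hc <- make_phantom(p, eff$HC, dose = 15, id = "pair")
  ad <- make_phantom(p, eff$AD, dose = 15, id = "pair")
  hipp <- hc$rois$label[hc$rois$name == "hippocampus"]
  expect_lt(mean(ad$bpnd_clean[ad$atlas == hipp]),
            mean(hc$bpnd_clean[hc$atlas == hipp]))
  # AD effect definition: hippocampus/temporal analogs strictly < 1
  expect_lt(eff$AD$regional_sv2a_multipliers[["hippocampus"]], 1)
  expect_lt(eff$AD$regional_sv2a_multipliers[["temporal"]], 1)
  # HC must be the identity
  expect_error(disease_effect("HC", c(frontal = 0.9)), "identity")
})

test_that("cohort manifests have exact composition and deterministic draws", {
  p <- phantom_params(shape = c(16, 16, 16), seed = 3)
  co <- make_cohort(p, n = 8, diagnosis_ratio = c(HC = 2, SZ = 2, AD = 2, CUD = 2),
                    n_low_dose = 1, seed = 21, generate = FALSE)
  expect_equal(nrow(co$manifest), 8)
  expect_equal(sum(co$manifest$low_dose), 1)
  expect_true(all(co$manifest$dose_mCi[co$manifest$low_dose] < 5))
  expect_true(all(co$manifest$dose_mCi[!co$manifest$low_dose] >= 5))

  # full-scale composition analog
  big <- make_cohort(p, n = 160, diagnosis_ratio = c(HC = 83, SZ = 24, AD = 34, CUD = 19),
                     n_low_dose = 5, seed = 77, generate = FALSE)
  expect_equal(as.vector(table(big$manifest$diagnosis)[c("HC", "SZ", "AD", "CUD")]),
               c(83, 24, 34, 19))
  expect_equal(sum(big$manifest$low_dose), 5)

  big2 <- make_cohort(p, n = 160, diagnosis_ratio = c(HC = 83, SZ = 24, AD = 34, CUD = 19),
                      n_low_dose = 5, seed = 77, generate = FALSE)
  expect_identical(big$manifest, big2$manifest)

  expect_error(make_cohort(p, n = 10, diagnosis_ratio = c(HC = 4, SZ = 4), seed = 1),
               "sums to")
  expect_error(make_cohort(p, n = 4, diagnosis_ratio = c(HC = 4), n_low_dose = 5, seed = 1),
               "low_dose")
})

test_that("cohorts round-trip through the on-disk layout", {
  p <- phantom_params(shape = c(16, 16, 16), seed = 13)
  co <- make_cohort(p, n = 2, diagnosis_ratio = c(HC = 1, AD = 1), n_low_dose = 1, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$manifest$id, co$manifest$id)
  expect_identical(strip_vol(back$cases[[1]]$t1), strip_vol(co$cases[[1]]$t1))
  expect_identical(strip_vol(back$cases[[2]]$atlas), strip_vol(co$cases[[2]]$atlas))
})
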