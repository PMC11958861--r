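make_test_manifest <- function(n = 160, n_low = 5, seed = 88) {
  p <- phantom_params(shape = c(16, 16, 16), seed = seed)
  make_cohort(p, n = n,
              diagnosis_ratio = c(HC = round(n * 83 / 160), SZ = round(n * 24 / 160),
                                  AD = round(n * 34 / 160), CUD = n - round(n * 83 / 160) -
                                    round(n * 24 / 160) - round(n * 34 / 160)),
              n_low_dose = n_low, seed = seed, generate = FALSE)$manifest
}

test_that("strict folds reproduce the full-scale design exactly", {
  manifest <- make_test_manifest()
  folds <- make_folds(manifest, k = 10, sizes = c(130, 7, 23), seed = 99)
  low_ids <- manifest$id[manifest$low_dose]
  cohort_prop <- table(manifest$diagnosis) / nrow(manifest)
  for (f in 1:10) {
    sp <- fold_split(folds, f)
    expect_equal(length(sp$train), 130)
    expect_equal(length(sp$validation), 7)
    expect_equal(length(sp$test), 23)
    # pairwise disjoint
    expect_equal(length(intersect(sp$train, sp$validation)), 0)
    expect_equal(length(intersect(sp$train, sp$test)), 0)
    expect_equal(length(intersect(sp$validation, sp$test)), 0)
    # low-dose ids always and only in test
    expect_true(all(low_ids %in% sp$test))
    expect_false(any(low_ids %in% c(sp$train, sp$validation)))
    # train stratification within one participant of cohort proportions
    tc <- table(factor(manifest$diagnosis[match(sp$train, manifest$id)],
                       levels = names(cohort_prop)))
    expect_true(all(abs(tc - 130 * cohort_prop) <= 1))
  }
  # every eligible participant tested at least once across folds
  tested <- unique(folds$id[folds$role == "test"])
  expect_setequal(tested, manifest$id)

  # determinism
  folds2 <- make_folds(manifest, k = 10, sizes = c(130, 7, 23), seed = 99)
  expect_identical(folds, folds2)

  # infeasible sizes name the binding constraint
  expect_error(make_folds(manifest, k = 10, sizes = c(150, 7, 23), seed = 1),
               "train\\+validation")
  expect_error(make_folds(manifest, k = 10, sizes = c(130, 7, 3), seed = 1),
               "low-dose")
})

test_that("default folds partition eligible ids and k = 1 is a single holdout", {
  manifest <- make_test_manifest(n = 32, n_low = 2)
  folds <- make_folds(manifest, k = 4, seed = 5)
  test_norm <- folds[folds$role == "test" & !folds$id %in% manifest$id[manifest$low_dose], ]
  # non-strict mode: eligible test chunks are a partition (each id once)
  expect_equal(length(unique(test_norm$id)), 30)
  expect_true(all(table(test_norm$id) == 1))

  f1 <- make_folds(manifest, k = 1, sizes = c(24, 4, 4), seed = 6)
  sp <- fold_split(f1, 1)
  expect_equal(lengths(sp), c(train = 24L, validation = 4L, test = 4L))
})

test_that("leave-one-disease-out splits partition the cohort by diagnosis", {
  manifest <- make_test_manifest()
  lodo <- leave_one_disease_out(manifest, "AD", seed = 7)
  sp <- fold_split(lodo, "lodo_AD")
  expect_equal(length(sp$test), 34)
  expect_true(all(manifest$diagnosis[match(sp$test, manifest$id)] == "AD"))
  expect_false(any(manifest$diagnosis[match(sp$train, manifest$id)] == "AD"))

  # union of the four held-out test sets is the full cohort
  all_test <- unlist(lapply(c("HC", "SZ", "AD", "CUD"), function(d) {
    fold_split(leave_one_disease_out(manifest, d, seed = 7), paste0("lodo_", d))$test
  }))
  expect_setequal(all_test, manifest$id)

  expect_error(leave_one_disease_out(manifest, "XX"), "not present")
  solo <- tibble::tibble(id = c("a", "b"), diagnosis = c("AD", "AD"),
                         low_dose = c(FALSE, FALSE))
  expect_error(leave_one_disease_out(solo, "AD"), "empty training")
})

test_that("a k = 2 cross-validation smoke run produces a coherent report", {
  p <- phantom_params(shape = c(32, 32, 32), voxel_size = c(4, 4, 4), seed = 301)
  co <- make_cohort(p, n = 8, diagnosis_ratio = c(HC = 4, SZ = 2, AD = 1, CUD = 1),
                    n_low_dose = 1, seed = 302)
  net_cfg <- network_config(c(2, 2, 2, 2), stride = 2)
  tr_cfg <- training_config(patch_size = 32, batch_size = 1, steps_per_epoch = 2,
                            epochs = 2, n_val_patches = 1, seed = 303)
  rpt <- run_crossval(co$cases, co$manifest, net_cfg, tr_cfg, k = 2, seed = 304)
  expect_s3_class(rpt, "experiment_report")
  expect_equal(sort(unique(rpt$per_participant$fold)), c(1, 2))
  expect_equal(nrow(rpt$history), 4)  # 2 folds x 2 epochs

  # coverage: every participant tested at least once
  expect_setequal(unique(rpt$per_participant$id), co$manifest$id)
  # low-dose never contributes to the normal-dose table and vice versa
  low_ids <- co$manifest$id[co$manifest$low_dose]
  expect_true(all(rpt$per_participant$low_dose[rpt$per_participant$id %in% low_ids]))
  # leakage audit: test ids disjoint from that fold's training ids
  for (f in 1:2) {
    sp <- fold_split(rpt$folds, f)
    scored <- rpt$per_participant$id[rpt$per_participant$fold == f]
    expect_setequal(scored, sp$test)
    expect_equal(length(intersect(scored, sp$train)), 0)
  }
  # ROI rows: one row per atlas ROI per scored participant
  n_rois <- nrow(co$cases[[1]]$rois)
  expect_equal(nrow(rpt$roi), n_rois * nrow(rpt$per_participant))
  # aggregates recompute from the per-participant rows
  tab <- report_group_table(rpt)
  norm <- rpt$per_participant[!rpt$per_participant$low_dose, ]
  expect_equal(tab$mse_mean[tab$group == "All"], mean(norm$mse))
  expect_s3_class(tidy(rpt), "tbl_df")
})

test_that("the denoising table is well-formed and exact in the zero-noise case", {
  p0 <- phantom_params(shape = c(32, 32, 32), voxel_size = c(4, 4, 4),
                       noise_scale = 0, seed = 311)
  case0 <- make_phantom(p0, disease_effects()$HC, dose = 3, id = "clean-01")
  net_cfg <- network_config(c(2, 2, 2, 2), stride = 2)
  m <- build_network(net_cfg, seed = 312)
  den <- denoising_comparison(m, list(case0))
  expect_equal(den$mse_noisy_vs_clean, 0)
  expect_true(all(c("id", "dose", "mse_noisy_vs_clean", "mse_pred_vs_clean",
                    "improved") %in% names(den)))

  # untrained model: no improvement guarantee, but the table is well-formed
  p <- phantom_params(shape = c(32, 32, 32), voxel_size = c(4, 4, 4), seed = 313)
  case <- make_phantom(p, disease_effects()$HC, dose = 2, id = "noisy-01")
  den2 <- denoising_comparison(m, list(case))
  expect_true(is.finite(den2$mse_pred_vs_clean))
  expect_gt(den2$mse_noisy_vs_clean, 0)

  case$bpnd_clean <- NULL
  expect_error(denoising_comparison(m, list(case)), "noiseless reference")
})
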