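# largest-remainder allocation of `total` slots proportional to `counts`
.largest_remainder <- function(total, counts) {
  props <- counts / sum(counts)
  raw <- total * props
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

# allocate `total` slots over diagnoses proportionally to `weights`, capped by
# per-diagnosis availability; any deficit goes to the diagnosis where one more
# participant deviates least from exact proportionality
.alloc_capped <- function(total, weights, avail) {
  avail <- avail[names(weights)]
  avail[is.na(avail)] <- 0L
  tgt <- pmin(.largest_remainder(total, weights), avail)
  ideal <- total * weights / sum(weights)
  while (sum(tgt) < total) {
    cand <- which(avail - tgt > 0)
    if (!length(cand)) break
    i <- cand[which.min(tgt[cand] + 1 - ideal[cand])]
    tgt[i] <- tgt[i] + 1L
  }
  tgt
}

# sample `target` ids per diagnosis from `pool` (tibble id/diagnosis)
.stratified_take <- function(pool, target) {
  taken <- character(0)
  for (d in names(target)) {
    avail <- pool$id[pool$diagnosis == d & !pool$id %in% taken]
    ntake <- min(target[[d]], length(avail))
    if (ntake > 0) taken <- c(taken, sample(avail, ntake))
  }
  short <- sum(target) - length(taken)
  if (short > 0) {
    left <- setdiff(pool$id, taken)
    taken <- c(taken, sample(left, min(short, length(left))))
  }
  taken
}

#' Stratified k-fold splits with low-dose-always-test
#'
#' Non-low-dose ("eligible") participants are partitioned into `k`
#' diagnosis-stratified chunks; each fold's test set is its chunk plus all
#' low-dose participants, so low-dose ids appear in every fold's test set and
#' never in training or validation, and every eligible participant is tested
#' in at least one fold. With `strict = TRUE` and explicit `sizes`
#' (train, validation, test), test sets are topped up by resampling eligible
#' participants so every fold has exactly the stated sizes (a participant may
#' then be tested in more than one fold), and training sets are allocated to
#' cohort diagnosis proportions by largest remainder — within one participant
#' of exact proportionality whenever the low-dose composition leaves enough
#' eligible participants per diagnosis (a heavily skewed low-dose draw can
#' make simultaneous coverage, exact sizes and proportionality infeasible,
#' in which case the allocation deviates minimally).
#'
#' @param manifest Tibble with columns `id`, `diagnosis`, `low_dose`.
#' @param k Number of folds.
#' @param sizes Optional integer length-3 `(train, validation, test)`; the
#'   full-scale analog is `c(130, 7, 23)` for 160 participants with 5
#'   low-dose.
#' @param seed Integer seed.
#' @param strict Enforce exact sizes (requires `sizes`).
#' @return Tibble with columns `fold`, `id`, `role`
#'   (train/validation/test).
#' @export
make_folds <- function(manifest, k, sizes = NULL, seed = 1L, strict = !is.null(sizes)) {
  stopifnot(all(c("id", "diagnosis", "low_dose") %in% names(manifest)))
  if (strict && is.null(sizes)) stop("`strict = TRUE` requires `sizes`", call. = FALSE)
  low_ids <- manifest$id[manifest$low_dose]
  eligible <- manifest[!manifest$low_dose, c("id", "diagnosis")]
  n_low <- length(low_ids)
  if (!is.null(sizes)) {
    sizes <- as.integer(sizes)
    if (sizes[3] < n_low)
      stop(sprintf("infeasible sizes: test size %d is below the %d low-dose participants that must always be tested",
                   sizes[3], n_low), call. = FALSE)
  }
  cohort_counts <- table(manifest$diagnosis)

  with_seed(as.integer(seed), {
    # diagnosis-stratified round-robin chunking of eligible ids
    chunk_of <- stats::setNames(integer(nrow(eligible)), eligible$id)
    for (d in unique(eligible$diagnosis)) {
      ids_d <- sample(eligible$id[eligible$diagnosis == d])
      chunk_of[ids_d] <- (seq_along(ids_d) - 1L) %% k + 1L
    }
    out <- vector("list", k)
    for (f in seq_len(k)) {
      test_norm <- names(chunk_of)[chunk_of == f]
      if (strict) {
        need <- sizes[3] - n_low
        elig_counts <- table(eligible$diagnosis)
        # training capacity: taking a test participant from diagnosis d must
        # leave at least round(train * cohort proportion) - 1 of d for training
        train_min <- pmax(.largest_remainder(sizes[1], cohort_counts) - 1L, 0L)
        if (length(test_norm) > need) {
          # stratified trim so the remaining pool stays proportional
          pool <- eligible[eligible$id %in% test_norm, ]
          tgt <- .alloc_capped(need, elig_counts, table(pool$diagnosis))
          test_norm <- .stratified_take(pool, tgt)
        } else if (length(test_norm) < need) {
          extra_pool <- eligible[!eligible$id %in% test_norm, ]
          if (nrow(extra_pool) < need - length(test_norm))
            stop(sprintf("infeasible sizes: fold %d cannot reach %d normal-dose test participants from %d eligible",
                         f, need, nrow(eligible)), call. = FALSE)
          dg <- names(elig_counts)
          cnt <- function(x) {
            v <- as.integer(table(factor(x, levels = dg)))
            stats::setNames(v, dg)
          }
          elig_n <- cnt(eligible$diagnosis)
          in_test <- cnt(eligible$diagnosis[eligible$id %in% test_norm])
          slack <- pmax(0L, elig_n - in_test - train_min[dg])
          pool_n <- cnt(extra_pool$diagnosis)
          avail <- pmin(pool_n, slack)
          if (sum(avail) < need - length(test_norm)) avail <- pool_n
          tgt <- .alloc_capped(need - length(test_norm), elig_counts, avail)
          test_norm <- c(test_norm, .stratified_take(extra_pool, tgt))
        }
      }
      rem <- eligible[!eligible$id %in% test_norm, ]
      if (!is.null(sizes)) {
        if (sizes[1] + sizes[2] > nrow(rem))
          stop(sprintf("infeasible sizes: train+validation = %d exceeds the %d eligible participants outside fold %d's test set",
                       sizes[1] + sizes[2], nrow(rem), f), call. = FALSE)
        target_train <- .alloc_capped(sizes[1], cohort_counts, table(rem$diagnosis))
        train_ids <- .stratified_take(rem, target_train)
        rem2 <- rem[!rem$id %in% train_ids, ]
        target_val <- .largest_remainder(sizes[2], table(rem2$diagnosis))
        val_ids <- .stratified_take(rem2, target_val)
      } else {
        nv <- max(1L, round(0.05 * nrow(rem)))
        target_val <- .largest_remainder(nv, table(rem$diagnosis))
        val_ids <- .stratified_take(rem, target_val)
        train_ids <- setdiff(rem$id, val_ids)
      }
      out[[f]] <- tibble::tibble(
        fold = f,
        id = c(train_ids, val_ids, test_norm, low_ids),
        role = c(rep("train", length(train_ids)),
                 rep("validation", length(val_ids)),
                 rep("test", length(test_norm) + n_low)))
    }
    dplyr::bind_rows(out)
  })
}

#' Extract one fold's id sets
#'
#' @param folds A [make_folds()] (or [leave_one_disease_out()]) tibble.
#' @param f Fold identifier.
#' @return List with `train`, `validation`, `test` character vectors.
#' @export
fold_split <- function(folds, f) {
  ff <- folds[folds$fold == f, ]
  list(train = ff$id[ff$role == "train"],
       validation = ff$id[ff$role == "validation"],
       test = ff$id[ff$role == "test"])
}

#' Leave-one-disease-out split
#'
#' All participants with the held-out diagnosis form the test set; the
#' remainder is split into diagnosis-stratified training and validation sets.
#'
#' @param manifest Tibble with `id`, `diagnosis`, `low_dose`.
#' @param held_out Diagnosis label to hold out.
#' @param val_fraction Fraction of the remainder reserved for validation.
#' @param seed Integer seed.
#' @return Tibble with `fold` (`"lodo_<diagnosis>"`), `id`, `role`.
#' @export
leave_one_disease_out <- function(manifest, held_out, val_fraction = 0.05, seed = 1L) {
  if (!held_out %in% manifest$diagnosis)
    stop(sprintf("diagnosis '%s' not present in the manifest", held_out), call. = FALSE)
  test_ids <- manifest$id[manifest$diagnosis == held_out]
  rem <- manifest[manifest$diagnosis != held_out, c("id", "diagnosis")]
  if (!nrow(rem)) stop("holding out this diagnosis leaves an empty training set", call. = FALSE)
  with_seed(as.integer(seed), {
    nv <- max(1L, round(val_fraction * nrow(rem)))
    target_val <- .largest_remainder(nv, table(rem$diagnosis))
    val_ids <- .stratified_take(rem, target_val)
    train_ids <- setdiff(rem$id, val_ids)
    tibble::tibble(fold = paste0("lodo_", held_out),
                   id = c(train_ids, val_ids, test_ids),
                   role = c(rep("train", length(train_ids)),
                            rep("validation", length(val_ids)),
                            rep("test", length(test_ids))))
  })
}

#' Score a trained model on a set of cases
#'
#' @param model A `dvr_network`.
#' @param cases Named list of `phantom_case`s.
#' @param truth `"clean"` (noiseless reference, synthetic only) or
#'   `"noisy"` (measured analog, as with real data).
#' @param reference_label Reference-region atlas label.
#' @param tile_input Optional tile input shape for inference.
#' @param tile_margin Optional overlap-tile margin (see [predict_case()]).
#' @return List with `metrics` (per-participant tibble) and `roi`
#'   (per-participant, per-ROI tibble).
#' @export
evaluate_cases <- function(model, cases, truth = c("clean", "noisy"),
                           reference_label = 1L, tile_input = NULL,
                           tile_margin = NULL) {
  truth <- match.arg(truth)
  res <- purrr::map(cases, function(case) {
    prep <- prepare_case(case, reference_label, truth = truth)
    pred <- predict_case(model, case, tile_input = tile_input,
                         tile_margin = tile_margin)
    m <- metrics_report(prep$target, pred, prep$mask) |>
      dplyr::mutate(id = case$id, diagnosis = case$diagnosis, dose = case$dose,
                    .before = 1)
    r <- roi_report(prep$target, pred, case$atlas, case$rois) |>
      dplyr::mutate(id = case$id, diagnosis = case$diagnosis, .before = 1)
    list(metrics = m, roi = r)
  })
  list(metrics = dplyr::bind_rows(purrr::map(res, "metrics")),
       roi = dplyr::bind_rows(purrr::map(res, "roi")))
}

#' Run the cross-validated experiment
#'
#' For each fold: trains a freshly initialized network on the training ids
#' (validation ids are loss monitoring only; final-epoch weights are used),
#' predicts every test id by tiled inference, and scores global and per-ROI
#' metrics. Low-dose participants are flagged so that normal-dose and
#' low-dose aggregates can be reported separately.
#'
#' @param cases Named list of `phantom_case`s (names = ids).
#' @param manifest Cohort manifest tibble.
#' @param net_cfg A [network_config()].
#' @param train_cfg A [training_config()]; each fold trains with seed
#'   `train_cfg$seed + fold_index` for fresh weights per fold.
#' @param k Number of folds (ignored when `folds` is supplied).
#' @param sizes Optional strict fold sizes, see [make_folds()].
#' @param seed Seed for fold construction.
#' @param folds Optional precomputed fold tibble.
#' @param truth Evaluation reference, see [evaluate_cases()].
#' @param reference_label Reference-region atlas label.
#' @param tile_input Optional tile input shape.
#' @param verbose Print progress.
#' @return An `experiment_report`: list with `per_participant`, `roi`,
#'   `history` tibbles and the `folds` used.
#' @export
run_crossval <- function(cases, manifest, net_cfg, train_cfg, k = 10L,
                         sizes = NULL, seed = 1L, folds = NULL,
                         truth = c("clean", "noisy"), reference_label = 1L,
                         tile_input = NULL, verbose = FALSE) {
  truth <- match.arg(truth)
  if (is.null(folds)) folds <- make_folds(manifest, k, sizes, seed)
  fold_ids <- unique(folds$fold)
  pp <- list(); rr <- list(); hh <- list()
  for (fi in seq_along(fold_ids)) {
    f <- fold_ids[fi]
    sp <- fold_split(folds, f)
    if (length(intersect(sp$train, sp$test)) || length(intersect(sp$train, sp$validation)))
      stop(sprintf("fold %s: leakage between id sets", f), call. = FALSE)
    if (verbose) message(sprintf("fold %s: training on %d, validating on %d, testing on %d",
                                 f, length(sp$train), length(sp$validation), length(sp$test)))
    prep <- function(ids) purrr::map(cases[ids], prepare_case,
                                     reference_label = reference_label, truth = "noisy")
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + fi
    fit <- tryCatch(
      train(prep(sp$train), net_cfg, cfg_f, val_pairs = prep(sp$validation)),
      error = function(e) stop(sprintf("fold %s failed during training: %s", f,
                                       conditionMessage(e)), call. = FALSE))
    ev <- tryCatch(
      evaluate_cases(fit$model, cases[sp$test], truth = truth,
                     reference_label = reference_label, tile_input = tile_input),
      error = function(e) stop(sprintf("fold %s failed during scoring: %s", f,
                                       conditionMessage(e)), call. = FALSE))
    low <- manifest$low_dose[match(ev$metrics$id, manifest$id)]
    pp[[fi]] <- dplyr::mutate(ev$metrics, fold = f, low_dose = low, .before = 1)
    rr[[fi]] <- dplyr::mutate(ev$roi, fold = f,
                              low_dose = manifest$low_dose[match(ev$roi$id, manifest$id)],
                              .before = 1)
    hh[[fi]] <- dplyr::mutate(fit$history, fold = f, .before = 1)
  }
  structure(list(per_participant = dplyr::bind_rows(pp),
                 roi = dplyr::bind_rows(rr),
                 history = dplyr::bind_rows(hh),
                 folds = folds),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d folds, %d test evaluations\n",
              length(unique(x$per_participant$fold)), nrow(x$per_participant)))
  print(report_group_table(x))
  invisible(x)
}

#' @rdname run_crossval
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @export
tidy.experiment_report <- function(x, ...) x$per_participant

#' @rdname run_crossval
#' @export
glance.experiment_report <- function(x, ...) {
  norm <- x$per_participant[!x$per_participant$low_dose, ]
  tibble::tibble(n_folds = length(unique(x$per_participant$fold)),
                 n_tested = nrow(x$per_participant),
                 mean_bias = mean(norm$percent_bias), mean_mse = mean(norm$mse),
                 mean_ssim = mean(norm$ssim), mean_pearson = mean(norm$pearson))
}

#' Group-aggregate metric table
#'
#' Mean +/- SD of the global metrics by diagnosis, computed over normal-dose
#' test evaluations by default or over low-dose ones with
#' `low_dose = TRUE` (the two never mix).
#'
#' @param report An `experiment_report`.
#' @param low_dose Aggregate the low-dose evaluations instead.
#' @return Tibble with one row per diagnosis plus `"All"`.
#' @export
report_group_table <- function(report, low_dose = FALSE) {
  d <- report$per_participant[report$per_participant$low_dose == low_dose, ]
  if (!nrow(d)) stop("no evaluations in the requested dose stratum", call. = FALSE)
  aggregate_metrics(d, diagnosis)
}

#' Per-ROI aggregate table
#'
#' Mean +/- SD of percentage bias and SSIM per ROI over test evaluations in
#' the chosen dose stratum.
#'
#' @param report An `experiment_report`.
#' @param low_dose Aggregate the low-dose evaluations instead.
#' @return Tibble with one row per ROI.
#' @export
report_roi_table <- function(report, low_dose = FALSE) {
  d <- report$roi[report$roi$low_dose == low_dose & !report$roi$empty, ]
  if (!nrow(d)) stop("no ROI rows in the requested dose stratum", call. = FALSE)
  d |>
    dplyr::group_by(label, name) |>
    dplyr::summarise(n = dplyr::n(),
                     bias_mean = mean(percent_bias), bias_sd = stats::sd(percent_bias),
                     ssim_mean = mean(ssim), ssim_sd = stats::sd(ssim),
                     .groups = "drop")
}

#' Denoising comparison on low-dose cases
#'
#' For each case carrying both clean and noisy BPND (synthetic data), compares
#' the measured-noisy DVR and the model prediction against the noiseless DVR
#' reference by within-mask MSE.
#'
#' @param model A `dvr_network`.
#' @param cases List of `phantom_case`s with `bpnd_clean` present.
#' @param reference_label Reference-region atlas label.
#' @param tile_input Optional tile input shape.
#' @param tile_margin Optional overlap-tile margin (see [predict_case()]).
#' @return Tibble: `id`, `dose`, `mse_noisy_vs_clean`, `mse_pred_vs_clean`,
#'   `improved`.
#' @export
denoising_comparison <- function(model, cases, reference_label = 1L,
                                 tile_input = NULL, tile_margin = NULL) {
  purrr::map(cases, function(case) {
    if (is.null(case$bpnd_clean))
      stop(sprintf("case %s lacks a noiseless reference", case$id), call. = FALSE)
    clean <- prepare_case(case, reference_label, truth = "clean")
    noisy <- prepare_case(case, reference_label, truth = "noisy")
    pred <- predict_case(model, case, tile_input = tile_input,
                         tile_margin = tile_margin)
    tibble::tibble(id = case$id, dose = case$dose,
                   mse_noisy_vs_clean = vol_mse(clean$target, noisy$target, clean$mask),
                   mse_pred_vs_clean = vol_mse(clean$target, pred, clean$mask)) |>
      dplyr::mutate(improved = mse_pred_vs_clean < mse_noisy_vs_clean)
  }) |> dplyr::bind_rows()
}

#' Select an overlap-tile margin on validation cases
#'
#' Scores whole-volume predictions of the validation cases against their
#' measured (noisy) DVR — the only reference available with real data — for
#' each candidate margin and returns the margin with the lowest mean MSE.
#' A standard model-selection step: only training-side data are used.
#'
#' @param model A trained `dvr_network`.
#' @param val_cases List of validation `phantom_case`s.
#' @param margins Candidate margins (default 3, 5, 7, 9).
#' @param reference_label Reference-region atlas label.
#' @param tile_input Optional tile input shape.
#' @return The selected margin (integer), with the score table as attribute
#'   `scores`.
#' @export
select_tile_margin <- function(model, val_cases, margins = c(3L, 5L, 7L, 9L),
                               reference_label = 1L, tile_input = NULL) {
  scores <- purrr::map_dbl(margins, function(mg) {
    mean(purrr::map_dbl(val_cases, function(case) {
      prep <- prepare_case(case, reference_label, truth = "noisy")
      pred <- predict_case(model, case, tile_input = tile_input,
                           tile_margin = mg)
      vol_mse(prep$target, pred, prep$mask)
    }))
  })
  out <- margins[which.min(scores)]
  attr(out, "scores") <- tibble::tibble(margin = margins, val_mse = scores)
  out
}
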