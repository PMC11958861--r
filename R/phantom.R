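#' Parameters of the synthetic phantom generator
#'
#' Phantoms are nested-ellipsoid heads: a ventricular CSF core, a white-matter
#' shell, a gray-matter ribbon with mild angular thickness modulation (so
#' volumes carry spatial structure beyond radial symmetry), and an outer CSF
#' rim. Synaptic density (a BPND analog) is a linear function of local
#' gray-matter density; voxel noise scales as `noise_scale / sqrt(dose)`, the
#' count-statistics analogy for injected activity.
#'
#' @param shape Integer length-3, grid size in voxels (each axis >= 16 so the
#'   head ellipsoid fits).
#' @param voxel_size Numeric length-3, mm per axis.
#' @param n_rois Number of non-cerebellar wedge ROIs in the toy atlas.
#' @param gm_to_sv2a_gain Slope mapping gray-matter density to BPND (> 0).
#' @param base_bpnd Baseline BPND inside the head (>= 0).
#' @param noise_scale Voxel noise SD at unit dose (>= 0).
#' @param t1_noise_sd Additive Gaussian noise SD on the T1-like intensity.
#' @param seed Integer seed; phantom generation is deterministic given
#'   `(seed, id)`.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(shape = c(64, 64, 64), voxel_size = c(2, 2, 2),
                           n_rois = 11L, gm_to_sv2a_gain = 3.5,
                           base_bpnd = 0.5, noise_scale = 0.6,
                           t1_noise_sd = 0.02, seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(shape <= 0)) stop("`shape` must be positive on all axes", call. = FALSE)
  if (any(shape < 16)) stop("`shape` too small to contain the head ellipsoid (need >= 16 voxels per axis)", call. = FALSE)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive", call. = FALSE)
  if (gm_to_sv2a_gain <= 0) stop("`gm_to_sv2a_gain` must be > 0", call. = FALSE)
  if (base_bpnd < 0) stop("`base_bpnd` must be >= 0", call. = FALSE)
  if (noise_scale < 0) stop("`noise_scale` must be >= 0", call. = FALSE)
  if (n_rois < 1) stop("`n_rois` must be >= 1", call. = FALSE)
  structure(list(shape = shape, voxel_size = voxel_size, n_rois = as.integer(n_rois),
                 gm_to_sv2a_gain = gm_to_sv2a_gain, base_bpnd = base_bpnd,
                 noise_scale = noise_scale, t1_noise_sd = t1_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

.dvr_wedge_names <- c("frontal", "insula", "hippocampus", "amygdala",
                      "occipital", "parietal", "precuneus", "putamen",
                      "pallidum", "temporal", "anterior_cingulate")

#' ROI label table of the toy atlas
#'
#' Label 1 is the cerebellum-analog reference region (the inferior cap of the
#' head ellipsoid); the remaining labels are azimuthal wedges named after the
#' cortical/subcortical regions reported in the source study's ROI tables.
#'
#' @param n_rois Number of wedge ROIs (default 11).
#' @return Tibble with columns `label`, `name`, `reference`.
#' @export
roi_table <- function(n_rois = 11L) {
  nm <- if (n_rois == length(.dvr_wedge_names)) .dvr_wedge_names else
    sprintf("roi_%02d", seq_len(n_rois))
  tibble::tibble(label = seq_len(n_rois + 1L),
                 name = c("cerebellum", nm),
                 reference = c(TRUE, rep(FALSE, n_rois)))
}

#' Diagnosis-specific regional effect
#'
#' @param diagnosis One of `"HC"`, `"SZ"`, `"AD"`, `"CUD"`.
#' @param regional_sv2a_multipliers Named numeric vector in (0, 1], names are
#'   ROI names; unnamed ROIs keep multiplier 1 (no effect).
#' @param atrophy_factor Global gray-matter density shrink factor in (0, 1];
#'   lost GM probability is reassigned to CSF so structural and synaptic
#'   changes co-vary.
#' @return A `disease_effect` list.
#' @export
disease_effect <- function(diagnosis, regional_sv2a_multipliers = numeric(0),
                           atrophy_factor = 1) {
  diagnosis <- match.arg(diagnosis, c("HC", "SZ", "AD", "CUD"))
  m <- regional_sv2a_multipliers
  if (length(m) && (is.null(names(m)) || any(!nzchar(names(m)))))
    stop("`regional_sv2a_multipliers` must be a named vector of ROI names", call. = FALSE)
  if (any(m <= 0) || any(m > 1))
    stop("regional multipliers must lie in (0, 1]", call. = FALSE)
  if (atrophy_factor <= 0 || atrophy_factor > 1)
    stop("`atrophy_factor` must lie in (0, 1]", call. = FALSE)
  if (diagnosis == "HC" && (length(m) && any(m != 1) || atrophy_factor != 1))
    stop("the HC effect must be the identity", call. = FALSE)
  structure(list(diagnosis = diagnosis,
                 regional_sv2a_multipliers = m,
                 atrophy_factor = atrophy_factor),
            class = "disease_effect")
}

#' Default diagnosis effects
#'
#' Healthy controls are the identity. AD carries the strongest, spatially
#' widespread reductions (hippocampal/temporal analogs strictly < 1) plus
#' gray-matter atrophy; SZ and CUD carry milder frontal/limbic reductions.
#' Effect sizes for SZ/CUD are configurable defaults, not quantitative claims
#' about the disorders.
#'
#' @return Named list of [disease_effect()] objects for HC, SZ, AD, CUD.
#' @export
disease_effects <- function() {
  list(
    HC = disease_effect("HC"),
    SZ = disease_effect("SZ",
      c(frontal = 0.92, anterior_cingulate = 0.92, hippocampus = 0.95),
      atrophy_factor = 0.98),
    AD = disease_effect("AD",
      c(hippocampus = 0.78, temporal = 0.85, amygdala = 0.85,
        frontal = 0.90, parietal = 0.90, precuneus = 0.88),
      atrophy_factor = 0.92),
    CUD = disease_effect("CUD",
      c(hippocampus = 0.90, frontal = 0.92),
      atrophy_factor = 0.99)
  )
}

# deterministic 31-ary string hash into [0, 2^31 - 59)
id_hash <- function(id) {
  codes <- utf8ToInt(as.character(id))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483589
  h
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# per-voxel normalized coordinate arrays for an ellipsoid with semi-axes a (voxels)
.coord_arrays <- function(shape, centre, a) {
  s1 <- shape[1]; s2 <- shape[2]; s3 <- shape[3]
  xn <- array((seq_len(s1) - centre[1]) / a[1], dim = shape)
  yn <- aperm(array((seq_len(s2) - centre[2]) / a[2], dim = c(s2, s1, s3)), c(2, 1, 3))
  zn <- aperm(array((seq_len(s3) - centre[3]) / a[3], dim = c(s3, s1, s2)), c(2, 3, 1))
  list(xn = xn, yn = yn, zn = zn)
}

#' Generate one synthetic participant
#'
#' Deterministic given `(params$seed, id)`: the same call yields bit-identical
#' volumes. The clean BPND volume is
#' `base_bpnd + gm_to_sv2a_gain * GM * multiplier(ROI)` inside the head; the
#' noisy BPND adds Gaussian voxel noise with SD `noise_scale / sqrt(dose)`,
#' clipped at zero.
#'
#' @param params A [phantom_params()] object.
#' @param effect A [disease_effect()] object.
#' @param dose Injected-dose analog in mCi (> 0).
#' @param id Participant identifier (any string/number).
#' @return A `phantom_case`: list with elements `id`, `diagnosis`, `dose`,
#'   `t1`, `bpnd_clean`, `bpnd_noisy`, `segments` (list gm/wm/csf), `atlas`,
#'   `rois` (label table), `params`.
#' @export
make_phantom <- function(params, effect, dose, id) {
  stopifnot(inherits(params, "phantom_params"), inherits(effect, "disease_effect"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("`dose` must be a single positive number", call. = FALSE)
  shape <- params$shape
  case_seed <- (params$seed %% 2147483589) * 1009 + id_hash(id)
  case_seed <- as.integer(case_seed %% 2147483589)

  with_seed(case_seed, {
    # per-subject anatomy jitter: semi-axes and gm ribbon modulation phase
    jit <- 1 + 0.03 * stats::rnorm(3)
    centre <- (shape + 1) / 2
    a <- 0.44 * shape * pmax(0.9, pmin(1.1, jit))
    co <- .coord_arrays(shape, centre, a)
    r <- sqrt(co$xn^2 + co$yn^2 + co$zn^2)
    theta <- atan2(co$yn, co$xn)
    psi <- atan2(co$zn, sqrt(co$xn^2 + co$yn^2))
    phase <- stats::runif(1, 0, 2 * pi)

    w <- 0.035
    head <- (r < 1.0) * 1
    gm_outer <- 0.90 + 0.025 * sin(3 * theta + phase) * cos(2 * psi)
    vent <- stats::plogis((0.20 - r) / w)
    wm <- stats::plogis((r - 0.20) / w) * stats::plogis((0.62 - r) / w)
    gm <- stats::plogis((r - 0.62) / w) * stats::plogis((gm_outer - r) / w)
    csf <- vent + stats::plogis((r - gm_outer) / w) * stats::plogis((0.99 - r) / w)
    tot <- gm + wm + csf
    f <- pmax(tot, 1)
    gm <- gm / f * head; wm <- wm / f * head; csf <- csf / f * head

    # atrophy: GM loss becomes CSF, so T1 and BPND co-vary with diagnosis
    af <- effect$atrophy_factor
    csf <- csf + (1 - af) * gm
    gm <- gm * af

    # toy atlas: inferior cap = cerebellum (label 1), azimuthal wedges otherwise
    rois <- roi_table(params$n_rois)
    atlas <- array(0L, dim = shape)
    inside <- head > 0
    wedge <- 2L + pmin(params$n_rois - 1L,
                       as.integer(floor((theta + pi) / (2 * pi) * params$n_rois)))
    lab <- ifelse(psi < -0.9, 1L, wedge)
    atlas[inside] <- lab[inside]

    # regional SV2A multipliers by atlas label
    mult_by_label <- rep(1, nrow(rois) + 1L)  # index = label + 1 (label 0 = background)
    if (length(effect$regional_sv2a_multipliers)) {
      nm <- names(effect$regional_sv2a_multipliers)
      unknown <- setdiff(nm, rois$name)
      if (length(unknown))
        stop(sprintf("unknown ROI names in effect: %s", paste(unknown, collapse = ", ")), call. = FALSE)
      idx <- match(nm, rois$name)
      mult_by_label[rois$label[idx] + 1L] <- effect$regional_sv2a_multipliers
    }
    mult <- array(mult_by_label[atlas + 1L], dim = shape)

    bpnd_clean <- head * (params$base_bpnd + params$gm_to_sv2a_gain * gm * mult)

    noise_sd <- params$noise_scale / sqrt(dose)
    noise <- array(stats::rnorm(prod(shape), 0, noise_sd), dim = shape)
    bpnd_noisy <- head * pmax(bpnd_clean + noise, 0)

    # T1: per-tissue intensity mixture x smooth bias field + Gaussian noise
    bcoef <- stats::rnorm(3, 0, 1)
    bias <- 1 + 0.05 * (bcoef[1] * co$xn + bcoef[2] * co$yn + bcoef[3] * co$zn)
    t1 <- head * pmax((1.0 * wm + 0.7 * gm + 0.25 * csf) * bias +
                        array(stats::rnorm(prod(shape), 0, params$t1_noise_sd), dim = shape), 0)

    vs <- params$voxel_size
    structure(list(
      id = as.character(id), diagnosis = effect$diagnosis, dose = dose,
      t1 = as_volume(t1, vs),
      bpnd_clean = as_volume(bpnd_clean, vs),
      bpnd_noisy = as_volume(bpnd_noisy, vs),
      segments = list(gm = as_volume(gm, vs), wm = as_volume(wm, vs),
                      csf = as_volume(csf, vs)),
      atlas = as_volume(array(as.numeric(atlas), dim = shape), vs),
      rois = rois, params = params
    ), class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s  diagnosis=%s  dose=%.2f mCi  grid %s\n",
              x$id, x$diagnosis, x$dose, paste(dim(x$t1), collapse = "x")))
  invisible(x)
}

#' Generate a synthetic cohort with a manifest
#'
#' Diagnosis counts match `diagnosis_ratio` exactly. `n_low_dose` participants
#' are flagged low-dose with doses drawn below `low_dose_threshold`; the
#' remainder draw from a truncated normal dose distribution (defaults match
#' the source cohort: mean 15.71, SD 4.32 mCi).
#'
#' @param params A [phantom_params()] object.
#' @param n Cohort size.
#' @param diagnosis_ratio Named integer vector (names in HC/SZ/AD/CUD) summing
#'   to `n`.
#' @param n_low_dose Number of low-dose participants (<= n).
#' @param seed Integer seed for the cohort (overrides `params$seed` so the
#'   whole cohort is reproducible from one number).
#' @param low_dose_threshold Dose threshold in mCi (default 5).
#' @param normal_dose_mean,normal_dose_sd Dose distribution of normal-dose
#'   participants.
#' @param effects Named list of [disease_effect()]s, one per diagnosis.
#' @param generate Generate the image volumes (`TRUE`); with `FALSE` only the
#'   manifest is built (useful for experiment-design work on large cohorts).
#' @return List with `cases` (named list of `phantom_case`, or `NULL` when
#'   `generate = FALSE`) and `manifest` (tibble: `id`, `diagnosis`,
#'   `dose_mCi`, `low_dose`).
#' @export
make_cohort <- function(params, n, diagnosis_ratio, n_low_dose = 0L,
                        seed = params$seed, low_dose_threshold = 5,
                        normal_dose_mean = 15.71, normal_dose_sd = 4.32,
                        effects = disease_effects(), generate = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  diagnosis_ratio <- diagnosis_ratio[diagnosis_ratio > 0]
  if (is.null(names(diagnosis_ratio)) || !all(names(diagnosis_ratio) %in% names(effects)))
    stop("`diagnosis_ratio` must be named with known diagnoses", call. = FALSE)
  if (sum(diagnosis_ratio) != n)
    stop(sprintf("`diagnosis_ratio` sums to %d but n = %d", sum(diagnosis_ratio), n), call. = FALSE)
  if (n_low_dose > n) stop("`n_low_dose` must be <= n", call. = FALSE)

  params$seed <- as.integer(seed)
  manifest <- with_seed(as.integer(seed), {
    ids <- sprintf("sub-%03d", seq_len(n))
    diag <- sample(rep(names(diagnosis_ratio), times = diagnosis_ratio))
    low_ids <- if (n_low_dose > 0) sample(ids, n_low_dose) else character(0)
    low <- ids %in% low_ids
    dose <- numeric(n)
    for (i in seq_len(n)) {
      if (low[i]) {
        dose[i] <- stats::runif(1, min = max(0.5, low_dose_threshold / 3),
                                max = low_dose_threshold - 0.25)
      } else {
        d <- stats::rnorm(1, normal_dose_mean, normal_dose_sd)
        while (d < low_dose_threshold) d <- stats::rnorm(1, normal_dose_mean, normal_dose_sd)
        dose[i] <- d
      }
    }
    tibble::tibble(id = ids, diagnosis = diag, dose_mCi = dose, low_dose = low)
  })
  if (!generate) return(list(cases = NULL, manifest = manifest))
  cases <- purrr::pmap(manifest, function(id, diagnosis, dose_mCi, low_dose) {
    make_phantom(params, effects[[diagnosis]], dose_mCi, id)
  })
  names(cases) <- manifest$id
  list(cases = cases, manifest = manifest)
}

#' Write a cohort to disk
#'
#' Lays each case out as a per-participant directory of NIfTI volumes
#' (`t1.nii.gz`, `bpnd_clean.nii.gz`, `bpnd_noisy.nii.gz`, `gm/wm/csf.nii.gz`,
#' `atlas.nii.gz`) with a tab-delimited `manifest.tsv` and `rois.tsv`; the
#' same layout accepted for externally supplied, pre-aligned real data.
#'
#' @param cohort A list as returned by [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$cases[[1]]$rois, file.path(dir, "rois.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (case in cohort$cases) {
    d <- file.path(dir, case$id)
    dir.create(d, showWarnings = FALSE)
    write_volume(case$t1, file.path(d, "t1.nii.gz"))
    write_volume(case$bpnd_clean, file.path(d, "bpnd_clean.nii.gz"))
    write_volume(case$bpnd_noisy, file.path(d, "bpnd_noisy.nii.gz"))
    write_volume(case$segments$gm, file.path(d, "gm.nii.gz"))
    write_volume(case$segments$wm, file.path(d, "wm.nii.gz"))
    write_volume(case$segments$csf, file.path(d, "csf.nii.gz"))
    write_volume(case$atlas, file.path(d, "atlas.nii.gz"))
  }
  invisible(dir)
}

#' Read a cohort from disk
#'
#' @param dir Directory written by [write_cohort()] (or externally supplied
#'   data in the same layout).
#' @return List with `cases` and `manifest`, as in [make_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.delim(file.path(dir, "manifest.tsv")))
  rois <- tibble::as_tibble(utils::read.delim(file.path(dir, "rois.tsv")))
  cases <- purrr::pmap(manifest, function(id, diagnosis, dose_mCi, low_dose) {
    d <- file.path(dir, id)
    rd <- function(f) read_volume(file.path(d, f))
    structure(list(
      id = as.character(id), diagnosis = diagnosis, dose = dose_mCi,
      t1 = rd("t1.nii.gz"),
      bpnd_clean = if (file.exists(file.path(d, "bpnd_clean.nii.gz"))) rd("bpnd_clean.nii.gz") else NULL,
      bpnd_noisy = rd("bpnd_noisy.nii.gz"),
      segments = list(gm = rd("gm.nii.gz"), wm = rd("wm.nii.gz"), csf = rd("csf.nii.gz")),
      atlas = rd("atlas.nii.gz"), rois = rois, params = NULL
    ), class = "phantom_case")
  })
  names(cases) <- manifest$id
  list(cases = cases, manifest = manifest)
}
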