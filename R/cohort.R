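#' Synthetic cohort configuration
#'
#' Collects every parameter of the synthetic study: cohort sizes, the age
#' range, per-modality atlas geometry and voxel signal model, and the
#' pathology (accelerated-aging) effects injected into the patient group.
#' Defaults emulate the study design the package targets: a training cohort
#' of 230 healthy controls aged 20-84, test cohorts of 100 controls and 194
#' patients, and 90 GM / 90 FC / 48 FA region maps per subject.
#'
#' The voxel signal model: within each region a fixed `signal_fraction`
#' subset of voxels has expectation `baseline + signal_slope * age`; the
#' remaining voxels are pure noise around `baseline`. Default slopes and
#' noise levels give informative voxels a population age correlation of
#' about |r| = 0.6 under the uniform 20-84 age distribution
#' (r = slope*sd_age / sqrt(slope^2*sd_age^2 + noise_sd^2)).
#'
#' @param n_hc_train healthy controls in the training cohort.
#' @param n_hc_test healthy controls in the test cohort.
#' @param n_scz patients in the test cohort.
#' @param age_range numeric length-2, years; ages are drawn uniformly.
#' @param voxels_per_region voxels per atlas region (all modalities).
#' @param n_regions named list of region counts per modality.
#' @param signal_fraction fraction of voxels per region carrying age signal.
#' @param signal_params named list per modality with `baseline`,
#'   `signal_slope` (units/year) and `noise_sd` (units). GM values are tissue
#'   intensity (a.u.), FC values Fisher-z units, FA dimensionless in [0, 1].
#' @param effect_spec `NULL`, or a data frame with columns `modality`,
#'   `region_id`, `gap_years` giving the brain-age-gap offset injected into
#'   patient maps of those regions.
#' @param duration_scaled logical; if `TRUE` the injected offset is scaled by
#'   each patient's illness duration relative to the cohort mean duration.
#' @param bold parameters of the synthetic BOLD generator (see
#'   [generate_bold()]): `n_time`, `tr` (s), `weight_base`, `weight_slope`
#'   (/year), `idio_sd`, `freq_band` (Hz).
#' @param seed master seed; every stage derives sub-streams from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_hc_train = 230L,
                             n_hc_test = 100L,
                             n_scz = 194L,
                             age_range = c(20, 84),
                             voxels_per_region = 200L,
                             n_regions = list(GM = 90L, FC = 90L, FA = 48L),
                             signal_fraction = 0.2,
                             signal_params = list(
                               GM = list(baseline = 0.60, signal_slope = -0.005, noise_sd = 0.125),
                               FC = list(baseline = 0.30, signal_slope = -0.003, noise_sd = 0.075),
                               FA = list(baseline = 0.70, signal_slope = -0.002, noise_sd = 0.050)
                             ),
                             effect_spec = NULL,
                             duration_scaled = FALSE,
                             bold = list(n_time = 120L, tr = 2, weight_base = 1,
                                         weight_slope = -0.01, idio_sd = 1,
                                         freq_band = c(0.01, 0.1)),
                             seed = 1L) {
  if (length(age_range) != 2L || !is.numeric(age_range) ||
      age_range[1] >= age_range[2]) {
    stop("age_range must be two increasing numbers (years)", call. = FALSE)
  }
  counts <- c(n_hc_train = n_hc_train, n_hc_test = n_hc_test, n_scz = n_scz)
  if (any(counts < 0) || n_hc_train <= 0) {
    stop("cohort sizes must be nonnegative and n_hc_train positive",
         call. = FALSE)
  }
  stop_if_not_scalar_prob(signal_fraction, "signal_fraction")
  for (m in names(n_regions)) {
    if (n_regions[[m]] <= 0L) stop("region counts must be positive", call. = FALSE)
  }
  if (!is.null(effect_spec)) {
    need <- c("modality", "region_id", "gap_years")
    if (!is.data.frame(effect_spec) || !all(need %in% names(effect_spec))) {
      stop("effect_spec must be a data frame with columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_hc_train = as.integer(n_hc_train),
         n_hc_test = as.integer(n_hc_test),
         n_scz = as.integer(n_scz),
         age_range = as.numeric(age_range),
         voxels_per_region = as.integer(voxels_per_region),
         n_regions = n_regions,
         signal_fraction = signal_fraction,
         signal_params = signal_params,
         effect_spec = effect_spec,
         duration_scaled = isTRUE(duration_scaled),
         bold = bold,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate the synthetic subject table
#'
#' Draws demographics and clinical covariates for the training controls, the
#' test controls and the patient group. Ages are uniform over the configured
#' range in every cohort. Clinical fields (illness duration, age of onset,
#' PANSS subscales, chlorpromazine-equivalent dose, nicotine use) are drawn
#' only for patients; controls carry `NA` there. Covariate distributions
#' follow the published cohort summaries (MMSE 29.0 +/- 1.0 in controls vs
#' 26.8 +/- 3.4 in patients, education 15.9 +/- 3.7 vs 12.5 +/- 3.6 years,
#' duration 15.6 +/- 10.3 years, CPZ dose 402 +/- 324 mg/day available for
#' about two thirds of patients), drawn independently of age.
#'
#' @param config a [synthetic_config()].
#' @return data frame with one row per subject: `subject_id`,
#'   `chronological_age`, `sex` ("M"/"F"), `group` ("HC"/"SCZ"), `cohort`
#'   ("train"/"test"), `mmse`, `education`, `illness_duration`,
#'   `age_of_onset`, `panss_positive`, `panss_negative`, `panss_general`,
#'   `cpz_dose`, `nicotine_use`, `bmi`.
#' @export
generate_subjects <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(substream_seed(config$seed, "subjects"), {
    lo <- config$age_range[1]; hi <- config$age_range[2]
    make_hc <- function(n, cohort, prefix) {
      if (n == 0L) return(NULL)
      data.frame(
        subject_id = sprintf("%s%04d", prefix, seq_len(n)),
        chronological_age = runif(n, lo, hi),
        sex = ifelse(runif(n) < 0.40, "M", "F"),
        group = "HC",
        cohort = cohort,
        mmse = pmin(30, pmax(0, round(rnorm(n, 29.0, 0.98)))),
        education = round(rnorm_trunc(n, 15.89, 3.67, lower = 6, upper = 25), 1),
        illness_duration = NA_real_,
        age_of_onset = NA_real_,
        panss_positive = NA_real_,
        panss_negative = NA_real_,
        panss_general = NA_real_,
        cpz_dose = NA_real_,
        nicotine_use = runif(n) < 0.12,
        bmi = round(rnorm_trunc(n, 23.35, 3.25, lower = 14, upper = 45), 1),
        stringsAsFactors = FALSE
      )
    }
    hc_train <- make_hc(config$n_hc_train, "train", "TRN")
    hc_test <- make_hc(config$n_hc_test, "test", "HC")
    scz <- NULL
    if (config$n_scz > 0L) {
      n <- config$n_scz
      age <- runif(n, max(lo, 20), hi)
      # onset after age 13 and before scan; duration = age - onset exactly
      duration <- rnorm_trunc(n, 15.56, 10.30, lower = 0)
      duration <- pmin(duration, age - 13)
      duration <- pmax(duration, 0)
      has_dose <- runif(n) < 161 / 244
      scz <- data.frame(
        subject_id = sprintf("SCZ%04d", seq_len(n)),
        chronological_age = age,
        sex = ifelse(runif(n) < 0.44, "M", "F"),
        group = "SCZ",
        cohort = "test",
        mmse = pmin(30, pmax(0, round(rnorm(n, 26.81, 3.39)))),
        education = round(rnorm_trunc(n, 12.50, 3.55, lower = 0, upper = 25), 1),
        illness_duration = duration,
        age_of_onset = age - duration,
        panss_positive = round(rnorm_trunc(n, 10.74, 3.37, lower = 7, upper = 49)),
        panss_negative = round(rnorm_trunc(n, 10.04, 3.76, lower = 7, upper = 49)),
        panss_general = round(rnorm_trunc(n, 21.26, 5.18, lower = 16, upper = 112)),
        cpz_dose = ifelse(has_dose,
                          round(rnorm_trunc(n, 402.42, 324.27, lower = 25), 1),
                          NA_real_),
        nicotine_use = runif(n) < 0.335,
        bmi = round(rnorm_trunc(n, 25.10, 4.40, lower = 14, upper = 45), 1),
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(hc_train, hc_test, scz)
    rownames(out) <- NULL
    out
  })
}

#' Generate per-region voxel maps for a cohort
#'
#' For every subject and atlas region, draws a voxel-value vector following
#' the configured signal model: a fixed subset of voxels (the "informative"
#' voxels, `signal_fraction` of the region, identical across subjects) has
#' expectation `baseline + signal_slope * age`; all other voxels are
#' `baseline` plus noise. FA values are clipped to [0, 1]. The indices of the
#' informative voxels are returned as machine-readable ground truth.
#'
#' @param subjects subject data frame (see [generate_subjects()]).
#' @param atlas a `regionage_atlas`.
#' @param config a [synthetic_config()].
#' @return object of class `region_maps`: list with `modality`, `atlas`,
#'   `subject_id`, `values` (named list: region id -> subjects x voxels
#'   matrix), `truth` (named list: region id -> informative voxel positions,
#'   1-based within the region's voxel order) and `signal` (the modality's
#'   signal parameters).
#' @export
generate_region_maps <- function(subjects, atlas, config) {
  stopifnot(inherits(atlas, "regionage_atlas"),
            inherits(config, "synthetic_config"))
  if (nrow(atlas$regions) == 0L) stop("atlas has no regions", call. = FALSE)
  m <- atlas$modality
  sp <- config$signal_params[[m]]
  if (is.null(sp)) stop("no signal parameters for modality ", m, call. = FALSE)
  n <- nrow(subjects)
  age <- subjects$chronological_age
  values <- vector("list", nrow(atlas$regions))
  truth <- vector("list", nrow(atlas$regions))
  names(values) <- names(truth) <- as.character(atlas$regions$region_id)
  for (k in seq_len(nrow(atlas$regions))) {
    rid <- atlas$regions$region_id[k]
    V <- atlas$regions$n_voxels[k]
    n_inf <- floor(config$signal_fraction * V)
    with_seed(substream_seed(config$seed, "maps", m, rid), {
      inf <- if (n_inf > 0L) sort(sample.int(V, n_inf)) else integer(0)
      mat <- matrix(sp$baseline + rnorm(n * V, 0, sp$noise_sd), n, V)
      if (n_inf > 0L) {
        mat[, inf] <- mat[, inf] + sp$signal_slope * age
      }
      if (m == "FA") mat <- pmin(pmax(mat, 0), 1) # arg order keeps dim attrs
      values[[k]] <- mat
      truth[[k]] <- inf
    })
  }
  structure(
    list(modality = m, atlas = atlas, subject_id = subjects$subject_id,
         values = values, truth = truth, signal = sp),
    class = "region_maps"
  )
}

#' Inject regional accelerated-aging effects into patient maps
#'
#' Shifts the informative voxels of the listed regions in patient (group
#' "SCZ") rows by the voxel-level equivalent of a brain-age-gap offset:
#' `offset = gap_years * signal_slope`. With `duration_scaled = TRUE` the
#' offset is further multiplied by `illness_duration / mean(illness_duration)`
#' so that longer-ill patients deviate more. Control maps are untouched. FA
#' values are re-clipped to [0, 1] after the shift.
#'
#' @param maps a `region_maps` object.
#' @param subjects the subject table the maps were generated for (same row
#'   order).
#' @param effect_spec data frame with columns `modality`, `region_id`,
#'   `gap_years`; rows for other modalities are ignored.
#' @param duration_scaled logical (see above).
#' @return the modified `region_maps`.
#' @export
inject_pathology <- function(maps, subjects, effect_spec,
                             duration_scaled = FALSE) {
  stopifnot(inherits(maps, "region_maps"))
  if (is.null(effect_spec) || nrow(effect_spec) == 0L) return(maps)
  es <- effect_spec[effect_spec$modality == maps$modality, , drop = FALSE]
  if (nrow(es) == 0L) return(maps)
  unknown <- setdiff(as.character(es$region_id), names(maps$values))
  if (length(unknown) > 0L) {
    stop("effect_spec names unknown region id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- which(subjects$group == "SCZ")
  if (length(rows) == 0L) return(maps)
  scale <- rep(1, length(rows))
  if (isTRUE(duration_scaled)) {
    dur <- subjects$illness_duration[rows]
    if (anyNA(dur)) stop("duration scaling needs illness_duration for all patients",
                         call. = FALSE)
    scale <- dur / mean(dur)
  }
  slope <- maps$signal$signal_slope
  for (i in seq_len(nrow(es))) {
    key <- as.character(es$region_id[i])
    inf <- maps$truth[[key]]
    if (length(inf) == 0L) next
    shift <- es$gap_years[i] * slope * scale
    maps$values[[key]][rows, inf] <-
      maps$values[[key]][rows, inf] + shift
    if (maps$modality == "FA") {
      maps$values[[key]][rows, inf] <-
        pmin(1, pmax(0, maps$values[[key]][rows, inf]))
    }
  }
  maps
}

#' Generate synthetic band-limited BOLD series for one cohort
#'
#' Emulates already-preprocessed resting-state series: every voxel is an
#' age-weighted copy of a shared band-limited latent signal (sum of
#' random-phase sinusoids inside `freq_band`, emulating lowpass-filtered
#' BOLD) plus idiosyncratic white noise. The common-signal weight
#' `weight_base + weight_slope * (age - mean age)` makes average pairwise
#' connectivity decline with age, so FC maps built from these series carry an
#' age signal.
#'
#' @param subjects subject data frame.
#' @param atlas a `regionage_atlas` (its labelled voxel count sets the voxel
#'   dimension).
#' @param config a [synthetic_config()] (fields under `config$bold`).
#' @return list with `series` (list per subject of voxels x time matrices,
#'   voxel order = concatenated atlas region order), `weights` (per-subject
#'   common-signal weight, the ground-truth mixing weight) and `subject_id`.
#' @export
generate_bold <- function(subjects, atlas, config) {
  stopifnot(inherits(atlas, "regionage_atlas"),
            inherits(config, "synthetic_config"))
  b <- config$bold
  n_time <- as.integer(b$n_time)
  if (n_time < 2L) stop("BOLD series needs at least 2 time points", call. = FALSE)
  V <- atlas_n_voxels(atlas)
  tt <- seq_len(n_time) * b$tr
  freqs <- seq(b$freq_band[1], b$freq_band[2], length.out = 8)
  n <- nrow(subjects)
  age_c <- subjects$chronological_age - mean(subjects$chronological_age)
  weights <- b$weight_base + b$weight_slope * age_c
  series <- vector("list", n)
  for (i in seq_len(n)) {
    with_seed(substream_seed(config$seed, "bold", i), {
      phase <- runif(length(freqs), 0, 2 * pi)
      s <- rowSums(sapply(seq_along(freqs),
                          function(j) sin(2 * pi * freqs[j] * tt + phase[j])))
      s <- (s - mean(s)) / stats::sd(s)
      noise <- matrix(rnorm(V * n_time, 0, b$idio_sd), V, n_time)
      series[[i]] <- weights[i] * matrix(s, V, n_time, byrow = TRUE) + noise
    })
  }
  names(series) <- subjects$subject_id
  list(series = series, weights = weights, subject_id = subjects$subject_id)
}
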