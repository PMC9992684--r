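#' Linear bias fit of predicted on chronological age
#'
#' Regression-to-the-mean makes raw brain-age predictions too young in old
#' subjects and too old in young ones. The correction models this as
#' `brain age = alpha * chronological age + beta` by ordinary least squares
#' on (chronological, predicted) pairs.
#'
#' @param predicted raw predicted ages (years).
#' @param chronological chronological ages (years).
#' @return named numeric vector `c(alpha, beta)` (slope, intercept).
#' @export
fit_bias <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("predicted and chronological must have equal length", call. = FALSE)
  }
  if (length(predicted) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(chronological) == 0) {
    stop("chronological ages are constant; bias fit undefined", call. = FALSE)
  }
  co <- stats::coef(stats::lm(predicted ~ chronological))
  c(alpha = unname(co[2]), beta = unname(co[1]))
}

#' Bias-correct raw brain-age predictions
#'
#' `corrected = raw + [chronological - (alpha * chronological + beta)]`,
#' element-wise. With (alpha, beta) fitted by [fit_bias()] on the same
#' sample, refitting predicted-on-chronological after correction gives slope
#' 1 and intercept 0.
#'
#' @param raw raw predicted ages (years).
#' @param chronological chronological ages (years).
#' @param alpha,beta bias coefficients from [fit_bias()].
#' @return corrected ages (years).
#' @export
correct_age <- function(raw, chronological, alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta)) {
    stop("alpha and beta must be finite", call. = FALSE)
  }
  raw + (chronological - (alpha * chronological + beta))
}

#' Brain-age gap
#'
#' `gap = corrected brain age - chronological age`; positive values mean
#' apparent accelerated aging.
#'
#' @param corrected corrected brain ages (years).
#' @param chronological chronological ages (years).
#' @return gaps (years).
#' @export
compute_gap <- function(corrected, chronological) {
  if (length(corrected) != length(chronological)) {
    stop("corrected and chronological must have equal length", call. = FALSE)
  }
  corrected - chronological
}

#' Prediction performance: MAE and Pearson correlation
#'
#' @param corrected corrected brain ages (years).
#' @param chronological chronological ages (years).
#' @return named numeric vector `c(mae, r)`.
#' @export
evaluate_predictions <- function(corrected, chronological) {
  if (length(corrected) != length(chronological)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (length(corrected) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(corrected) == 0 || stats::var(chronological) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  c(mae = mean(abs(corrected - chronological)),
    r = stats::cor(corrected, chronological))
}

#' Train one region's brain-age model
#'
#' Fits a Gaussian-process regressor of age on the region's selected voxel
#' features with k-fold cross-validation: out-of-fold predictions are
#' produced for every training subject, the bias coefficients (alpha, beta)
#' are fitted once on the pooled out-of-fold predictions, and CV performance
#' (MAE, Pearson r) is computed on the bias-corrected out-of-fold
#' predictions. The final regressor is refit on all subjects; the stored
#' (alpha, beta) are reused unchanged for every test cohort.
#'
#' @param features subjects x voxels matrix already restricted to the
#'   region's feature mask.
#' @param ages chronological ages (years).
#' @param k_folds folds (default 5).
#' @param seed seed for the random fold assignment.
#' @param modality,region_id carried into the result for bookkeeping.
#' @param mask optional `feature_mask` stored with the model.
#' @return object of class `region_age_model` with the fitted regressor,
#'   `alpha`, `beta`, `cv_mae`, `cv_r` (on corrected predictions),
#'   `raw_cv_mae`, `raw_cv_r` (on uncorrected predictions), `oof`
#'   (out-of-fold raw predictions) and fold assignment.
#'
#' @section A caution on corrected-age performance:
#' Because the correction adds `chronological - (alpha * chronological +
#' beta)` to the raw prediction, the corrected prediction equals
#' chronological age plus the out-of-fold regression residual. `cv_r` is
#' therefore high whenever that residual is small relative to the age
#' spread — including for an uninformative regressor whose predictions are
#' near-constant. Use `raw_cv_r` to judge how much age signal the features
#' themselves carry.
#' @export
train_region_model <- function(features, ages, k_folds = 5L, seed = 1L,
                               modality = NA_character_,
                               region_id = NA_integer_, mask = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  if (n < k_folds) stop("fewer subjects (", n, ") than folds (", k_folds, ")",
                        call. = FALSE)
  if (ncol(features) < 1L) stop("need at least 1 feature", call. = FALSE)
  if (length(ages) != n) stop("ages length must match rows", call. = FALSE)

  fold <- with_seed(substream_seed(seed, "folds"), {
    sample(rep_len(seq_len(k_folds), n))
  })
  oof <- rep(NA_real_, n)
  for (f in seq_len(k_folds)) {
    hold <- fold == f
    fit_f <- gpr_fit(features[!hold, , drop = FALSE], ages[!hold])
    oof[hold] <- predict(fit_f, features[hold, , drop = FALSE])
  }
  bias <- fit_bias(oof, ages)
  corrected <- correct_age(oof, ages, bias["alpha"], bias["beta"])
  perf <- evaluate_predictions(corrected, ages)
  # raw (uncorrected) CV statistics: unlike the corrected ones, these do not
  # inherit chronological age through the correction term, so they are the
  # honest measure of how much age signal the regressor itself captures
  raw_mae <- mean(abs(oof - ages))
  raw_r <- if (stats::var(oof) > 0) stats::cor(oof, ages) else 0
  final <- gpr_fit(features, ages)
  structure(
    list(modality = modality, region_id = region_id, mask = mask,
         regressor = final, alpha = unname(bias["alpha"]),
         beta = unname(bias["beta"]),
         cv_mae = unname(perf["mae"]), cv_r = unname(perf["r"]),
         raw_cv_mae = raw_mae, raw_cv_r = raw_r,
         oof = oof, fold = fold, k_folds = k_folds, n_train = n),
    class = "region_age_model"
  )
}

#' @export
print.region_age_model <- function(x, ...) {
  cat(sprintf(
    "<region_age_model> %s region %s: %d features, cv MAE %.2f y, cv r %.3f\n",
    x$modality, x$region_id, length(x$regressor$x_mean), x$cv_mae, x$cv_r))
  invisible(x)
}

#' Apply a trained region model to a cohort
#'
#' Produces raw GP predictions, corrects them with the model's stored
#' (alpha, beta) — never refit on test data — and attaches brain-age gaps.
#'
#' @param model a `region_age_model`.
#' @param features subjects x voxels matrix with the same columns the model
#'   was trained on.
#' @param subjects subject data frame (rows matching `features`).
#' @return data frame: `subject_id`, `modality`, `region_id`,
#'   `raw_brain_age`, `corrected_brain_age`, `brain_age_gap`.
#' @export
apply_model <- function(model, features, subjects) {
  stopifnot(inherits(model, "region_age_model"))
  if (!is.matrix(features)) features <- as.matrix(features)
  if (ncol(features) != length(model$regressor$x_mean)) {
    stop("feature columns (", ncol(features),
         ") do not match the model's mask (",
         length(model$regressor$x_mean), ")", call. = FALSE)
  }
  raw <- predict(model$regressor, features)
  chron <- subjects$chronological_age
  corrected <- correct_age(raw, chron, model$alpha, model$beta)
  data.frame(subject_id = subjects$subject_id,
             modality = model$modality,
             region_id = model$region_id,
             raw_brain_age = raw,
             corrected_brain_age = corrected,
             brain_age_gap = compute_gap(corrected, chron),
             stringsAsFactors = FALSE)
}
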