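#' Region-wise group comparison of brain-age gaps (ANCOVA)
#'
#' Tests the group difference in brain-age gaps with a linear model
#' `gap ~ group + covariates` (default covariates: chronological age, sex,
#' MMSE, education). The group F statistic comes from the extra sum of
#' squares of the group term (full vs group-dropped model) on (1, n - p - 2)
#' degrees of freedom, and the effect size is the partial eta-squared
#' `SS_group / (SS_group + SS_error)`.
#'
#' @param gaps numeric vector of brain-age gaps (years), one per subject.
#' @param subjects subject data frame with `group` and the covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty, giving the classical two-group comparison: F = t^2).
#' @return one-row data frame: `f_stat`, `p_value`, `partial_eta_sq`,
#'   `mean_gap_hc`, `mean_gap_scz`, `n_hc`, `n_scz`, `df1`, `df2`.
#' @export
ancova_gap <- function(gaps, subjects,
                       covariates = c("chronological_age", "sex", "mmse",
                                      "education")) {
  if (length(gaps) != nrow(subjects)) {
    stop("gaps length must match subjects rows", call. = FALSE)
  }
  groups <- unique(subjects$group)
  if (length(groups) != 2L) {
    stop("exactly two groups required, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(gap = gaps,
                    group = factor(subjects$group, levels = c("HC", "SCZ")))
  for (cv in covariates) {
    if (!cv %in% names(subjects)) stop("missing covariate column: ", cv,
                                       call. = FALSE)
    dat[[cv]] <- if (is.character(subjects[[cv]])) {
      factor(subjects[[cv]])
    } else {
      subjects[[cv]]
    }
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  if (stats::var(gaps) == 0) {
    # constant outcome: nothing to explain
    return(data.frame(f_stat = 0, p_value = 1, partial_eta_sq = 0,
                      mean_gap_hc = mean(gaps[subjects$group == "HC"]),
                      mean_gap_scz = mean(gaps[subjects$group == "SCZ"]),
                      n_hc = sum(subjects$group == "HC"),
                      n_scz = sum(subjects$group == "SCZ"),
                      df1 = 1L, df2 = NA_integer_))
  }
  full <- stats::lm(stats::as.formula(paste("gap ~ group +", rhs)), data = dat)
  if (anyNA(stats::coef(full))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("singular ANCOVA design; aliased terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reduced <- stats::lm(stats::as.formula(paste("gap ~", rhs)), data = dat)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  ss_group <- rss_red - rss_full
  df2 <- stats::df.residual(full)
  f <- (ss_group / 1) / (rss_full / df2)
  f <- max(f, 0)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  eta <- if (ss_group + rss_full > 0) ss_group / (ss_group + rss_full) else 0
  eta <- min(max(eta, 0), 1)
  data.frame(f_stat = f, p_value = p, partial_eta_sq = eta,
             mean_gap_hc = mean(gaps[subjects$group == "HC"]),
             mean_gap_scz = mean(gaps[subjects$group == "SCZ"]),
             n_hc = sum(subjects$group == "HC"),
             n_scz = sum(subjects$group == "SCZ"),
             df1 = 1L, df2 = df2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values: with p values sorted ascending,
#' `q_i = min_{j >= i} p_j * m / j`, capped at 1, returned in input order.
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @return adjusted p values, same order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# z-score continuous columns; binary/logical left as 0/1
standardize_columns <- function(df, cols) {
  for (cv in cols) {
    x <- df[[cv]]
    if (is.logical(x)) {
      df[[cv]] <- as.numeric(x)
    } else if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) > 2L) stop("cannot code multi-level column ", cv,
                                 call. = FALSE)
      df[[cv]] <- as.numeric(as.character(x) == lev[length(lev)])
    } else if (length(unique(x)) > 2L) {
      df[[cv]] <- as.numeric(scale(x))
    }
  }
  df
}

#' Regression of brain-age gaps on clinical characteristics (patients)
#'
#' One joint linear model per region over the patient group: the outcome is
#' the (z-scored) brain-age gap, the predictors are clinicodemographic
#' characteristics (PANSS subscales, illness duration, age of onset, history
#' of nicotine use, body-mass index by default), and chronological age and
#' sex enter as control variables. Continuous predictors and the outcome are
#' z-scored so coefficients are standardized betas; binary predictors stay
#' 0/1. Subjects with any missing predictor are dropped listwise (count
#' reported via message).
#'
#' @param gaps brain-age gaps for the patients (years).
#' @param subjects patient subject rows (group "SCZ").
#' @param predictors predictor column names.
#' @param controls control column names.
#' @return data frame, one row per predictor: `predictor`, `beta`, `t_stat`,
#'   `p_value`, `n_used`.
#' @export
clinical_regression <- function(gaps, subjects,
                                predictors = c("panss_positive",
                                               "panss_negative",
                                               "panss_general",
                                               "illness_duration",
                                               "age_of_onset",
                                               "nicotine_use", "bmi"),
                                controls = c("chronological_age", "sex")) {
  if (any(subjects$group != "SCZ")) {
    stop("clinical regression is defined for the patient group only",
         call. = FALSE)
  }
  if (length(intersect(predictors, controls)) > 0L) {
    stop("predictor duplicated among controls: ",
         paste(intersect(predictors, controls), collapse = ", "),
         call. = FALSE)
  }
  dat <- subjects[, c(predictors, controls), drop = FALSE]
  dat$gap <- gaps
  keep <- stats::complete.cases(dat)
  if (sum(!keep) > 0L) {
    message(sum(!keep), " subject(s) dropped for missing predictors")
  }
  dat <- dat[keep, , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(predictors) + 3L) {
    stop("too few complete cases (", n, ") for ", length(predictors),
         " predictors", call. = FALSE)
  }
  dat <- standardize_columns(dat, c("gap", predictors, controls))
  form <- stats::as.formula(paste("gap ~",
                                  paste(c(predictors, controls),
                                        collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular regression design; aliased terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- stats::summary.lm(fit)$coefficients
  rows <- match(predictors, rownames(sm))
  data.frame(predictor = predictors,
             beta = sm[rows, "Estimate"],
             t_stat = sm[rows, "t value"],
             p_value = sm[rows, "Pr(>|t|)"],
             n_used = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regression of brain-age gaps on antipsychotic dose (patients)
#'
#' Patients without a chlorpromazine-equivalent dose are excluded first;
#' then `gap ~ cpz_dose + age + sex` with standardized continuous variables.
#'
#' @param gaps brain-age gaps for the patients (years).
#' @param subjects patient subject rows with a `cpz_dose` column.
#' @param controls control column names.
#' @return one-row data frame: `predictor`, `beta`, `t_stat`, `p_value`,
#'   `n_used`.
#' @export
cpz_regression <- function(gaps, subjects,
                           controls = c("chronological_age", "sex")) {
  keep <- !is.na(subjects$cpz_dose)
  if (sum(keep) < 10L) {
    stop("fewer than 10 subjects with antipsychotic dose information",
         call. = FALSE)
  }
  clinical_regression(gaps[keep], subjects[keep, , drop = FALSE],
                      predictors = "cpz_dose", controls = controls)
}

#' Region-wise ANCOVA with FDR correction over a table of estimates
#'
#' Runs [ancova_gap()] for every region in an estimates table (long format,
#' as produced by [apply_model()] row-bound over regions), then adjusts the
#' region p values with [fdr_adjust()] within the chosen family.
#'
#' @param estimates data frame with `modality`, `region_id`, `subject_id`,
#'   `brain_age_gap`.
#' @param subjects subject data frame (test cohort, both groups).
#' @param covariates ANCOVA covariate columns.
#' @param fdr_family "modality" (default; the 90/90/48 tests of each
#'   modality are corrected separately) or "joint" (one family across all
#'   regions supplied).
#' @return data frame, one row per modality x region, with the ANCOVA
#'   outputs plus `p_adjusted`.
#' @export
group_compare_regions <- function(estimates, subjects,
                                  covariates = c("chronological_age", "sex",
                                                 "mmse", "education"),
                                  fdr_family = c("modality", "joint")) {
  fdr_family <- match.arg(fdr_family)
  sub_idx <- match(estimates$subject_id, subjects$subject_id)
  if (anyNA(sub_idx)) stop("estimates reference unknown subjects", call. = FALSE)
  keys <- unique(estimates[, c("modality", "region_id")])
  res <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- estimates$modality == keys$modality[i] &
      estimates$region_id == keys$region_id[i]
    subs <- subjects[sub_idx[sel], , drop = FALSE]
    r <- ancova_gap(estimates$brain_age_gap[sel], subs, covariates)
    res[[i]] <- cbind(keys[i, , drop = FALSE], r)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (fdr_family == "modality") {
    out$p_adjusted <- NA_real_
    for (m in unique(out$modality)) {
      sel <- out$modality == m
      out$p_adjusted[sel] <- fdr_adjust(out$p_value[sel])
    }
  } else {
    out$p_adjusted <- fdr_adjust(out$p_value)
  }
  out
}
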