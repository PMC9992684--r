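# random two-group subject table for design-matrix tests
random_design <- function(n, seed) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("HC", "SCZ"), length.out = n),
    chronological_age = runif(n, 20, 84),
    sex = sample(c("M", "F"), n, replace = TRUE),
    mmse = round(runif(n, 20, 30)),
    education = round(runif(n, 6, 20)),
    stringsAsFactors = FALSE
  )
}

test_that("ANCOVA degenerates correctly without variance or covariates", {
  sub <- random_design(40, 1)
  res <- ancova_gap(rep(2.5, 40), sub)
  expect_equal(res$f_stat, 0)
  expect_equal(res$partial_eta_sq, 0)

  # without covariates the group F equals the squared pooled two-sample t
  set.seed(2)
  gaps <- rnorm(40) + ifelse(sub$group == "SCZ", 1, 0)
  res0 <- ancova_gap(gaps, sub, covariates = character(0))
  tt <- t.test(gaps[sub$group == "SCZ"], gaps[sub$group == "HC"],
               var.equal = TRUE)
  expect_equal(res0$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res0$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANCOVA matches a brute-force two-model residual-SS oracle", {
  for (i in 1:100) {
    n <- sample(30:80, 1)
    sub <- random_design(n, 1000 + i)
    set.seed(2000 + i)
    gaps <- rnorm(n, sd = 3) + 0.05 * sub$chronological_age +
      0.8 * (sub$group == "SCZ")
    res <- ancova_gap(gaps, sub)
    # oracle: QR-based projections of the two design matrices
    Xf <- model.matrix(~ factor(group) + chronological_age + factor(sex) +
                         mmse + education, data = sub)
    Xr <- Xf[, colnames(Xf) != "factor(group)SCZ", drop = FALSE]
    rss <- function(X) {
      q <- qr(X)
      sum((gaps - qr.fitted(q, gaps))^2)
    }
    rss_f <- rss(Xf); rss_r <- rss(Xr)
    df2 <- n - ncol(Xf)
    f <- (rss_r - rss_f) / (rss_f / df2)
    expect_equal(res$f_stat, f, tolerance = 1e-8)
    expect_equal(res$p_value, pf(f, 1, df2, lower.tail = FALSE),
                 tolerance = 1e-8)
    expect_equal(res$partial_eta_sq, (rss_r - rss_f) / (rss_r),
                 tolerance = 1e-8)
    expect_true(res$partial_eta_sq >= 0 && res$partial_eta_sq <= 1)
  }
})

test_that("ANCOVA rejects singular designs by naming aliased terms", {
  sub <- random_design(30, 3)
  sub$mmse2 <- sub$mmse  # duplicated covariate
  expect_error(ancova_gap(rnorm(30), sub,
                          covariates = c("chronological_age", "mmse", "mmse2")),
               "aliased")
})

test_that("BH adjustment matches hand and naive oracles and is monotone", {
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # naive O(m^2) step-up oracle: q_i = min_{j >= i} p_(j) m / j, in input order
  naive_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[i] <- min(1, min(m / (i:m) * ps[i:m]))
    }
    out <- numeric(m)
    out[o] <- q
    out
  }
  for (i in 1:20) {
    set.seed(i)
    p <- runif(sample(1:40, 1))
    adj <- fdr_adjust(p)
    expect_identical(adj, naive_bh(p))
    expect_true(all(adj >= p))
  }
})

test_that("clinical regression recovers a planted duration effect", {
  set.seed(71)
  n <- 150
  sub <- data.frame(
    subject_id = sprintf("P%03d", 1:n),
    group = "SCZ",
    chronological_age = runif(n, 20, 80),
    sex = sample(c("M", "F"), n, replace = TRUE),
    illness_duration = rnorm(n, 15, 8),
    age_of_onset = rnorm(n, 27, 9),
    panss_positive = rnorm(n, 11, 3),
    panss_negative = rnorm(n, 10, 4),
    panss_general = rnorm(n, 21, 5),
    nicotine_use = runif(n) < 0.3,
    bmi = rnorm(n, 25, 4),
    stringsAsFactors = FALSE
  )
  zdur <- as.numeric(scale(sub$illness_duration))
  gaps <- 0.3 * zdur + rnorm(n, 0, sqrt(1 - 0.3^2))
  res <- clinical_regression(gaps, sub)
  b_dur <- res$beta[res$predictor == "illness_duration"]
  expect_lt(abs(b_dur - 0.3), 0.1)
  others <- res$beta[!res$predictor %in% "illness_duration"]
  expect_true(all(abs(others) < 0.25))
  # duplicate control among predictors is a design error
  expect_error(clinical_regression(gaps, sub,
                                   predictors = c("illness_duration",
                                                  "chronological_age")),
               "duplicated")
})

test_that("null predictors are rejected at close to the nominal rate", {
  n <- 120
  rej <- logical(200)
  for (i in 1:200) {
    set.seed(5000 + i)
    sub <- data.frame(
      subject_id = sprintf("P%03d", 1:n), group = "SCZ",
      chronological_age = runif(n, 20, 80),
      sex = sample(c("M", "F"), n, replace = TRUE),
      bmi = rnorm(n, 25, 4), stringsAsFactors = FALSE)
    gaps <- rnorm(n)
    res <- clinical_regression(gaps, sub, predictors = "bmi")
    rej[i] <- res$p_value < 0.05
  }
  expect_lte(mean(rej), 0.07)
})

test_that("dose regression excludes undosed subjects consistently", {
  set.seed(81)
  n <- 100
  sub <- data.frame(
    subject_id = sprintf("P%03d", 1:n), group = "SCZ",
    chronological_age = runif(n, 20, 80),
    sex = sample(c("M", "F"), n, replace = TRUE),
    cpz_dose = ifelse(runif(n) < 0.7, rnorm(n, 400, 300), NA),
    stringsAsFactors = FALSE)
  dosed <- !is.na(sub$cpz_dose)

  # perfect association (summary.lm warns about the perfect fit)
  gaps <- ifelse(dosed, 0.01 * sub$cpz_dose, rnorm(n))
  res <- suppressWarnings(cpz_regression(gaps, sub))
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$beta, 0)

  # filter-then-fit equals fitting on the pre-filtered table
  gaps2 <- rnorm(n) + 0.001 * ifelse(dosed, sub$cpz_dose, 0)
  r1 <- cpz_regression(gaps2, sub)
  r2 <- cpz_regression(gaps2[dosed], sub[dosed, ])
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  # null dose: beta centred on zero across seeds
  betas <- sapply(1:20, function(i) {
    set.seed(6000 + i)
    g <- rnorm(n)
    cpz_regression(g, sub)$beta
  })
  expect_lt(abs(mean(betas)), 0.08)

  sub_few <- sub; sub_few$cpz_dose[-(1:5)] <- NA
  expect_error(cpz_regression(gaps, sub_few), "fewer than 10")
})

test_that("region-wise comparison applies FDR within the requested family", {
  set.seed(91)
  sub <- random_design(60, 91)
  regions <- expand.grid(modality = c("GM", "FA"), region_id = 1:5,
                         stringsAsFactors = FALSE)
  est <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    data.frame(modality = regions$modality[i],
               region_id = regions$region_id[i],
               subject_id = sub$subject_id,
               brain_age_gap = rnorm(60) +
                 ifelse(sub$group == "SCZ" & regions$region_id[i] == 1, 2, 0),
               stringsAsFactors = FALSE)
  }))
  res_mod <- group_compare_regions(est, sub, fdr_family = "modality")
  res_joint <- group_compare_regions(est, sub, fdr_family = "joint")
  expect_equal(nrow(res_mod), 10L)
  expect_equal(res_mod$p_value, res_joint$p_value, tolerance = 1e-12)
  for (m in c("GM", "FA")) {
    sel <- res_mod$modality == m
    expect_equal(res_mod$p_adjusted[sel], fdr_adjust(res_mod$p_value[sel]))
  }
  expect_equal(res_joint$p_adjusted, fdr_adjust(res_joint$p_value))
})
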