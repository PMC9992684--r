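test_that("generate_subjects honours cohort sizes, age range and clinical-field rules", {
  cfg <- synthetic_config(n_hc_train = 230L, n_hc_test = 20L, n_scz = 25L,
                          seed = 42L)
  sub <- generate_subjects(cfg)
  expect_equal(sum(sub$cohort == "train"), 230L)
  expect_equal(sum(sub$group == "HC" & sub$cohort == "test"), 20L)
  expect_equal(sum(sub$group == "SCZ"), 25L)
  expect_true(all(sub$chronological_age >= 20 & sub$chronological_age <= 84))
  # clinical fields only for the patient group
  hc <- sub[sub$group == "HC", ]
  scz <- sub[sub$group == "SCZ", ]
  expect_true(all(is.na(hc$illness_duration)))
  expect_true(all(is.na(hc$panss_positive)))
  expect_true(all(is.na(hc$cpz_dose)))
  expect_true(all(!is.na(scz$illness_duration)))
  expect_true(all(scz$age_of_onset <= scz$chronological_age))
  expect_equal(scz$illness_duration,
               scz$chronological_age - scz$age_of_onset)
  expect_true(all(sub$mmse >= 0 & sub$mmse <= 30))
})

test_that("an empty patient group yields no patient records", {
  cfg <- synthetic_config(n_hc_train = 20L, n_hc_test = 0L, n_scz = 0L,
                          seed = 3L)
  sub <- generate_subjects(cfg)
  expect_equal(nrow(sub), 20L)
  expect_true(all(sub$group == "HC"))
})

test_that("subject and map generation are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 11L)
  s1 <- generate_subjects(cfg)
  s2 <- generate_subjects(cfg)
  expect_identical(s1, s2)
  atlas <- make_grid_atlas("GM", 3L, 25L)
  m1 <- generate_region_maps(s1, atlas, cfg)
  m2 <- generate_region_maps(s2, atlas, cfg)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$truth, m2$truth)
  b1 <- generate_bold(s1[1:3, ], make_grid_atlas("FC", 2L, 8L), cfg)
  b2 <- generate_bold(s1[1:3, ], make_grid_atlas("FC", 2L, 8L), cfg)
  expect_identical(b1$series, b2$series)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(age_range = c(84, 20)), "age_range")
  expect_error(synthetic_config(n_hc_train = 0L), "positive")
  expect_error(synthetic_config(signal_fraction = 1.5), "signal_fraction")
})

test_that("region maps obey the voxel signal model and its invariants", {
  cfg <- tiny_config(seed = 5L)
  sub <- generate_subjects(cfg)
  age <- sub$chronological_age

  # no-signal configuration: voxel-age correlations hover near zero
  cfg0 <- tiny_config(seed = 5L)
  cfg0$signal_params$GM$signal_slope <- 0
  maps0 <- generate_region_maps(sub, make_grid_atlas("GM", 2L, 40L), cfg0)
  r0 <- voxel_age_corr(maps0$values[[1]], age, quiet = TRUE)
  expect_true(mean(abs(r0) < 3 / sqrt(length(age))) >= 0.95)

  # noiseless fully-informative configuration: exactly linear in age
  cfg1 <- tiny_config(seed = 5L)
  cfg1$signal_params$GM$noise_sd <- 1e-12
  cfg1$signal_fraction <- 1
  maps1 <- generate_region_maps(sub, make_grid_atlas("GM", 2L, 10L), cfg1)
  r1 <- voxel_age_corr(maps1$values[[1]], age, quiet = TRUE)
  expect_true(all(abs(abs(r1) - 1) < 1e-6))

  # FA maps bounded in [0,1], nothing non-finite anywhere
  fa <- generate_region_maps(sub, make_grid_atlas("FA", 2L, 40L), cfg)
  for (v in fa$values) {
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("informative voxels reach the closed-form population correlation", {
  # r = slope*sd_age / sqrt(slope^2 sd_age^2 + noise^2) ~ 0.6 at defaults
  cfg <- synthetic_config(n_hc_train = 230L, n_hc_test = 0L, n_scz = 0L,
                          voxels_per_region = 100L,
                          n_regions = list(GM = 2L), seed = 9L)
  r_pop <- population_r(cfg$signal_params$GM$signal_slope,
                        cfg$signal_params$GM$noise_sd)
  expect_equal(r_pop, 0.6, tolerance = 0.02)
  sub <- generate_subjects(cfg)
  maps <- generate_region_maps(sub, make_grid_atlas("GM", 2L, 100L), cfg)
  r <- voxel_age_corr(maps$values[[1]], sub$chronological_age, quiet = TRUE)
  mean_inf_r <- mean(abs(r[maps$truth[[1]]]))
  expect_lt(abs(mean_inf_r - 0.6), 0.05)
})

test_that("pathology injection shifts only patient informative voxels as specified", {
  cfg <- tiny_config(seed = 21L)
  sub <- generate_subjects(cfg)
  atlas <- make_grid_atlas("GM", 3L, 30L)
  maps <- generate_region_maps(sub, atlas, cfg)

  # empty effect spec: identity
  same <- inject_pathology(maps, sub,
                           data.frame(modality = character(0),
                                      region_id = integer(0),
                                      gap_years = numeric(0)))
  expect_identical(same$values, maps$values)

  es <- data.frame(modality = "GM", region_id = 1L, gap_years = 5)
  shifted <- inject_pathology(maps, sub, es)
  scz <- sub$group == "SCZ"
  inf <- maps$truth[["1"]]
  delta <- shifted$values[["1"]] - maps$values[["1"]]
  expect_equal(mean(delta[scz, inf]),
               5 * cfg$signal_params$GM$signal_slope, tolerance = 1e-12)
  expect_true(all(delta[!scz, ] == 0))
  noise_vox <- setdiff(seq_len(30L), inf)
  expect_true(all(delta[, noise_vox] == 0))
  # untouched region
  expect_identical(shifted$values[["2"]], maps$values[["2"]])

  # duration scaling: a patient at the mean duration gets the unscaled shift
  sub2 <- sub
  sub2$illness_duration[scz] <- mean(sub$illness_duration[scz])
  scaled <- inject_pathology(maps, sub2, es, duration_scaled = TRUE)
  expect_equal(scaled$values[["1"]][scz, inf],
               shifted$values[["1"]][scz, inf], tolerance = 1e-12)

  expect_error(inject_pathology(maps, sub,
                                data.frame(modality = "GM", region_id = 99L,
                                           gap_years = 5)),
               "unknown region")
})

test_that("synthetic BOLD has the specified correlation structure", {
  cfg <- tiny_config(seed = 2L)
  sub <- generate_subjects(cfg)[1:4, ]
  atlas <- make_grid_atlas("FC", 2L, 6L)

  # no idiosyncratic noise: every voxel pair correlates at +/-1
  cfg1 <- tiny_config(seed = 2L)
  cfg1$bold$idio_sd <- 0
  b1 <- generate_bold(sub, atlas, cfg1)
  cc <- cor(t(b1$series[[1]]))
  expect_true(all(abs(abs(cc) - 1) < 1e-10))

  # no common signal: expected pairwise correlation ~ 0
  cfg2 <- tiny_config(seed = 2L)
  cfg2$bold$weight_base <- 0
  cfg2$bold$weight_slope <- 0
  b2 <- generate_bold(sub, atlas, cfg2)
  cc2 <- cor(t(b2$series[[1]]))
  off <- cc2[upper.tri(cc2)]
  expect_lt(abs(mean(off)), 0.15)

  expect_error({
    cfg3 <- tiny_config(); cfg3$bold$n_time <- 1L
    generate_bold(sub, atlas, cfg3)
  }, "2 time points")
})
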