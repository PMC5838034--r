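test_that("generated tables validate and are byte-identical under one seed", {
  cfg <- small_synth_config(seed = 14)
  s1 <- generate_captures(cfg)
  s2 <- generate_captures(cfg)
  expect_identical(s1$captures, s2$captures)
  expect_identical(s1$truth, s2$truth)
  # validation is a no-op on generated output
  expect_identical(validate_captures(s1$captures), s1$captures)
  s3 <- generate_captures(small_synth_config(seed = 15))
  expect_false(identical(s1$captures, s3$captures))
})

test_that("perfect detection with zero scatter pins captures to home cells", {
  cfg <- synthetic_config(n_plots = 1, n_residents_f = 3, n_residents_m = 2,
                          n_migrants_per_season = 2, juvenile_fraction = 0,
                          detection_p = 1, home_range_sd_f = 0,
                          home_range_sd_m = 0, seed = 4)
  synth <- generate_captures(cfg)
  caps <- assign_seasons(synth$captures)
  n_surveys <- length(unique(caps$survey_date))
  # residents (arrival season 1) are captured on every survey
  res_ids <- synth$truth$individual_id[synth$truth$arrival_season == 1]
  for (id in res_ids)
    expect_equal(sum(caps$individual_id == id), n_surveys)
  # every capture is in the cell containing the true centre
  m <- merge(caps, synth$truth, by = c("individual_id", "plot_id"))
  cell <- cell_of_point(m$center_x, m$center_y)
  expect_equal(m$cell_row, cell$cell_row)
  expect_equal(m$cell_col, cell$cell_col)
})

test_that("pipeline cohorts agree with ground truth on knowable cases", {
  cfg <- synthetic_config(n_plots = 2, n_residents_f = 4, n_residents_m = 3,
                          n_migrants_per_season = 4, detection_p = 1,
                          seed = 20)
  synth <- generate_captures(cfg)
  co <- classify_cohorts(assign_seasons(synth$captures))
  m <- merge(co, synth$truth, by = c("individual_id", "plot_id"))
  m$season_idx <- as.integer(m$season)
  # adults arriving after season 1: migrant on arrival, resident afterwards
  adults <- m[!m$juvenile_at_arrival & m$arrival_season > 1, ]
  arriving <- adults[adults$season_idx == adults$arrival_season, ]
  expect_true(all(arriving$cohort %in% c("MF", "MM")))
  settled <- adults[adults$season_idx > adults$arrival_season, ]
  expect_true(all(settled$cohort %in% c("RF", "RM")))
  # founders are residents in every season (perfect detection)
  founders <- m[m$arrival_season == 1 & !m$juvenile_at_arrival, ]
  expect_true(all(founders$cohort %in% c("RF", "RM")))
  # cohort sex matches true sex for adult classifications
  ad <- m[m$cohort %in% c("RF", "MF", "RM", "MM"), ]
  expect_equal(substr(ad$cohort, 2, 2), ad$sex)
})

test_that("juveniles mature across the threshold and become residents", {
  cfg <- synthetic_config(n_plots = 1, n_residents_f = 3, n_residents_m = 2,
                          n_migrants_per_season = 4, juvenile_fraction = 1,
                          detection_p = 1, growth_mm_per_season = 4,
                          seed = 6)
  synth <- generate_captures(cfg)
  co <- classify_cohorts(assign_seasons(synth$captures))
  m <- merge(co, synth$truth, by = c("individual_id", "plot_id"))
  m$season_idx <- as.integer(m$season)
  juv <- m[m$juvenile_at_arrival, ]
  expect_true(all(juv$cohort[juv$season_idx == juv$arrival_season] == "J"))
  grown <- juv[juv$season_idx > juv$arrival_season & juv$cohort != "J", ]
  expect_gt(nrow(grown), 0)
  expect_true(all(grown$cohort %in% c("RF", "RM")))
})

test_that("the recovery experiment reports rates per condition and statistic", {
  base <- synthetic_config(n_plots = 2, n_residents_f = 4, n_residents_m = 3,
                           n_migrants_per_season = 4)
  out <- parameter_recovery_experiment(
    cluster_sds = c(NA, 0.3), detection_ps = 0.6, n_sims = 1,
    base_config = base, n_null_replicates = 3, seed = 2)
  expect_equal(nrow(out), 6L)
  expect_setequal(unique(out$mode), c("csr", "attraction"))
  expect_true(all(out$rejection_rate >= 0 & out$rejection_rate <= 1))
  expect_warning(
    parameter_recovery_experiment(cluster_sds = NA, detection_ps = 0,
                                  n_sims = 1, base_config = base, seed = 1),
    "no data")
})
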