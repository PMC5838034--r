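test_that("dates map to the documented seasonal windows", {
  w <- season_windows()
  caps <- make_captures(c("a", "b"),
                        survey_date = c("1982-03-15", "1982-10-02"))
  out <- assign_seasons(caps, w)
  expect_equal(as.character(out$season), c("dry-1982", "wet2-1982"))
  expect_error(
    assign_seasons(make_captures("c", survey_date = "1984-01-01"), w),
    "1984-01-01")
})

test_that("maturity threshold is 19 mm, adults inclusive", {
  expect_equal(maturity_class(c(18.9, 19, 30)),
               c("juvenile", "adult", "adult"))
  expect_error(maturity_class(-1))
})

test_that("cohort rules: first-season residents, migrants, re-sighting", {
  # a1: adult female present from season 1 -> always resident
  # a2: adult male first seen season 3, again season 4 -> MM then RM
  # a3: juvenile (17 mm) season 2, adult female (20 mm) season 3 same plot
  caps <- rbind(
    make_captures("a1", survey_date = season_dates, svl_mm = 22, sex = "F"),
    make_captures("a2", survey_date = season_dates[3:4], svl_mm = 23,
                  sex = "M"),
    make_captures("a3", survey_date = season_dates[2], svl_mm = 17,
                  sex = "U"),
    make_captures("a3", survey_date = season_dates[3], svl_mm = 20,
                  sex = "F"))
  co <- classify_cohorts(caps)
  get <- function(id, season)
    co$cohort[co$individual_id == id & co$season == season]
  expect_equal(get("a1", "dry-1982"), "RF")
  expect_true(all(co$cohort[co$individual_id == "a1"] == "RF"))
  expect_equal(get("a2", "wet2-1982"), "MM")
  expect_equal(get("a2", "dry-1983"), "RM")
  expect_equal(get("a3", "wet1-1982"), "J")
  expect_equal(get("a3", "wet2-1982"), "RF")
})

test_that("adults with unknown sex are excluded and logged", {
  caps <- make_captures("u1", survey_date = season_dates[2], svl_mm = 25,
                        sex = "U")
  co <- classify_cohorts(caps)
  expect_equal(nrow(co), 0L)
  excl <- attr(co, "excluded")
  expect_equal(excl$individual_id, "u1")
})

test_that("an adult absent a full season reverts to migrant on return", {
  caps <- rbind(
    make_captures("r1", survey_date = season_dates[c(1, 2, 4)], svl_mm = 22,
                  sex = "F"))
  co <- classify_cohorts(caps)
  expect_equal(co$cohort[co$season == "wet1-1982"], "RF")
  expect_equal(co$cohort[co$season == "dry-1983"], "MF")
})

test_that("one cohort per individual per plot-season; determinism", {
  synth <- generate_captures(small_synth_config(seed = 9))
  caps <- assign_seasons(synth$captures)
  co1 <- classify_cohorts(caps)
  co2 <- classify_cohorts(caps[sample(nrow(caps)), ])
  expect_false(anyDuplicated(
    co1[, c("individual_id", "plot_id", "season")]) > 0)
  o <- order(co2$plot_id, as.integer(co2$season), co2$individual_id)
  expect_equal(co1$cohort, co2$cohort[o])
})

test_that("minimum-capture subset keeps exactly the frequent individuals", {
  caps <- rbind(
    make_captures("few", survey_date = season_dates[1:2]),
    make_captures("many", survey_date = season_dates))
  out <- subset_min_captures(caps, k = 3)
  expect_equal(unique(out$individual_id), "many")
  s <- attr(out, "subset_summary")
  expect_equal(s$n_individuals_full, 2L)
  expect_equal(s$n_captures_full, 7L)
  expect_equal(s$n_individuals_subset, 1L)
  expect_equal(s$n_captures_subset, 5L)
  # identity filter at k = 1; monotone in k
  expect_equal(nrow(subset_min_captures(caps, k = 1)), nrow(caps))
  for (k in 2:6) {
    kept_k <- unique(subset_min_captures(caps, k)$individual_id)
    kept_k1 <- unique(subset_min_captures(caps, k + 1)$individual_id)
    expect_true(all(kept_k1 %in% kept_k))
  }
})

test_that("seasonal centroids average cell centres, order-invariantly", {
  caps <- assign_seasons(rbind(
    make_captures("a", survey_date = "1982-03-01", cell_row = 0, cell_col = 0),
    make_captures("a", survey_date = "1982-03-05", cell_row = 0, cell_col = 1),
    make_captures("b", survey_date = "1982-03-01", cell_row = 0, cell_col = 0)))
  co <- classify_cohorts(caps)
  cen <- seasonal_centroids(caps, co)
  expect_equal(cen$x[cen$individual_id == "a"], 1.5)
  expect_equal(cen$y[cen$individual_id == "a"], 0.75)
  expect_equal(cen$x[cen$individual_id == "b"], 0.75)
  cen2 <- seasonal_centroids(caps[rev(seq_len(nrow(caps))), ], co)
  expect_equal(cen[order(cen$individual_id), c("x", "y")],
               cen2[order(cen2$individual_id), c("x", "y")])
})

test_that("abundance groups partition the classified individuals", {
  caps <- assign_seasons(rbind(
    make_captures(paste0("f", 1:3), survey_date = season_dates[1],
                  svl_mm = 22, sex = "F"),
    make_captures(paste0("m", 1:2), survey_date = season_dates[2],
                  svl_mm = 22, sex = "F")))
  co <- classify_cohorts(caps)
  ab <- abundance_table(co)
  # 3 RF in season 1, 2 MF in season 2 -> female counts 3 and 2
  expect_equal(ab$count[ab$season == "dry-1982" & ab$group == "female"], 3L)
  expect_equal(ab$count[ab$season == "wet1-1982" & ab$group == "female"], 2L)
  # empty seasons are reported as zeros
  expect_true(all(ab$count[ab$season == "dry-1983"] == 0L))
  # partition oracle on synthetic data: group counts sum to classified n
  synth <- generate_captures(small_synth_config(seed = 2))
  co2 <- classify_cohorts(assign_seasons(synth$captures))
  ab2 <- abundance_table(co2)
  expect_equal(sum(ab2$count), nrow(co2))
  for (pl in unique(co2$plot_id)) for (se in levels(co2$season)) {
    n_class <- sum(co2$plot_id == pl & co2$season == se)
    expect_equal(sum(ab2$count[ab2$plot_id == pl & ab2$season == se]),
                 n_class)
  }
})
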