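survey_caps <- function(ids, cohorts, rows, cols) {
  data.frame(individual_id = ids, plot_id = "P1",
             survey_date = as.Date("1982-03-02"),
             cell_row = rows, cell_col = cols, svl_mm = 20, mass_g = NA,
             sex = "F", cohort = cohorts, stringsAsFactors = FALSE)
}

test_that("shared-site proportion counts cross-class co-occupancy only", {
  # one J and one RF in the same cell -> 1/1
  sc <- survey_caps(c("a", "b"), c("J", "RF"), c(0, 0), c(0, 0))
  expect_equal(shared_site_proportion(sc, c("J", "RF"))$proportion, 1)
  # in different cells -> 0/2
  sc <- survey_caps(c("a", "b"), c("J", "RF"), c(0, 1), c(0, 0))
  res <- shared_site_proportion(sc, c("J", "RF"))
  expect_equal(res$n_occupied_cells, 2L)
  expect_equal(res$proportion, 0)
  # two residents of the same class never count as shared
  sc <- survey_caps(c("a", "b"), c("RF", "RF"), c(0, 0), c(0, 0))
  expect_equal(shared_site_proportion(sc, c("J", "RF"))$n_shared_cells, 0L)
  # no occupied cell for the pair -> undefined
  sc <- survey_caps("a", "MM", 0, 0)
  expect_true(is.na(shared_site_proportion(sc, c("J", "RF"))$proportion))
})

test_that("denominator modes differ exactly by off-pair occupancy", {
  sc <- survey_caps(c("a", "b", "c"), c("J", "RF", "MM"), c(0, 0, 2),
                    c(0, 0, 2))
  expect_equal(shared_site_proportion(sc, c("J", "RF"), "pair")$proportion, 1)
  expect_equal(shared_site_proportion(sc, c("J", "RF"), "all")$proportion,
               0.5)
})

test_that("an individual recaptured within a survey counts once", {
  sc <- survey_caps(c("a", "a", "b"), c("J", "J", "RF"), c(0, 1, 1),
                    c(0, 0, 0))
  res <- shared_site_proportion(sc, c("J", "RF"))
  # a counts at its first cell (0,0); b occupies (1,0): no sharing, 2 cells
  expect_equal(res$n_shared_cells, 0L)
  expect_equal(res$n_occupied_cells, 2L)
})

test_that("adding a focal-class individual to an occupied cell never lowers the numerator", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(2:8, 1)
    sc <- survey_caps(paste0("i", 1:n),
                      sample(c("J", "RF"), n, replace = TRUE),
                      sample(0:5, n, replace = TRUE),
                      sample(0:7, n, replace = TRUE))
    base <- shared_site_proportion(sc, c("J", "RF"))
    rf <- which(sc$cohort == "RF")
    if (!length(rf)) next
    extra <- survey_caps("new", "J", sc$cell_row[rf[1]], sc$cell_col[rf[1]])
    grown <- shared_site_proportion(rbind(sc, extra), c("J", "RF"))
    expect_gte(grown$n_shared_cells, base$n_shared_cells)
  }
})

test_that("the (1,1) null expectation converges to the enumeration value 1/48", {
  res <- null_shared_expectation(1, 1, 48, reps = 4000, seed = 2)
  expect_lt(abs(res$expectation - 1 / 48), 3 * res$se)
  expect_true(is.na(null_shared_expectation(0, 3)$expectation))
})

test_that("Monte-Carlo null matches exact enumeration for two-by-two occupancy", {
  # exact mean over all 6^4 placements of 2 + 2 individuals in 6 cells
  n_cells <- 6
  grid <- expand.grid(a1 = 1:n_cells, a2 = 1:n_cells, b1 = 1:n_cells,
                      b2 = 1:n_cells)
  exact <- mean(apply(grid, 1, function(g) {
    shared <- length(intersect(g[1:2], g[3:4]))
    shared / length(unique(g))
  }))
  res <- null_shared_expectation(2, 2, n_cells, reps = 20000, seed = 4)
  expect_lt(abs(res$expectation - exact), 3 * res$se)
})

test_that("per-survey table is relabeling-invariant and keyed correctly", {
  caps <- assign_seasons(rbind(
    make_captures(c("j1", "r1"), survey_date = "1982-03-02",
                  cell_row = c(1, 1), cell_col = c(1, 1),
                  svl_mm = c(15, 22), sex = c("U", "F")),
    make_captures(c("j1", "r1"), survey_date = "1982-03-09",
                  cell_row = c(0, 2), cell_col = c(0, 2),
                  svl_mm = c(15, 22), sex = c("U", "F"))))
  co <- classify_cohorts(caps)
  tab <- shared_sites_table(caps, co)
  jrf <- tab[tab$migrant == "J" & tab$resident == "RF", ]
  expect_equal(nrow(jrf), 2L)
  expect_equal(sort(jrf$proportion), c(0, 1))
})
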