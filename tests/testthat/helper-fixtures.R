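# small hand-built capture tables for unit tests

make_captures <- function(individual_id, plot_id = "P1", survey_date,
                          cell_row = 0L, cell_col = 0L, svl_mm = 20,
                          sex = "F") {
  n <- max(length(individual_id), length(survey_date))
  data.frame(
    individual_id = rep_len(individual_id, n),
    plot_id = rep_len(plot_id, n),
    survey_date = as.Date(rep_len(survey_date, n)),
    cell_row = rep_len(as.integer(cell_row), n),
    cell_col = rep_len(as.integer(cell_col), n),
    svl_mm = rep_len(svl_mm, n),
    mass_g = NA_real_,
    sex = rep_len(sex, n),
    stringsAsFactors = FALSE
  )
}

# one capture date per default season, in order
season_dates <- as.Date(c("1982-03-15", "1982-07-15", "1982-11-15",
                          "1983-03-15", "1983-07-15"))

# small, fast synthetic study for pipeline-level tests
small_synth_config <- function(...) {
  synthetic_config(n_plots = 2, n_residents_f = 5, n_residents_m = 3,
                   n_migrants_per_season = 5, ...)
}
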