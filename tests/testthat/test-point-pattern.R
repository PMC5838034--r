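test_that("cross-type NND matches a brute-force double loop", {
  g <- plot_geometry()
  out <- cross_nnd(cbind(1, 1), cbind(4, 5), g)
  expect_equal(out$nnd, 5)
  expect_equal(cross_nnd(cbind(0.75, 0.75), cbind(4, 5), g)$border, 0.75)

  set.seed(31)
  from <- cbind(runif(100, 0, 12), runif(100, 0, 9))
  to <- cbind(runif(60, 0, 12), runif(60, 0, 9))
  fast <- cross_nnd(from, to, g)
  brute <- numeric(100)
  for (i in 1:100) {
    best <- Inf
    for (j in 1:60)
      best <- min(best, sqrt(sum((from[i, ] - to[j, ])^2)))
    brute[i] <- best
  }
  expect_equal(fast$nnd, brute)
  expect_error(cross_nnd(from, from[0, , drop = FALSE], g), "nonempty")
})

test_that("Clark-Evans R on the full cell-centre lattice is strongly uniform", {
  g <- plot_geometry()
  cells <- expand.grid(row = 0:5, col = 0:7)
  lat <- as.matrix(cell_center(cells$row, cells$col, g))
  rv <- clark_evans_r(lat, lat, g)
  expect_equal(rv$mean_observed_nnd, 1.5)
  expect_equal(rv$expected_nnd, donnelly_expectation(48, g))
  # frozen from direct evaluation of the corrected expectation:
  # 0.5*sqrt(108/48) + (0.0514 + 0.041/sqrt(48)) * 42/48 = 0.800153
  expect_equal(rv$r_value, 1.5 / 0.8001531, tolerance = 1e-6)
})

test_that("coincident focal points give R = 0; degenerate counts error", {
  g <- plot_geometry()
  to <- cbind(c(2, 5, 8), c(2, 5, 8))
  rv <- clark_evans_r(to + 1e-12, to, g)
  expect_equal(rv$r_value, 0, tolerance = 1e-9)
  expect_error(clark_evans_r(to[0, , drop = FALSE], to, g), "at least one")
})

test_that("R is invariant to relabeling and to in-window rigid shifts", {
  g <- plot_geometry()
  set.seed(8)
  from <- cbind(runif(15, 2, 10), runif(15, 2, 7))
  to <- cbind(runif(12, 2, 10), runif(12, 2, 7))
  r0 <- clark_evans_r(from, to, g)$r_value
  expect_equal(clark_evans_r(from[sample(15), ], to[sample(12), ], g)$r_value,
               r0)
  shift <- c(0.8, -0.5)
  expect_equal(clark_evans_r(sweep(from, 2, shift, "+"),
                             sweep(to, 2, shift, "+"), g)$r_value, r0)
})

test_that("theoretical CSR G has the closed form and limits", {
  expect_equal(g_theoretical(0, 2), 0)
  expect_equal(g_theoretical(1, 1 / pi), 1 - exp(-1))
  expect_equal(g_theoretical(1e6, 0.1), 1)
  r <- seq(0, 3, by = 0.01)
  expect_true(all(diff(g_theoretical(r, 0.5)) >= 0))
  expect_error(g_theoretical(-1, 1), "nonnegative")
})

test_that("KM G-hat reduces to the ECDF without censoring and to 0 when all censored", {
  r <- seq(0, 3, by = 0.05)
  nnd <- c(0.3, 0.8, 1.2, 1.2, 2.0)
  wide <- rep(10, 5)
  expect_equal(g_hat_km(nnd, wide, r), ecdf(nnd)(r))
  expect_equal(g_hat_km(nnd, rep(0.1, 5), r), rep(0, length(r)))
})

test_that("KM G-hat equals the survival-package product-limit estimate", {
  set.seed(12)
  r <- seq(0, 4, length.out = 200)
  for (case in 1:3) {
    nnd <- rexp(30, 1)
    border <- runif(30, 0, 2)
    d <- pmin(nnd, border)
    ev <- as.integer(nnd <= border)
    mine <- g_hat_km(nnd, border, r)
    sf <- survival::survfit(survival::Surv(d, ev) ~ 1)
    ref <- 1 - summary(sf, times = r, extend = TRUE)$surv
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("KM G-hat is monotone and bounded under arbitrary censoring", {
  set.seed(99)
  r <- seq(0, 3, length.out = 100)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    nnd <- rexp(n, rate = runif(1, 0.5, 3))
    border <- runif(n, 0, 2.5)
    g <- g_hat_km(nnd, border, r)
    expect_true(all(diff(g) >= -1e-12))
    expect_true(all(g >= 0 & g <= 1))
    expect_equal(g[1], 0)
  }
})

test_that("MAD statistic finds the largest deviation and its sign", {
  r <- seq(0, 2, length.out = 50)
  g <- g_theoretical(r, 0.5)
  expect_equal(mad_statistic(g, g, r)$u_statistic, 0)
  res <- mad_statistic(pmin(g + 0.2, 1), g, r)
  expect_equal(res$u_statistic, 0.2, tolerance = 1e-9)
  expect_equal(res$direction, 1)
  expect_error(mad_statistic(g, g[-1], r), "grid")
})

test_that("MAD on the standard grid agrees with a dense-grid refinement", {
  g <- plot_geometry()
  set.seed(4)
  pat <- simulate_csr_pattern(15, 15, g)
  nn <- cross_nnd(pat$from, pat$to, g)
  lam <- 15 / g$area
  u_std <- {
    r <- nnd_grid(g, 512)
    mad_statistic(g_hat_km(nn$nnd, nn$border, r),
                  g_theoretical(r, lam), r)$u_statistic
  }
  u_dense <- {
    r <- nnd_grid(g, 8192)
    mad_statistic(g_hat_km(nn$nnd, nn$border, r),
                  g_theoretical(r, lam), r)$u_statistic
  }
  # grid refinement changes the maximum by at most the G slope times step
  expect_lt(abs(u_std - u_dense), 0.01)
})
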