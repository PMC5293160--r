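test_that("inducer selection applies the start and induction rules", {
  norm <- make_norm(list(
    keep = cbind(c(5, 40, 80), c(0, 0, 0)),     # starts 5, reaches 80
    high = cbind(c(15, 60, 100), c(0, 0, 0)),   # starts at 15: out
    weak = cbind(c(5, 40, 70), c(0, 0, 0))))    # peaks at 70: out
  expect_identical(select_inducers(norm, "pct3"), "keep")
  # boundary: start exactly 10 fails "below 10"; peak exactly 75 passes
  edge <- make_norm(list(a = cbind(c(10, 80), c(0, 0)),
                         b = cbind(c(9.9, 75), c(0, 0))))
  expect_identical(select_inducers(edge, "pct3"), "b")
})

test_that("induction lag interpolates the first upward crossing", {
  lg <- induction_lag(c(100, 120), c(8, 12), threshold = 10)
  expect_equal(lg$lag, 110)
  expect_false(lg$censored)
  # never crosses: censored at the last observation
  cen <- induction_lag(c(0, 20, 40), c(1, 5, 9), threshold = 10)
  expect_true(cen$censored)
  expect_identical(cen$lag, 40)
  # starts above: zero lag with a flag
  above <- induction_lag(c(0, 20), c(50, 60), threshold = 10)
  expect_identical(above$lag, 0)
  expect_true(above$started_above)
  # only the FIRST upward crossing counts
  multi <- induction_lag(c(0, 20, 40, 60), c(0, 20, 5, 30), threshold = 10)
  expect_equal(multi$lag, 10)
})

test_that("ECDF bands are valid pointwise percentile intervals", {
  lags <- c(10, 20, 30, 40)
  eb <- ecdf_with_ci(lags, B = 500, seed = 3, grid = c(5, 25, 45))
  expect_equal(eb$band$ecdf, c(0, 0.5, 1))
  expect_true(all(eb$band$lo <= eb$band$ecdf),
              all(eb$band$ecdf <= eb$band$hi))
  expect_true(all(diff(eb$band$ecdf) >= 0))
  # identical lags: band collapses off the step
  same <- ecdf_with_ci(rep(25, 6), B = 100, seed = 1, grid = c(10, 30))
  expect_equal(same$band$lo, same$band$hi)
  expect_error(ecdf_with_ci(5, B = 10, seed = 1), "at least 2")
  expect_error(ecdf_with_ci(c(1, 2), B = 10), "seed")
  # invariant to cell ordering
  a <- ecdf_with_ci(c(3, 1, 4, 1, 5), B = 200, seed = 9)
  b <- ecdf_with_ci(sort(c(3, 1, 4, 1, 5)), B = 200, seed = 9)
  expect_equal(a$band$ecdf, b$band$ecdf)
})

test_that("censored cells are excluded from the band but reported", {
  lt <- tibble::tibble(cell_id = 1:5, lag = c(10, 20, 30, 40, 99),
                       censored = c(rep(FALSE, 4), TRUE),
                       started_above = FALSE)
  eb <- ecdf_with_ci(lt, B = 100, seed = 2, grid = c(50))
  expect_identical(eb$n, 4L)
  expect_identical(eb$n_censored, 1L)
  expect_equal(eb$band$ecdf, 1)  # the censored 99 never entered
})

test_that("viability proportions carry Wilson intervals", {
  # independent arithmetic for 8/10 at 95%:
  z <- qnorm(0.975)
  ctr <- (0.8 + z^2 / 20) / (1 + z^2 / 10)
  half <- z / (1 + z^2 / 10) * sqrt(0.8 * 0.2 / 10 + z^2 / 400)
  tracks <- tibble::tibble(
    frame = rep(1:3, each = 10), t_min = rep(c(0, 20, 40), each = 10),
    class = "exp",
    alive = c(rep(1, 10), rep(c(1, 0), c(8, 2)), rep(0, 10)))
  v <- viability_curve(tracks)
  expect_equal(v$prop, c(1, 0.8, 0))
  expect_equal(v$lo[2], ctr - half, tolerance = 1e-12)
  expect_equal(v$hi[2], ctr + half, tolerance = 1e-12)
  expect_equal(round(c(v$lo[2], v$hi[2]), 3), c(0.490, 0.943))
  expect_equal(v$hi[1], 1)
  expect_equal(v$lo[3], 0)
  # control/bad cells never enter the denominator
  tracks2 <- dplyr::bind_rows(tracks, tibble::tibble(
    frame = 1, t_min = 0, class = "control", alive = 0))
  expect_equal(viability_curve(tracks2)$n[1], 10L)
})

test_that("movement medians measure displacement per minute", {
  bf <- tibble::tibble(
    cell_id = rep(1:3, each = 2),
    frame_bf = rep(1:2, 3), t_min = rep(c(0, 2), 3),
    x_um = c(0, 0.2, 0, 0.4, 0, 0.6), y_um = 0)
  mv <- movement_median(bf, B = 50, seed = 1)
  expect_equal(mv$median_um_min, 0.2)   # displacements {.2,.4,.6}/2 min
  expect_identical(mv$n, 3L)
  # stationary cells: zero median, zero-width interval
  still <- tibble::tibble(cell_id = rep(1:2, each = 3),
                          frame_bf = rep(1:3, 2),
                          t_min = rep(c(0, 2, 4), 2),
                          x_um = 1, y_um = 2)
  ms <- movement_median(still, B = 20, seed = 1)
  expect_true(all(ms$median_um_min == 0))
  # a frame with one displacement is absent
  lone <- bf[bf$cell_id == 1, ]
  expect_identical(nrow(movement_median(lone, B = 10, seed = 1)), 0L)
})

test_that("variance decomposition nails the edge cases", {
  set.seed(5)
  # shared mean, independent noise: fraction near 0
  d0 <- tidyr::expand_grid(cell_id = 1:40, t_min = seq(900, 1480, 20))
  d0$experiment <- "e"
  d0$pct1 <- rnorm(nrow(d0))
  v0 <- variance_decomposition(d0, B = 0)
  expect_lt(v0$intercell_fraction, 0.05)
  # spread cell means, zero residual: fraction exactly 1
  d1 <- d0
  d1$pct1 <- rep(rnorm(40, sd = 3), each = 30)
  v1 <- variance_decomposition(d1, B = 0)
  expect_equal(v1$intercell_fraction, 1)
  # per-timepoint constants are removed by centering
  d2 <- d1
  d2$pct1 <- d2$pct1 + 50 * sin(d2$t_min / 100)
  v2 <- variance_decomposition(d2, B = 0)
  expect_equal(v2$intercell_fraction, v1$intercell_fraction)
  expect_error(variance_decomposition(d0[d0$cell_id == 1, ], B = 0),
               "fewer than")
})

test_that("variance decomposition agrees with a REML mixed model", {
  skip_if_not_installed("lme4")
  set.seed(31)
  n_cell <- 60; n_t <- 25
  d <- tidyr::expand_grid(cell_id = seq_len(n_cell),
                          t_min = seq(900, by = 20, length.out = n_t))
  d$experiment <- "e"
  d$pct1 <- rep(rnorm(n_cell, sd = 2), each = n_t) + rnorm(nrow(d))
  ours <- variance_decomposition(d, B = 0)
  fit <- lme4::lmer(pct1 ~ 1 + (1 | cell_id), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  reml_frac <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(ours$intercell_fraction, reml_frac, tolerance = 0.02)
})

test_that("bootstrap interval brackets the intercell fraction", {
  set.seed(77)
  d <- tidyr::expand_grid(cell_id = 1:50, t_min = seq(900, 1480, 20))
  d$experiment <- "e"
  d$pct1 <- rep(rnorm(50, sd = 2), each = 30) + rnorm(nrow(d))
  v <- variance_decomposition(d, B = 100, seed = 8)
  expect_true(v$ci95[["lo"]] <= v$intercell_fraction)
  expect_true(v$ci95[["hi"]] >= v$intercell_fraction)
  expect_gt(v$intercell_fraction, 0.6)
})
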