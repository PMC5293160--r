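test_that("circular variance and sd match their analytic values", {
  expect_identical(circular_variance(c(0, 0, 0)), 0)
  expect_equal(circular_variance(c(0, pi)), 1)
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2)
  expect_identical(circular_sd(c(0.4, 0.4)), 0)
  expect_equal(circular_sd(c(0, pi / 2)), sqrt(log(2)))
  expect_error(circular_variance(numeric(0)), "empty")
  expect_error(circular_sd(c(0, pi)), "resultant")
  # diverges as the resultant shrinks
  expect_gt(circular_sd(c(0, pi - 1e-4)), 4)
})

test_that("circular statistics are rotation- and magnitude-invariant", {
  set.seed(14)
  for (i in 1:20) {
    th <- runif(sample(2:30, 1), -pi, pi)
    rot <- runif(1, -10, 10)
    expect_equal(circular_variance(th + rot), circular_variance(th),
                 tolerance = 1e-12)
    v <- circular_variance(th)
    expect_gte(v, 0)
    expect_lte(v, 1)
    if (1 - v > 1e-8) {
      expect_equal(circular_sd(th + rot), circular_sd(th),
                   tolerance = 1e-9)
    }
  }
})

test_that("state-space bins are half-open, zero-aligned, floor-divided", {
  expect_identical(assign_bin(7, 3), tibble::tibble(i3 = 1L, i1 = 0L))
  expect_identical(assign_bin(-2, 0), tibble::tibble(i3 = -1L, i1 = 0L))
  expect_identical(assign_bin(6, 6), tibble::tibble(i3 = 1L, i1 = 1L))
  expect_identical(assign_bin(5.999, 0)$i3, 0L)
  b <- assign_bin(c(0, 11.9, 12), c(-0.1, 50, 100), width = 6)
  expect_identical(b$i3, c(0L, 1L, 2L))
  expect_identical(b$i1, c(-1L, 8L, 16L))
})

test_that("velocities come from consecutive tracked frames only", {
  expect_equal(cell_velocity(c(3, 3), c(9, 9), 20), c(0.3, 0.3))
  expect_identical(cell_velocity(5, 5, 20), 0)
  norm <- make_norm(list(
    a = cbind(c(3, 9, 15), c(3, 9, 15)),   # tracked throughout
    b = cbind(c(3, NA, 15), c(3, NA, 15))))
  norm <- norm[!is.na(norm$pct3), ]        # cell b loses frame 2
  vf <- estimate_field(norm, width = 6)
  # cell b's frame-1 point has no next frame: excluded from members
  expect_false(any(vf$members$cell_id == "b" & vf$members$frame == 1))
  expect_true(any(vf$members$cell_id == "a" & vf$members$frame == 1))
})

test_that("field estimation aggregates members per bin with circular variance", {
  norm <- make_norm(list(
    a = cbind(c(3, 9), c(3, 9)),     # velocity (0.3, 0.3)
    b = cbind(c(3, 9), c(3, -3))))   # velocity (0.3, -0.3)
  vf <- estimate_field(norm, width = 6)
  f <- vf$field[vf$field$i3 == 0 & vf$field$i1 == 0, ]
  expect_identical(f$n, 2L)
  expect_equal(f$v3, 0.3)
  expect_equal(f$v1, 0)
  expect_equal(f$circ_var, 1 - sqrt(2) / 2)
  one <- make_norm(list(a = cbind(c(3, 9), c(3, 9))))
  f1 <- estimate_field(one, width = 6)$field
  expect_identical(f1$n, 1L)
  expect_equal(c(f1$v3, f1$v1), c(0.3, 0.3))
  expect_identical(f1$circ_var, 0)
  # empty input gives an empty, valid field
  empty <- make_norm(list(a = cbind(c(1, 1), c(1, 1))))[0, ]
  expect_identical(nrow(estimate_field(empty)$field), 0L)
})

test_that("field estimation ignores row order and cell labels", {
  set.seed(6)
  cells <- lapply(1:30, function(i) {
    n <- 8
    cbind(cumsum(runif(n, 0, 12)), cumsum(runif(n, 0, 12)))
  })
  names(cells) <- paste0("c", 1:30)
  norm <- make_norm(cells)
  vf1 <- estimate_field(norm)
  shuf <- norm[sample(nrow(norm)), ]
  shuf$cell_id <- paste0("relabel_", shuf$cell_id)
  vf2 <- estimate_field(shuf)
  o1 <- vf1$field[order(vf1$field$i3, vf1$field$i1), ]
  o2 <- vf2$field[order(vf2$field$i3, vf2$field$i1), ]
  expect_equal(o1$n, o2$n)
  expect_equal(o1$v3, o2$v3)
  expect_equal(o1$circ_var, o2$circ_var)
})

test_that("zero-velocity members count toward n but not the circular stats", {
  norm <- make_norm(list(
    a = cbind(c(3, 3), c(3, 3)),      # does not move: no direction
    b = cbind(c(3, 9), c(3, 9))))
  f <- estimate_field(norm, width = 6)$field
  expect_identical(f$n, 2L)
  expect_identical(f$circ_var, 0)     # only b contributes a direction
})

test_that("cutoff frames follow the 95%-inducer and five-high-frames rules", {
  # 20 identical step cells: induce (>=75) at frame 6, >85 from frame 6
  step <- function(jump_at, n = 30) {
    g <- c(rep(1, jump_at - 1), rep(95, n - jump_at + 1))
    cbind(g, g)
  }
  cells <- lapply(3:22, step)          # one cell crossing per frame
  names(cells) <- paste0("c", 3:22)
  norm <- make_norm(cells)
  co <- cutoff_frames(norm)
  # 19 of 20 inducers (95%) have induced by frame 21
  expect_identical(co$experiment_frame, 21L)
  # the earliest cell is above 85% from frame 3 on: cut at its 5th high frame
  expect_identical(co$cutoffs$cutoff_frame[co$cutoffs$cell_id == "c3"],
                   7L)
  # the straggler (crosses at 22) has no high frames before F: cut at F
  expect_identical(co$cutoffs$cutoff_frame[co$cutoffs$cell_id == "c22"],
                   21L)
  # all identical cells -> all cutoffs equal
  same <- make_norm(stats::setNames(lapply(1:12, function(i) step(6)),
                                    paste0("s", 1:12)))
  cs <- cutoff_frames(same)
  expect_identical(length(unique(cs$cutoffs$cutoff_frame)), 1L)
  # a never-inducing population is an error
  low <- make_norm(list(x = cbind(rep(1, 10), rep(1, 10)),
                        y = cbind(rep(2, 10), rep(2, 10))))
  expect_error(cutoff_frames(low), "no inducing")
  # applying cutoffs drops the later frames
  cut <- apply_cutoffs(norm, co)
  expect_lte(max(cut$frame[cut$cell_id == "c3"]), 7)
})

test_that("consistency statistic matches the enumerated three-experiment case", {
  # brute-force oracle, computed first: constant directions {0, 0, pi/2};
  # every resample of a constant set is constant, so the statistic is the
  # circular sd of the three means: resultant (2/3, 1/3),
  # Rbar = sqrt(5)/3, sd = sqrt(-2 log(sqrt(5)/3))
  oracle <- sqrt(-2 * log(sqrt(sum(c(2 / 3, 1 / 3)^2))))
  expect_equal(oracle, sqrt(-2 * log(sqrt(5) / 3)), tolerance = 1e-12)
  fields <- list(e1 = make_field_with_dirs(rep(0, 12)),
                 e2 = make_field_with_dirs(rep(0, 12)),
                 e3 = make_field_with_dirs(rep(pi / 2, 12)))
  cm <- consistency_statistic(fields, seed = 1)
  expect_identical(nrow(cm$map), 1L)
  expect_equal(cm$map$stat, oracle, tolerance = 1e-12)
  # identical directions everywhere: statistic exactly 0
  same <- consistency_statistic(list(a = make_field_with_dirs(rep(1, 15)),
                                     b = make_field_with_dirs(rep(1, 15))),
                                seed = 2)
  expect_equal(same$map$stat, 0)
  expect_error(consistency_statistic(fields[1], seed = 1), "at least 2")
  expect_error(consistency_statistic(fields), "seed")
})

test_that("bins under the member threshold are absent, not zero", {
  fields <- list(a = make_field_with_dirs(rep(0, 9)),     # 9 < 10
                 b = make_field_with_dirs(rep(0, 30)))
  cm <- consistency_statistic(fields, seed = 3)
  expect_identical(nrow(cm$map), 0L)
  # same bins, enough members everywhere: present
  cm2 <- consistency_statistic(
    list(a = make_field_with_dirs(rep(0, 10)),
         b = make_field_with_dirs(rep(0, 30))), seed = 3)
  expect_identical(nrow(cm2$map), 1L)
})

test_that("consistency map is reproducible under a fixed seed", {
  set.seed(99)
  fields <- list(
    a = make_field_with_dirs(runif(40, 0, 0.6)),
    b = make_field_with_dirs(runif(40, 0.2, 0.9)),
    c = make_field_with_dirs(runif(40, -0.3, 0.4)))
  m1 <- consistency_statistic(fields, seed = 7)
  m2 <- consistency_statistic(fields, seed = 7)
  expect_identical(m1$map, m2$map)
  m3 <- consistency_statistic(fields, seed = 8)
  expect_false(identical(m1$map$stat, m3$map$stat))
})

test_that("map interpolation is bilinear, bounded, and never extrapolates", {
  mk_map <- function(df) {
    structure(list(map = df, width = 6, B = 500, m = 10, seed = 1),
              class = "consistency_map")
  }
  # two horizontally adjacent bins 0 and 1: midpoint interpolates to 0.5
  two <- mk_map(tibble::tibble(i3 = c(0L, 1L), i1 = c(0L, 0L),
                               stat = c(0, 1), n_min = 10L))
  fine <- interpolate_map(two, factor = 2)
  mid <- fine[abs(fine$g3 - 6) < 1e-9 & abs(fine$g1 - 3) < 1e-9, ]
  expect_equal(mid$stat, 0.5)
  expect_true(all(fine$stat >= 0 & fine$stat <= 1))
  # uniform map stays uniform
  uni <- mk_map(tibble::tibble(i3 = c(0L, 1L, 0L, 1L),
                               i1 = c(0L, 0L, 1L, 1L),
                               stat = rep(0.3, 4), n_min = 10L))
  expect_true(all(abs(interpolate_map(uni, 4)$stat - 0.3) < 1e-12))
  # an isolated bin comes back unchanged
  iso <- mk_map(tibble::tibble(i3 = 2L, i1 = 5L, stat = 0.7, n_min = 12L))
  expect_identical(interpolate_map(iso)$stat, 0.7)
  # absent neighbours leave fine cells absent (no extrapolation)
  gap <- mk_map(tibble::tibble(i3 = c(0L, 2L), i1 = c(0L, 0L),
                               stat = c(0.1, 0.9), n_min = 10L))
  fg <- interpolate_map(gap, 2)
  expect_false(any(fg$g3 > 3.1 & fg$g3 < 14.9))  # nothing between centers
})
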