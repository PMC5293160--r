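#' Circular variance of a set of directions
#'
#' `1 - Rbar`, where `Rbar` is the mean resultant length of the unit
#' vectors of the angles. Ranges from 0 (all directions identical) to 1
#' (directions perfectly dispersed). Magnitudes play no role: every
#' direction enters as a unit vector.
#'
#' @param angles Directions in radians (length >= 1).
#' @return Value in \[0, 1\].
#' @examples
#' circular_variance(c(0, 0, 0))   # 0
#' circular_variance(c(0, pi))     # 1
#' circular_variance(c(0, pi / 2)) # 1 - sqrt(2)/2
#' @export
circular_variance <- function(angles) {
  if (length(angles) == 0) stop("circular_variance(): empty input")
  stopifnot(all(is.finite(angles)))
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  1 - rbar
}

#' Circular standard deviation of a set of directions
#'
#' `sqrt(-2 * log(Rbar))` in radians (Mardia convention). Diverges as the
#' mean resultant length approaches zero (perfectly dispersed directions),
#' and `Rbar = 0` is an error rather than infinity.
#'
#' @param angles Directions in radians.
#' @return Circular sd in radians.
#' @examples
#' circular_sd(c(0.4, 0.4))     # 0
#' circular_sd(c(0, pi / 2))    # sqrt(log(2))
#' @export
circular_sd <- function(angles) {
  if (length(angles) == 0) stop("circular_sd(): empty input")
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  if (rbar <= .Machine$double.eps) {
    stop("circular_sd(): undefined for zero resultant length ",
         "(perfectly dispersed directions)")
  }
  sqrt(-2 * log(min(rbar, 1)))
}

#' Mean direction of a set of angles
#' @param angles Directions in radians.
#' @return Direction of the resultant vector, radians in (-pi, pi].
#' @keywords internal
mean_direction <- function(angles) {
  atan2(mean(sin(angles)), mean(cos(angles)))
}

#' Assign state-space bin indices
#'
#' Half-open floor-division binning of the (Gal3p%, Gal1p%) plane into
#' squares of `width` percent aligned so that 0% is a bin edge. Negative
#' expression (baseline noise) maps to negative indices.
#'
#' @param g3,g1 Percent-of-plateau coordinates (vectors allowed).
#' @param width Bin width in % (default 6).
#' @return Tibble `i3, i1` of integer bin indices; bin `i` covers
#'   `[i * width, (i + 1) * width)`.
#' @examples
#' assign_bin(7, 3)    # (1, 0)
#' assign_bin(-2, 0)   # (-1, 0)
#' assign_bin(6, 6)    # (1, 1): edges belong to the upper bin
#' @export
assign_bin <- function(g3, g1, width = 6) {
  stopifnot(all(is.finite(g3)), all(is.finite(g1)), width > 0)
  tibble::tibble(i3 = as.integer(floor(g3 / width)),
                 i1 = as.integer(floor(g1 / width)))
}

#' Finite-difference velocity between consecutive fluorescence frames
#'
#' @param pct_now,pct_next Percent coordinates at the frame and the next
#'   tracked frame (vectors or 2-column matrices).
#' @param dt Frame interval in minutes.
#' @return Velocity in %/min (same shape as input).
#' @export
cell_velocity <- function(pct_now, pct_next, dt = 20) {
  stopifnot(dt > 0)
  (pct_next - pct_now) / dt
}

#' Estimate the empirical vector field on the state space
#'
#' Every (cell, frame) observation inside `t_range` that is also tracked
#' into the next fluorescence frame contributes one velocity to the bin
#' containing its current position; a cell contributes each time it
#' visits a bin, regardless of when. Per bin the mean velocity vector and
#' the circular variance of the member directions are computed.
#' Zero-velocity members have no direction: they are excluded from the
#' circular statistics but counted in `n`.
#'
#' @param norm Normalized-track tibble with `cell_id, frame, t_min, pct3,
#'   pct1` (e.g. `normalize_experiment()$data`), one experiment.
#' @param t_range Minutes to include (default `c(0, 900)`, the induction
#'   period).
#' @param width Bin width in %.
#' @param frame_interval Fluorescence frame interval, minutes.
#' @return List of class `vector_field`: `field` (tibble `i3, i1, lo3,
#'   lo1, n, v3, v1, circ_var`), `members` (tibble `i3, i1, cell_id,
#'   frame, theta, speed, v3, v1`), `width`, `t_range`.
#' @export
estimate_field <- function(norm, t_range = c(0, 900), width = 6,
                           frame_interval = 20) {
  stopifnot(all(c("cell_id", "frame", "t_min", "pct3", "pct1") %in%
                  names(norm)))
  cur <- norm[norm$t_min >= t_range[1] & norm$t_min <= t_range[2], ]
  nxt <- norm[, c("cell_id", "frame", "pct3", "pct1")]
  nxt$frame <- nxt$frame - 1L
  names(nxt)[3:4] <- c("pct3_next", "pct1_next")
  mem <- dplyr::inner_join(cur, nxt, by = c("cell_id", "frame"))
  if (nrow(mem) == 0) {
    return(structure(list(field = tibble::tibble(
      i3 = integer(), i1 = integer(), lo3 = numeric(), lo1 = numeric(),
      n = integer(), v3 = numeric(), v1 = numeric(), circ_var = numeric()),
      members = tibble::tibble(), width = width, t_range = t_range),
      class = "vector_field"))
  }
  mem$v3 <- cell_velocity(mem$pct3, mem$pct3_next, frame_interval)
  mem$v1 <- cell_velocity(mem$pct1, mem$pct1_next, frame_interval)
  b <- assign_bin(mem$pct3, mem$pct1, width)
  mem$i3 <- b$i3
  mem$i1 <- b$i1
  mem$speed <- sqrt(mem$v3^2 + mem$v1^2)
  mem$theta <- ifelse(mem$speed > 0, atan2(mem$v1, mem$v3), NA_real_)
  members <- mem[, c("i3", "i1", "cell_id", "frame", "theta", "speed",
                     "v3", "v1")]
  field <- members |>
    dplyr::group_by(.data$i3, .data$i1) |>
    dplyr::summarise(
      n = dplyr::n(),
      v3 = mean(.data$v3), v1 = mean(.data$v1),
      circ_var = if (all(is.na(.data$theta))) NA_real_ else
        circular_variance(.data$theta[!is.na(.data$theta)]),
      .groups = "drop") |>
    dplyr::mutate(lo3 = .data$i3 * width, lo1 = .data$i1 * width) |>
    dplyr::select("i3", "i1", "lo3", "lo1", "n", "v3", "v1", "circ_var")
  structure(list(field = field, members = members, width = width,
                 t_range = t_range),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat("<vector_field>", nrow(x$field), "bins,",
      nrow(x$members), "member velocities, width", x$width, "%\n")
  invisible(x)
}

#' Per-cell cutoff frames for the consistency analysis
#'
#' Removes most of the plateau period before consistency calculations.
#' The experiment-specific frame `F` is the first frame by which 95% of
#' the inducing cells (see [select_inducers()]) have first reached the
#' induced criterion (>= `induced_threshold`% of Gal1p plateau). A cell
#' that spends at least `min_high_frames` frames above `high_threshold`%
#' Gal1p before `F` is cut at its `min_high_frames`-th such frame; every
#' other cell is cut at `F`. Only data at or before the cutoff enter the
#' consistency statistic.
#'
#' @param norm Normalized-track tibble (`cell_id, frame, pct1, pct3`).
#' @param induced_threshold Percent defining "induced" (default 75, the
#'   inducer criterion).
#' @param high_threshold Percent defining the plateau band (default 85).
#' @param min_high_frames Frames above `high_threshold` before the
#'   per-cell rule applies (default 5).
#' @param coverage Fraction of inducers defining `F` (default 0.95).
#' @return List with `cutoffs` (tibble `cell_id, cutoff_frame`) and
#'   `experiment_frame` (`F`).
#' @export
cutoff_frames <- function(norm, induced_threshold = 75,
                          high_threshold = 85, min_high_frames = 5,
                          coverage = 0.95) {
  inducers <- select_inducers(norm, channel = "pct1",
                              induce_to = induced_threshold)
  if (length(inducers) == 0) {
    stop("cutoff_frames(): no inducing cells")
  }
  ind <- norm[norm$cell_id %in% inducers & !is.na(norm$pct1), ]
  first_induced <- ind |>
    dplyr::filter(.data$pct1 >= induced_threshold) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(f = min(.data$frame), .groups = "drop")
  fs <- sort(first_induced$f)
  F_exp <- fs[ceiling(coverage * length(fs))]
  high <- norm[!is.na(norm$pct1) & norm$pct1 > high_threshold &
                 norm$frame < F_exp, ]
  fifth <- high |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_high = dplyr::n(),
                     fifth = if (dplyr::n() >= min_high_frames)
                       sort(.data$frame)[min_high_frames] else NA_integer_,
                     .groups = "drop")
  cells <- unique(norm$cell_id)
  cutoffs <- tibble::tibble(cell_id = cells, cutoff_frame = F_exp)
  hit <- match(cutoffs$cell_id, fifth$cell_id)
  use <- !is.na(hit) & !is.na(fifth$fifth[hit])
  cutoffs$cutoff_frame[use] <- fifth$fifth[hit[use]]
  list(cutoffs = cutoffs, experiment_frame = F_exp)
}

#' Apply per-cell cutoff frames to a normalized track table
#' @param norm Normalized-track tibble.
#' @param cutoffs Result of [cutoff_frames()].
#' @return Rows at or before each cell's cutoff frame.
#' @export
apply_cutoffs <- function(norm, cutoffs) {
  co <- cutoffs$cutoffs
  m <- match(norm$cell_id, co$cell_id)
  norm[!is.na(m) & norm$frame <= co$cutoff_frame[m], ]
}

#' Cross-experiment consistency of flow directions
#'
#' For every state-space bin holding at least `min_n` member directions in
#' each experiment, each experiment's directions are resampled `B` times
#' with replacement at sample size `m` and the mean direction of each
#' replicate taken. For each of the `B` replicates, the circular standard
#' deviation of the experiments' resampled mean directions is computed;
#' the statistic is the mean of these `B` circular standard deviations.
#' Near-zero values mean the experiments' flows agree in that bin. Bins
#' failing `min_n` in any experiment are absent from the map, not zero.
#'
#' @param fields Named list (>= 2) of [estimate_field()] results, one per
#'   experiment, with cutoff-frame filtering already applied to their
#'   input tracks.
#' @param min_n Minimum member directions per experiment per bin.
#' @param B Number of bootstrap replicates.
#' @param m Resample size.
#' @param seed RNG seed (mandatory: the map must be reproducible).
#' @return List of class `consistency_map`: `map` (tibble `i3, i1, stat,
#'   n_min`), `width`, `B`, `m`, `seed`.
#' @export
consistency_statistic <- function(fields, min_n = 10, B = 500, m = 10,
                                  seed) {
  if (length(fields) < 2) {
    stop("consistency_statistic(): need at least 2 experiments")
  }
  if (missing(seed)) stop("consistency_statistic(): seed is mandatory")
  stopifnot(all(vapply(fields, inherits, logical(1), "vector_field")))
  width <- fields[[1]]$width
  set.seed(as.integer(seed))
  dirs <- lapply(fields, function(f) {
    mm <- f$members[!is.na(f$members$theta), ]
    split(mm$theta, interaction(mm$i3, mm$i1, drop = TRUE))
  })
  keys <- Reduce(intersect, lapply(dirs, names))
  keys <- keys[vapply(keys, function(k) {
    all(vapply(dirs, function(d) length(d[[k]]) >= min_n, logical(1)))
  }, logical(1))]
  if (length(keys) == 0) {
    return(structure(list(map = tibble::tibble(
      i3 = integer(), i1 = integer(), stat = numeric(), n_min = integer()),
      width = width, B = B, m = m, seed = seed),
      class = "consistency_map"))
  }
  rows <- lapply(keys, function(k) {
    # B resampled mean directions per experiment
    means <- vapply(dirs, function(d) {
      th <- d[[k]]
      idx <- matrix(sample.int(length(th), B * m, replace = TRUE), B, m)
      s <- matrix(sin(th)[idx], B, m)
      co <- matrix(cos(th)[idx], B, m)
      atan2(rowMeans(s), rowMeans(co))
    }, numeric(B))                      # B x n_experiments
    sds <- apply(means, 1, circular_sd)
    ij <- as.integer(strsplit(k, ".", fixed = TRUE)[[1]])
    nmin <- min(vapply(dirs, function(d) length(d[[k]]), integer(1)))
    tibble::tibble(i3 = ij[1], i1 = ij[2], stat = mean(sds),
                   n_min = nmin)
  })
  structure(list(map = dplyr::bind_rows(rows), width = width, B = B,
                 m = m, seed = seed),
            class = "consistency_map")
}

#' @export
print.consistency_map <- function(x, ...) {
  cat("<consistency_map>", nrow(x$map), "bins, B =", x$B,
      ", m =", x$m, "\n")
  invisible(x)
}

#' Interpolate a consistency map onto a fine grid
#'
#' Bilinear interpolation between defined bin centers, subdividing each
#' bin `factor` times per side. Fine points whose surrounding centers are
#' not all defined stay absent: the map is never extrapolated past the
#' defined bins. Purely one-dimensional neighbourhoods (a run of adjacent
#' defined bins in a single row or column) are linearly interpolated
#' along that line.
#'
#' @param map A [consistency_statistic()] result.
#' @param factor Subdivision factor per bin side (default 4).
#' @return Tibble `g3, g1, stat` of fine-grid points (percent
#'   coordinates of the interpolated positions).
#' @export
interpolate_map <- function(map, factor = 4) {
  stopifnot(inherits(map, "consistency_map"), factor >= 1)
  mp <- map$map
  w <- map$width
  if (nrow(mp) < 2) {
    return(tibble::tibble(g3 = (mp$i3 + 0.5) * w, g1 = (mp$i1 + 0.5) * w,
                          stat = mp$stat))
  }
  val <- function(i, j) {
    hit <- mp$stat[mp$i3 == i & mp$i1 == j]
    if (length(hit)) hit[1] else NA_real_
  }
  step <- 1 / factor
  fine <- expand.grid(
    u = seq(min(mp$i3), max(mp$i3), by = step),
    v = seq(min(mp$i1), max(mp$i1), by = step))
  interp_one <- function(u, v) {
    i0 <- floor(u); j0 <- floor(v)
    fu <- u - i0; fv <- v - j0
    c00 <- val(i0, j0)
    c10 <- if (fu > 0) val(i0 + 1, j0) else c00
    c01 <- if (fv > 0) val(i0, j0 + 1) else c00
    c11 <- if (fu > 0 && fv > 0) val(i0 + 1, j0 + 1) else c10
    if (fv == 0 && fu == 0) return(c00)
    if (fv == 0) {
      if (is.na(c00) || is.na(c10)) return(NA_real_)
      return((1 - fu) * c00 + fu * c10)
    }
    if (fu == 0) {
      if (is.na(c00) || is.na(c01)) return(NA_real_)
      return((1 - fv) * c00 + fv * c01)
    }
    if (any(is.na(c(c00, c10, c01, c11)))) return(NA_real_)
    (1 - fu) * (1 - fv) * c00 + fu * (1 - fv) * c10 +
      (1 - fu) * fv * c01 + fu * fv * c11
  }
  fine$stat <- mapply(interp_one, fine$u, fine$v)
  out <- tibble::tibble(g3 = (fine$u + 0.5) * w, g1 = (fine$v + 0.5) * w,
                        stat = fine$stat)
  out[!is.na(out$stat), ]
}
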