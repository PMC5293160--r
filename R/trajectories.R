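#' Smooth a single-cell fluorescence time series
#'
#' Two-stage smoother: discrete Gaussian kernel convolution (sd `sigma`
#' frames, truncated at +/- 3 sigma) followed by local-linear loess with a
#' short span of `span_points` points. The series must lie on a regular
#' time grid. Boundaries are handled by point (odd) reflection about the
#' end values, which preserves constants and straight lines exactly; the
#' loess stage also reproduces straight lines exactly, so the smoother is
#' unbiased on locally linear signal.
#'
#' @param t Time grid (strictly increasing, regular spacing).
#' @param y Values on the grid.
#' @param sigma Gaussian kernel sd in frames (default 1 frame = one
#'   fluorescence interval).
#' @param span_points Number of points in the loess window (default 5).
#' @return Smoothed values on the same grid. Series with fewer than 3
#'   points are returned unchanged with attribute `"unsmoothed" = TRUE`;
#'   series shorter than `2 * span_points` get the kernel stage only (a
#'   local-linear fit is ill-conditioned there).
#' @export
smooth_trajectory <- function(t, y, sigma = 1, span_points = 5) {
  stopifnot(length(t) == length(y), all(is.finite(y)))
  n <- length(y)
  if (n < 3) {
    attr(y, "unsmoothed") <- TRUE
    return(y)
  }
  if (n > 1) {
    dtv <- diff(t)
    if (any(dtv <= 0) || diff(range(dtv)) > 1e-8 * mean(dtv)) {
      stop("smooth_trajectory(): time grid must be regular and increasing")
    }
  }
  # Gaussian convolution with odd reflection
  h <- min(max(1L, ceiling(3 * sigma)), n - 1L)
  w <- stats::dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  pad_l <- 2 * y[1] - y[seq(h + 1, 2)]
  pad_r <- 2 * y[n] - y[seq(n - 1, n - h)]
  yp <- c(pad_l, y, pad_r)
  yg <- vapply(seq_len(n), function(i) sum(w * yp[i:(i + 2 * h)]),
               numeric(1))
  # local-linear loess with a short span; skipped for series too short to
  # condition a local fit (the kernel stage already smooths those)
  if (n < 2 * span_points) return(yg)
  span <- min(1, span_points / n)
  # tiny spans trigger benign pseudoinverse notes from the exact fit
  fit <- try(suppressWarnings(
    stats::loess(yg ~ t, span = span, degree = 1,
                 family = "gaussian", surface = "direct")), silent = TRUE)
  if (inherits(fit, "try-error")) return(yg)
  as.numeric(suppressWarnings(
    stats::predict(fit, newdata = data.frame(t = t))))
}

#' Truncate a trajectory after a persistent post-peak drop
#'
#' Finds each channel's global peak in the smoothed series (ties broken to
#' the earliest frame) and removes all frames after the peak when either
#' rule fires: (a) more than `drop_frac` (default 80%) of the post-peak
#' frame-to-frame changes in that channel are decreases, or (b) any five
#' consecutive post-peak frames are monotone non-increasing with a total
#' drop of at least `drop_total` (default 50%) of the peak value. Such
#' tails are signatures of cell death, photobleaching, or tracking errors.
#' With two channels, truncation at either channel's peak removes the
#' frames of both.
#'
#' @param y Numeric matrix (frames x channels) or vector of smoothed
#'   values.
#' @param drop_frac Fraction of decreasing post-peak steps that triggers
#'   rule (a).
#' @param window Length of the monotone window for rule (b).
#' @param drop_total Required drop over the window, as a fraction of the
#'   peak value.
#' @return List with `keep` (logical index of retained frames) and
#'   `truncated_at` (last retained frame index, or `NA` when nothing was
#'   removed).
#' @export
truncate_post_peak <- function(y, drop_frac = 0.8, window = 5,
                               drop_total = 0.5) {
  y <- as.matrix(y)
  n <- nrow(y)
  cut_at <- NA_integer_
  for (ch in seq_len(ncol(y))) {
    v <- y[, ch]
    p <- which.max(v)  # earliest index at ties
    if (p >= n) next
    post <- v[p:n]
    steps <- diff(post)
    fired <- length(steps) > 0 && mean(steps < 0) > drop_frac
    if (!fired && length(post) >= window) {
      for (i in seq_len(length(post) - window + 1)) {
        seg <- post[i:(i + window - 1)]
        if (all(diff(seg) <= 0) && (seg[1] - seg[window]) >=
              drop_total * v[p]) {
          fired <- TRUE
          break
        }
      }
    }
    if (fired) cut_at <- min(cut_at, p, na.rm = TRUE)
  }
  keep <- rep(TRUE, n)
  if (!is.na(cut_at) && cut_at < n) keep[(cut_at + 1):n] <- FALSE
  list(keep = keep,
       truncated_at = if (any(!keep)) cut_at else NA_integer_)
}

#' Estimate the 100% plateau level of an experiment
#'
#' Each cell's maximum intensity within the plateau window is taken, and
#' the median of these per-cell maxima is the experiment's full-induction
#' (100%) level.
#'
#' @param df Tibble with `cell_id`, `t_min`, and the value column.
#' @param value Name of the intensity column.
#' @param window `(t_start, t_end)` minutes of the plateau period.
#' @return List of class `plateau_estimate`: `plateau_au`, `window`,
#'   `n_cells`, `value`.
#' @export
estimate_plateau <- function(df, value = "au_yfp", window = c(900, 1500)) {
  stopifnot(all(c("cell_id", "t_min", value) %in% names(df)),
            length(window) == 2, window[1] < window[2])
  w <- df[df$t_min >= window[1] & df$t_min <= window[2], ]
  if (nrow(w) == 0) {
    stop("estimate_plateau(): no observations in the plateau window")
  }
  maxima <- tapply(w[[value]], w$cell_id, max)
  structure(list(plateau_au = as.numeric(stats::median(maxima)),
                 window = window, n_cells = length(maxima), value = value),
            class = "plateau_estimate")
}

#' Normalize intensities to percent of plateau
#'
#' `pct = 100 * au / plateau_au`, assuming `au` is already control-cell
#' baselined so that 0 AU is the uninduced level. Values may exceed 100%
#' (overshoot) or be negative (baseline noise).
#'
#' @param au Baselined intensities.
#' @param plateau A [estimate_plateau()] result or a positive number.
#' @return Percent-of-plateau values.
#' @export
normalize_to_plateau <- function(au, plateau) {
  p <- if (inherits(plateau, "plateau_estimate")) plateau$plateau_au
       else as.numeric(plateau)
  if (!is.finite(p) || p <= 0) {
    stop("normalize_to_plateau(): plateau must be a positive number")
  }
  100 * au / p
}

#' Smooth, truncate, and plateau-normalize an experiment's tracks
#'
#' Per-cell pipeline over a baselined track table: both channels are
#' smoothed with [smooth_trajectory()], post-peak artifacts removed with
#' [truncate_post_peak()], the per-experiment plateau estimated from the
#' smoothed series with [estimate_plateau()], and intensities rescaled to
#' percent of plateau. Only experimental-class cells are normalized;
#' control and bad cells are dropped here.
#'
#' @param tracks Baselined track tibble (`au_yfp`, `au_cfp` re-zeroed on
#'   the control median).
#' @param sigma,span_points Smoother parameters, see [smooth_trajectory()].
#' @param plateau_window Minutes defining the plateau period.
#' @param truncate Apply post-peak truncation (default TRUE).
#' @return List of class `normalized_tracks`: `data` (tibble `experiment,
#'   cell_id, frame, t_min, pct3, pct1, pct3_raw, pct1_raw, truncated`),
#'   `plateau3`, `plateau1` (the [estimate_plateau()] objects). The
#'   `_raw` columns are plateau-normalized but unsmoothed: first-crossing
#'   (onset) statistics should be computed from them, because smoothing
#'   before event detection biases crossing times toward the steep side
#'   of the induction front.
#' @export
normalize_experiment <- function(tracks, sigma = 1, span_points = 5,
                                 plateau_window = c(900, 1500),
                                 truncate = TRUE) {
  need <- c("experiment", "cell_id", "frame", "t_min", "au_yfp", "au_cfp",
            "class")
  stopifnot(all(need %in% names(tracks)))
  exp_rows <- tracks[tracks$class == "exp", need]
  if (nrow(exp_rows) == 0) {
    stop("normalize_experiment(): no experimental-class rows ",
         "(all frames excluded upstream?)")
  }
  exp_rows <- exp_rows[order(exp_rows$cell_id, exp_rows$t_min), ]
  parts <- split(exp_rows, exp_rows$cell_id)
  smoothed <- lapply(parts, function(d) {
    d$au_yfp_raw <- d$au_yfp
    d$au_cfp_raw <- d$au_cfp
    d$au_yfp <- smooth_trajectory(d$t_min, d$au_yfp, sigma, span_points)
    d$au_cfp <- smooth_trajectory(d$t_min, d$au_cfp, sigma, span_points)
    d$truncated <- FALSE
    if (truncate && nrow(d) > 2) {
      tr <- truncate_post_peak(cbind(d$au_yfp, d$au_cfp))
      if (any(!tr$keep)) {
        d <- d[tr$keep, ]
        d$truncated <- TRUE
      }
    }
    d
  })
  sm <- dplyr::bind_rows(smoothed)
  p3 <- estimate_plateau(sm, "au_yfp", plateau_window)
  p1 <- estimate_plateau(sm, "au_cfp", plateau_window)
  out <- tibble::tibble(
    experiment = sm$experiment, cell_id = sm$cell_id, frame = sm$frame,
    t_min = sm$t_min,
    pct3 = normalize_to_plateau(sm$au_yfp, p3),
    pct1 = normalize_to_plateau(sm$au_cfp, p1),
    pct3_raw = normalize_to_plateau(sm$au_yfp_raw, p3),
    pct1_raw = normalize_to_plateau(sm$au_cfp_raw, p1),
    truncated = sm$truncated)
  structure(list(data = out, plateau3 = p3, plateau1 = p1),
            class = "normalized_tracks")
}
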