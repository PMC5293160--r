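#' Select inducing cells
#'
#' A cell counts as an inducer when its first observed level is below
#' `start_below`% of plateau and its maximum reaches at least
#' `induce_to`% (the criterion used for the lag distributions; in
#' glucose-history conditions most cells fail it).
#'
#' @param norm Normalized-track tibble.
#' @param channel Column holding the percent values (`"pct3"` or
#'   `"pct1"`).
#' @param start_below Starting-level criterion, % (default 10).
#' @param induce_to Induction criterion, % (default 75).
#' @return Vector of inducing `cell_id`s.
#' @export
select_inducers <- function(norm, channel = "pct3", start_below = 10,
                            induce_to = 75) {
  stopifnot(all(c("cell_id", "t_min", channel) %in% names(norm)))
  norm <- norm[!is.na(norm[[channel]]), ]
  per <- norm |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      start = .data[[channel]][which.min(.data$t_min)],
      peak = max(.data[[channel]]), .groups = "drop")
  per$cell_id[per$start < start_below & per$peak >= induce_to]
}

#' First-crossing induction lag of a trajectory
#'
#' Time of the first upward crossing of `threshold`% of plateau, linearly
#' interpolated between the bracketing frames. Cells that never cross are
#' censored at their last observation; cells already at or above the
#' threshold at their first frame get lag 0 with a flag.
#'
#' @param t Time grid, minutes.
#' @param pct Percent-of-plateau values.
#' @param threshold Crossing threshold in (0, 100\].
#' @return List: `lag` (minutes), `censored`, `started_above`.
#' @examples
#' induction_lag(c(100, 120), c(8, 12), 10)$lag  # 110
#' @export
induction_lag <- function(t, pct, threshold = 10) {
  stopifnot(length(t) == length(pct), threshold > 0, threshold <= 100)
  o <- order(t)
  t <- t[o]; pct <- pct[o]
  if (pct[1] >= threshold) {
    return(list(lag = 0, censored = FALSE, started_above = TRUE))
  }
  above <- which(pct >= threshold)
  if (length(above) == 0) {
    return(list(lag = t[length(t)], censored = TRUE,
                started_above = FALSE))
  }
  i <- above[1]
  frac <- (threshold - pct[i - 1]) / (pct[i] - pct[i - 1])
  list(lag = t[i - 1] + frac * (t[i] - t[i - 1]), censored = FALSE,
       started_above = FALSE)
}

#' Induction lags for every cell of an experiment
#'
#' @param norm Normalized-track tibble.
#' @param channel Percent column; use the unsmoothed `"pct3_raw"` /
#'   `"pct1_raw"` columns of [normalize_experiment()] output when
#'   available (smoothing biases onset times).
#' @param threshold Crossing threshold, %.
#' @param inducers_only Restrict to [select_inducers()] cells (default
#'   TRUE, the convention of the lag distributions).
#' @return Tibble `cell_id, lag, censored, started_above`.
#' @export
lag_table <- function(norm, channel = "pct3", threshold = 10,
                      inducers_only = TRUE) {
  cells <- if (inducers_only) select_inducers(norm, channel)
           else unique(norm$cell_id)
  norm <- norm[norm$cell_id %in% cells & !is.na(norm[[channel]]), ]
  parts <- split(norm, norm$cell_id)
  rows <- lapply(parts, function(d) {
    lg <- induction_lag(d$t_min, d[[channel]], threshold)
    tibble::tibble(cell_id = d$cell_id[1], lag = lg$lag,
                   censored = lg$censored,
                   started_above = lg$started_above)
  })
  dplyr::bind_rows(rows)
}

#' Empirical CDF of induction lags with a bootstrap confidence band
#'
#' Censored cells are excluded (their count is reported); the pointwise
#' 95% band comes from `B` resamples of the cells with replacement.
#'
#' @param lags Numeric lags in minutes, or a [lag_table()] tibble.
#' @param B Bootstrap replicates.
#' @param seed RNG seed (mandatory).
#' @param grid Evaluation grid in minutes (default: 200 points spanning
#'   the lags).
#' @param conf Confidence level.
#' @return List of class `ecdf_band`: `band` (tibble `t, ecdf, lo, hi`),
#'   `n`, `n_censored`, `B`, `seed`.
#' @export
ecdf_with_ci <- function(lags, B = 1000, seed, grid = NULL, conf = 0.95) {
  if (missing(seed)) stop("ecdf_with_ci(): seed is mandatory")
  n_cens <- 0L
  if (is.data.frame(lags)) {
    n_cens <- sum(lags$censored)
    lags <- lags$lag[!lags$censored]
  }
  if (length(lags) < 2) {
    stop("ecdf_with_ci(): need at least 2 uncensored lags")
  }
  set.seed(as.integer(seed))
  if (is.null(grid)) grid <- seq(0, max(lags), length.out = 200)
  n <- length(lags)
  e <- stats::ecdf(lags)(grid)
  boot <- matrix(sample(lags, n * B, replace = TRUE), B, n)
  bs <- vapply(grid, function(g) rowMeans(boot <= g), numeric(B))
  a <- (1 - conf) / 2
  lo <- apply(bs, 2, stats::quantile, probs = a, names = FALSE)
  hi <- apply(bs, 2, stats::quantile, probs = 1 - a, names = FALSE)
  structure(list(band = tibble::tibble(t = grid, ecdf = e,
                                       lo = pmin(lo, e), hi = pmax(hi, e)),
                 n = n, n_censored = n_cens, B = B, seed = seed),
            class = "ecdf_band")
}

#' Wilson score interval for a binomial proportion
#' @param x Successes. @param n Trials. @param conf Confidence level.
#' @return Named vector `c(lo, hi)`.
#' @keywords internal
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z / den * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lo = max(0, ctr - half), hi = min(1, ctr + half))
}

#' Proportion of live cells per frame with Wilson 95% intervals
#'
#' Dying cells carry `alive = 1` until death, so the curve is an upper
#' bound on viability. Control and bad-class cells are excluded.
#'
#' @param tracks Track tibble with `frame, t_min, class, alive`.
#' @param conf Confidence level.
#' @return Tibble `frame, t_min, n, alive, prop, lo, hi`.
#' @export
viability_curve <- function(tracks, conf = 0.95) {
  stopifnot(all(c("frame", "t_min", "class", "alive") %in% names(tracks)))
  d <- tracks[tracks$class == "exp", ]
  d |>
    dplyr::group_by(.data$frame, .data$t_min) |>
    dplyr::summarise(n = dplyr::n(), alive = sum(.data$alive),
                     .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(prop = .data$alive / .data$n,
                  lo = wilson_ci(.data$alive, .data$n, conf)[["lo"]],
                  hi = wilson_ci(.data$alive, .data$n, conf)[["hi"]]) |>
    dplyr::ungroup()
}

#' Median cell movement per bright-field frame with bootstrap intervals
#'
#' Physical displacement of each tracked cell between consecutive
#' bright-field frames, in microns per minute; the per-frame median
#' across cells is a surrogate for the amount of cell division in the
#' crowded field. Percentile bootstrap intervals resample cells within
#' the frame.
#'
#' @param bf Bright-field position tibble `cell_id, frame_bf, t_min,
#'   x_um, y_um`.
#' @param B Bootstrap replicates per frame.
#' @param seed RNG seed (mandatory).
#' @param conf Confidence level.
#' @param thin Keep every `thin`-th bright-field frame (default 1).
#' @return Tibble `frame_bf, t_min, n, median_um_min, lo, hi`; frames
#'   with fewer than 2 displacements are absent.
#' @export
movement_median <- function(bf, B = 200, seed, conf = 0.95, thin = 1) {
  if (missing(seed)) stop("movement_median(): seed is mandatory")
  stopifnot(all(c("cell_id", "frame_bf", "t_min", "x_um", "y_um") %in%
                  names(bf)))
  set.seed(as.integer(seed))
  bf <- bf[order(bf$cell_id, bf$frame_bf), ]
  same <- c(FALSE, bf$cell_id[-1] == bf$cell_id[-nrow(bf)] &
              bf$frame_bf[-1] == bf$frame_bf[-nrow(bf)] + 1L)
  disp <- tibble::tibble(
    frame_bf = bf$frame_bf[same], t_min = bf$t_min[same],
    d = sqrt(diff(bf$x_um)[same[-1]]^2 + diff(bf$y_um)[same[-1]]^2) /
      diff(bf$t_min)[same[-1]])
  if (thin > 1) disp <- disp[disp$frame_bf %% thin == 0, ]
  a <- (1 - conf) / 2
  rows <- lapply(split(disp, disp$frame_bf), function(fr) {
    v <- fr$d
    if (length(v) < 2) return(NULL)
    bm <- vapply(seq_len(B), function(b)
      stats::median(sample(v, replace = TRUE)), numeric(1))
    tibble::tibble(frame_bf = fr$frame_bf[1], t_min = fr$t_min[1],
                   n = length(v), median_um_min = stats::median(v),
                   lo = stats::quantile(bm, a, names = FALSE),
                   hi = stats::quantile(bm, 1 - a, names = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- out[order(out$frame_bf), ]
  out
}

#' Method-of-moments one-way variance components
#'
#' ANOVA expected-mean-squares estimator for the between-cell and
#' residual variance of centred repeated measures, valid for unbalanced
#' group sizes (`n0 = (N - sum(n_i^2) / N) / (k - 1)`). Negative
#' between-group estimates are truncated at zero.
#'
#' @param value Centred observations.
#' @param group Cell identifier per observation.
#' @return List `sigma2_cell, sigma2_resid, fraction`.
#' @keywords internal
vc_moments <- function(value, group) {
  group <- as.character(group)
  k <- length(unique(group))
  if (k < 2) stop("vc_moments(): need at least 2 cells")
  N <- length(value)
  ni <- tapply(value, group, length)
  gm <- mean(value)
  mi <- tapply(value, group, mean)
  ss_b <- sum(ni * (mi - gm)^2)
  ss_w <- sum((value - mi[group])^2)
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2c <- max((ms_b - ms_w) / n0, 0)
  list(sigma2_cell = s2c, sigma2_resid = ms_w,
       fraction = s2c / (s2c + ms_w))
}

#' Decompose plateau expression variance into intercell and residual parts
#'
#' Within the plateau window, the mean fluorescence at each
#' (experiment, timepoint) is subtracted — removing the shared time trend
#' and the experiment fixed effect — and the remaining variance is split
#' into a cell-specific component and residual within-cell fluctuation.
#' The reported `intercell_fraction` is
#' `sigma2_cell / (sigma2_cell + sigma2_resid)`; its 95% interval comes
#' from a percentile bootstrap across cells.
#'
#' @param norm Normalized-track tibble (may span several experiments;
#'   needs `experiment, cell_id, t_min` and the channel column).
#' @param channel Percent column to decompose (default `"pct1"`).
#' @param window Plateau window, minutes.
#' @param min_frames Minimum in-window frames per cell.
#' @param min_cells Minimum number of qualifying cells.
#' @param B Bootstrap replicates.
#' @param seed RNG seed (mandatory when `B > 0`).
#' @param conf Confidence level.
#' @return List of class `variance_decomposition`: `intercell_fraction`,
#'   `ci95`, `sigma2_cell`, `sigma2_resid`, `n_cells`, `window`.
#' @export
variance_decomposition <- function(norm, channel = "pct1",
                                   window = c(900, 1500), min_frames = 5,
                                   min_cells = 20, B = 200, seed,
                                   conf = 0.95) {
  stopifnot(all(c("experiment", "cell_id", "t_min", channel) %in%
                  names(norm)))
  d <- norm[norm$t_min >= window[1] & norm$t_min <= window[2] &
              !is.na(norm[[channel]]), ]
  ok <- d |>
    dplyr::group_by(.data$experiment, .data$cell_id) |>
    dplyr::filter(dplyr::n() >= min_frames) |>
    dplyr::ungroup()
  cells <- unique(paste(ok$experiment, ok$cell_id))
  if (length(cells) < max(2, min_cells)) {
    stop("variance_decomposition(): fewer than ", min_cells,
         " cells with >= ", min_frames, " in-window frames")
  }
  ok <- ok |>
    dplyr::group_by(.data$experiment, .data$t_min) |>
    dplyr::mutate(.v = .data[[channel]] - mean(.data[[channel]])) |>
    dplyr::ungroup()
  # cell ids are only unique within an experiment
  ok$.cell <- paste(ok$experiment, ok$cell_id)
  est <- vc_moments(ok$.v, ok$.cell)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    if (missing(seed)) stop("variance_decomposition(): seed is mandatory")
    set.seed(as.integer(seed))
    parts <- split(ok$.v, ok$.cell)
    fracs <- vapply(seq_len(B), function(b) {
      pick <- sample(names(parts), length(parts), replace = TRUE)
      v <- unlist(parts[pick], use.names = FALSE)
      g <- rep(seq_along(pick), lengths(parts[pick]))
      vc_moments(v, g)$fraction
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- stats::quantile(fracs, c(a, 1 - a), names = FALSE)
  }
  structure(list(intercell_fraction = est$fraction,
                 ci95 = c(lo = ci[1], hi = ci[2]),
                 sigma2_cell = est$sigma2_cell,
                 sigma2_resid = est$sigma2_resid,
                 n_cells = length(cells), window = window,
                 channel = channel, B = B),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "<variance_decomposition> intercell fraction %.3f (95%% CI %.3f-%.3f), %d cells\n",
    x$intercell_fraction, x$ci95[["lo"]], x$ci95[["hi"]], x$n_cells))
  invisible(x)
}
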