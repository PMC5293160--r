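#' Adjusted Fisher-Pearson sample skewness
#' @param x Numeric vector (length >= 3 for a defined value).
#' @return Skewness, or `NA` when undefined (n < 3 or zero variance).
#' @keywords internal
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / (sqrt(mean((x - mean(x))^2)))^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Remove punctum pixels from a cell's pixel sample
#'
#' Two-step rejection of small, high-intensity fluorescent spots. The
#' pixel values are first scaled to \[0, 1\] and the adjusted
#' Fisher-Pearson skewness computed on the scaled values; if it exceeds
#' `skew_threshold` (default 1.5), pixels whose original value exceeds
#' `median + mad_mult * MAD` are removed, where MAD is the plain
#' (unscaled) median absolute deviation about the median. One pass only;
#' the median pixel always survives, so the kept set is never empty.
#'
#' @param pixels Numeric vector of pixel intensities (length >= 2).
#' @param skew_threshold Skewness gate on the scaled values.
#' @param mad_mult MAD multiplier for the rejection threshold.
#' @return List with `kept` (surviving pixels), `removed` (rejected
#'   pixels), `n_removed`, `fired` (whether the gate tripped), and
#'   `degenerate` (constant input: skewness undefined, nothing removed).
#' @examples
#' remove_puncta(c(10:18, 200))$kept  # drops 200; mean of the rest is 14
#' @export
remove_puncta <- function(pixels, skew_threshold = 1.5, mad_mult = 7) {
  stopifnot(is.numeric(pixels), length(pixels) >= 2, all(is.finite(pixels)))
  rng <- range(pixels)
  if (rng[1] == rng[2]) {
    return(list(kept = pixels, removed = numeric(0), n_removed = 0L,
                fired = FALSE, degenerate = TRUE))
  }
  scaled <- (pixels - rng[1]) / (rng[2] - rng[1])
  sk <- sample_skewness(scaled)
  if (!is.finite(sk) || sk <= skew_threshold) {
    return(list(kept = pixels, removed = numeric(0), n_removed = 0L,
                fired = FALSE, degenerate = FALSE))
  }
  med <- stats::median(pixels)
  mad_plain <- stats::median(abs(pixels - med))
  if (mad_plain == 0) {  # threshold undefined; refuse to remove
    return(list(kept = pixels, removed = numeric(0), n_removed = 0L,
                fired = FALSE, degenerate = TRUE))
  }
  thr <- med + mad_mult * mad_plain
  keep <- pixels <= thr
  list(kept = pixels[keep], removed = pixels[!keep],
       n_removed = sum(!keep), fired = TRUE, degenerate = FALSE)
}

#' Frame context for quantification
#'
#' @param frame Frame index.
#' @param t_min Time in minutes.
#' @param background_median_au Median intensity of non-cell image areas
#'   (per channel), AU.
#' @param n_control_cells Number of control cells present in the frame.
#' @return A list of class `frame_context`.
#' @export
frame_context <- function(frame, t_min = NA_real_, background_median_au = 0,
                          n_control_cells = 0L) {
  stopifnot(is.finite(background_median_au), n_control_cells >= 0)
  structure(list(frame = frame, t_min = t_min,
                 background_median_au = background_median_au,
                 n_control_cells = as.integer(n_control_cells)),
            class = "frame_context")
}

#' Background-corrected, puncta-cleaned mean cell intensity
#'
#' Subtracts the frame's median background from every pixel, removes
#' punctum pixels with [remove_puncta()], and returns the mean of the
#' survivors. The mean may be negative for dim cells (baseline noise).
#'
#' @param pixels Numeric vector of raw pixel values (length >= 1).
#' @param frame_ctx A [frame_context()] with the background median.
#' @param ... Passed to [remove_puncta()].
#' @return A one-row tibble: `frame, mean_au, n_pixels_used,
#'   n_pixels_removed, puncta_fired, degenerate`.
#' @export
cell_mean_intensity <- function(pixels, frame_ctx, ...) {
  if (length(pixels) == 0) stop("cell_mean_intensity(): empty pixel array")
  stopifnot(inherits(frame_ctx, "frame_context"))
  px <- pixels - frame_ctx$background_median_au
  if (length(px) == 1) {
    return(tibble::tibble(frame = frame_ctx$frame, mean_au = px,
                          n_pixels_used = 1L, n_pixels_removed = 0L,
                          puncta_fired = FALSE, degenerate = TRUE))
  }
  rp <- remove_puncta(px, ...)
  tibble::tibble(frame = frame_ctx$frame, mean_au = mean(rp$kept),
                 n_pixels_used = length(rp$kept),
                 n_pixels_removed = rp$n_removed,
                 puncta_fired = rp$fired, degenerate = rp$degenerate)
}

#' Subtract the per-frame control-cell median
#'
#' Re-zeroes every cell's intensity on the control cells: within each
#' frame the median intensity of control-class cells is subtracted from
#' all cells, so the control median maps exactly to 0. Frames with fewer
#' than `min_controls` control cells are excluded (with a logged reason),
#' never silently corrected.
#'
#' @param df Tibble with at least `frame`, `class`, and the value column;
#'   `class` uses `"control"` for control cells.
#' @param value Name of the intensity column (string). Both `au_yfp` and
#'   `au_cfp` may be given; each is baselined independently.
#' @param min_controls Minimum control cells a frame needs to be retained.
#' @return List with `data` (baselined rows of retained frames) and
#'   `excluded` (tibble of dropped frames: `frame, n_controls, reason`).
#' @export
baseline_by_controls <- function(df, value = c("au_yfp", "au_cfp"),
                                 min_controls = 50) {
  stopifnot(all(c("frame", "class") %in% names(df)),
            all(value %in% names(df)))
  counts <- df |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(n_controls = sum(.data$class == "control"),
                     .groups = "drop")
  bad <- counts |> dplyr::filter(.data$n_controls < min_controls)
  excluded <- tibble::tibble(
    frame = bad$frame, n_controls = bad$n_controls,
    reason = sprintf("only %d control cells (< %d required)",
                     bad$n_controls, min_controls))
  keep <- df |> dplyr::filter(!.data$frame %in% bad$frame)
  for (v in value) {
    med <- keep |>
      dplyr::filter(.data$class == "control") |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(.ctrl_med = stats::median(.data[[v]]),
                       .groups = "drop")
    keep <- keep |>
      dplyr::left_join(med, by = "frame") |>
      dplyr::mutate(!!v := .data[[v]] - .data$.ctrl_med) |>
      dplyr::select(-".ctrl_med")
  }
  list(data = keep, excluded = excluded)
}

#' Drop cells tracked for too few bright-field frames
#'
#' Cells present for fewer than `min_frames` frames are removed; these are
#' mostly segmentation artifacts. Counting uses the bright-field table
#' when supplied (the intended usage), otherwise the rows of `tracks`
#' itself. Row ordering of the survivors is preserved.
#'
#' @param tracks Track tibble with a `cell_id` column.
#' @param bf Optional bright-field position tibble (`cell_id` per frame).
#' @param min_frames Minimum number of frames (default 5, inclusive).
#' @return The filtered track tibble; attribute `"n_cells_removed"` gives
#'   the number of cells dropped.
#' @export
filter_short_tracks <- function(tracks, bf = NULL, min_frames = 5) {
  stopifnot("cell_id" %in% names(tracks))
  src <- if (is.null(bf)) tracks else bf
  tab <- table(src$cell_id)
  short <- names(tab)[tab < min_frames]
  # cells absent from the counting source have zero frames there
  if (!is.null(bf)) {
    missing <- setdiff(unique(tracks$cell_id), names(tab))
    short <- c(short, missing)
  }
  out <- tracks[!(tracks$cell_id %in% short), , drop = FALSE]
  attr(out, "n_cells_removed") <- length(short)
  out
}

#' Quantify a pixel table into per-cell-per-frame intensities
#'
#' Vectorized application of background subtraction and puncta rejection
#' to a long pixel table, one group per (cell, frame, channel).
#'
#' @param pixel_tbl Tibble `cell_id, frame, channel, au_px`.
#' @param background Named numeric: background median AU per channel, or a
#'   single number for both.
#' @param ... Passed to [remove_puncta()].
#' @return Tibble `cell_id, frame, channel, mean_au, n_pixels_used,
#'   n_pixels_removed, puncta_fired`.
#' @export
quantify_pixels <- function(pixel_tbl, background = 0, ...) {
  stopifnot(all(c("cell_id", "frame", "channel", "au_px") %in%
                  names(pixel_tbl)))
  bgv <- if (length(background) == 1) {
    stats::setNames(rep(background, 2), c("yfp", "cfp"))
  } else background
  pixel_tbl |>
    dplyr::group_by(.data$cell_id, .data$frame, .data$channel) |>
    dplyr::summarise({
      rp <- remove_puncta(.data$au_px - bgv[[.data$channel[1]]], ...)
      tibble::tibble(mean_au = mean(rp$kept),
                     n_pixels_used = length(rp$kept),
                     n_pixels_removed = rp$n_removed,
                     puncta_fired = rp$fired)
    }, .groups = "drop")
}
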