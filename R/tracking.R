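#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle `[x0, x1) x [y0, y1)` restricting where
#' scan lines are placed and how far each transmural profile extends. Used to
#' keep the tracking away from side branches, cannulae or adherent debris.
#'
#' @param x0,x1,y0,y1 Integer pixel bounds, `x1 > x0`, `y1 > y0`.
#' @return An object of class `vt_roi`.
#' @export
roi <- function(x0, x1, y0, y1) {
  x0 <- check_count(x0, "x0"); x1 <- check_count(x1, "x1")
  y0 <- check_count(y0, "y0"); y1 <- check_count(y1, "y1")
  if (x1 <= x0 || y1 <= y0 || x0 < 0 || y0 < 0) {
    stop_validation("ROI must satisfy 0 <= x0 < x1 and 0 <= y0 < y1")
  }
  structure(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1), class = "vt_roi")
}

check_roi_in_image <- function(r, image) {
  if (r$x1 > ncol(image) || r$y1 > nrow(image)) {
    stop_validation(sprintf(
      "ROI [%d,%d)x[%d,%d) exceeds the %d x %d image",
      r$x0, r$x1, r$y0, r$y1, ncol(image), nrow(image)))
  }
  invisible(r)
}

#' Place equally spaced scan lines
#'
#' Returns `n` scan-line columns spread uniformly over the ROI width:
#' `x_k = round(x0 + (k + 0.5) * (x1 - x0) / n)` for `k = 0 ... n-1`, with
#' halves rounded down so every column stays strictly inside `[x0, x1)`.
#' The default of 20 lines can be raised to at most 50.
#'
#' @param roi A [roi()].
#' @param n Number of scan lines, 1-50 (default 20).
#' @return Integer vector of 0-based column indices.
#' @export
place_scanlines <- function(roi, n = 20L) {
  stopifnot(inherits(roi, "vt_roi"))
  n <- check_scanline_count(n)
  width <- roi$x1 - roi$x0
  if (width < n) {
    stop_validation(sprintf("ROI width (%d px) is narrower than n = %d scan lines",
                            width, n))
  }
  k <- seq_len(n) - 1
  v <- roi$x0 + (k + 0.5) * width / n
  as.integer(ceiling(v - 0.5))   # round half down: columns stay inside [x0, x1)
}

#' Modified z-scores
#'
#' Robust outlier statistic M_i = 0.6745 (x_i - median) / MAD, where MAD is
#' the median absolute deviation from the median. When MAD is zero (at least
#' half the values identical) the mean-absolute-deviation fallback
#' M_i = (x_i - median) / (1.253314 * meanAD) is used; if that is also zero,
#' all scores are zero. NA entries are excluded from the location/scale
#' estimates and receive NA scores.
#'
#' Scores are invariant under positive affine transforms of the data.
#'
#' @param values Numeric vector (NAs allowed).
#' @return Numeric vector of scores, same length as `values`.
#' @examples
#' modified_zscore(c(1, 2, 3, 4, 5, 100))[6]   # ~ 43.39
#' @export
modified_zscore <- function(values) {
  if (length(values) == 0L) return(numeric(0))
  x <- values[!is.na(values)]
  out <- rep(NA_real_, length(values))
  if (length(x) == 0L) return(out)
  med <- median(x)
  ad <- abs(x - med)
  mad_ <- median(ad)
  scores <- if (mad_ > 0) {
    0.6745 * (x - med) / mad_
  } else {
    mean_ad <- mean(ad)
    if (mean_ad > 0) (x - med) / (1.253314 * mean_ad) else rep(0, length(x))
  }
  out[!is.na(values)] <- scores
  out
}

#' Flag outliers by modified z-score
#'
#' @param values Numeric vector (NAs allowed; NA entries are always flagged,
#'   i.e. excluded).
#' @param threshold Absolute score above which a value is flagged
#'   (default 3.5, the conventional cutoff for the modified z-score test).
#' @return Logical vector: TRUE = outlier / excluded.
#' @export
flag_outliers <- function(values, threshold = 3.5) {
  check_number(threshold, "threshold", min = 1e-12)
  scores <- modified_zscore(values)
  is.na(values) | (!is.na(scores) & abs(scores) > threshold)
}

#' Measure one frame
#'
#' The per-frame pipeline: place scan lines across the ROI, build each line's
#' transmural profile (averaging `integration_px` neighbouring columns),
#' smooth lightly along the profile, differentiate, detect derivative peaks,
#' classify the four wall edges, convert edge pairs to per-line OD/ID in
#' pixels, flag outlying lines with the modified z-score (independently for
#' OD and ID when `filter_on`), and average the surviving lines into
#' calibrated micron means.
#'
#' A frame in which no scan line yields a valid measurement returns absent
#' means and zero valid counts; it never raises.
#'
#' @param image Numeric matrix, gray levels.
#' @param calib A [calibration()].
#' @param roi A [roi()]; default the full frame.
#' @param n_lines Number of scan lines (1-50, default 20).
#' @param filter_on Apply the modified z-score outlier filter (default TRUE).
#' @param integration_px Transverse integration width per scan line, pixels
#'   (default 25).
#' @param smooth_px Odd along-profile moving-average window, pixels
#'   (default 5).
#' @param min_prominence_frac Peak prominence threshold as a fraction of the
#'   max absolute derivative (default 0.15).
#' @param min_gradient Minimum edge steepness, gray levels per pixel: a scan
#'   line whose derivative never reaches this magnitude is treated as
#'   containing no vessel (default 2). Prominence alone is scale-free, so
#'   without this gate a line of pure background noise could hallucinate
#'   edges.
#' @param zscore_threshold Outlier cutoff (default 3.5).
#' @param wall_total If TRUE report total wall thickness OD - ID instead of
#'   the conventional per-side (OD - ID) / 2.
#' @param frame_index,time_s Bookkeeping carried into the result.
#' @return An object of class `frame_measurement`; see [tidy.frame_measurement()]
#'   and [glance.frame_measurement()].
#' @export
measure_frame <- function(image, calib, roi = NULL, n_lines = 20L,
                          filter_on = TRUE, integration_px = 25L,
                          smooth_px = 5L, min_prominence_frac = 0.15,
                          min_gradient = 2, zscore_threshold = 3.5,
                          wall_total = FALSE,
                          frame_index = NA_integer_, time_s = NA_real_) {
  if (!is.matrix(image)) stop_validation("`image` must be a matrix")
  r <- roi %||% roi_full(image)
  stopifnot(inherits(r, "vt_roi"))
  check_roi_in_image(r, image)
  check_flag(filter_on, "filter_on")
  check_flag(wall_total, "wall_total")
  integration_px <- check_count(integration_px, "integration_px", min = 1L)
  smooth_px <- check_count(smooth_px, "smooth_px", min = 1L)
  check_number(min_gradient, "min_gradient", min = 0)
  if (r$y1 - r$y0 < smooth_px + 3L) {
    stop_validation("ROI height is too short for the smoothing window")
  }
  mpp <- microns_per_pixel(calib)
  xs <- place_scanlines(r, n_lines)

  pos <- r$y0:(r$y1 - 1L)
  half_max <- (integration_px - 1L) %/% 2L
  measure_line <- function(x) {
    half <- min(half_max, x - r$x0, r$x1 - 1L - x)
    v <- rowMeans(image[pos + 1L, (x - half):(x + half) + 1L, drop = FALSE])
    d <- deriv_vec(smooth_vec(v, smooth_px))
    cr <- if (max(abs(d)) < min_gradient) {
      classify_vec(numeric(0), numeric(0), numeric(0))   # no usable contrast
    } else {
      pk <- peaks_vec(pos, d, min_prominence_frac, zero_tol = 1e-9)
      classify_vec(pk$position_px, pk$sign, pk$magnitude)
    }
    c(if (cr$outer_valid) cr$outer_top_px else NA_real_,
      if (cr$inner_valid) cr$inner_top_px else NA_real_,
      if (cr$inner_valid) cr$inner_bottom_px else NA_real_,
      if (cr$outer_valid) cr$outer_bottom_px else NA_real_,
      as.numeric(cr$outer_valid), as.numeric(cr$inner_valid),
      if (cr$outer_valid) cr$outer_bottom_px - cr$outer_top_px else NA_real_,
      if (cr$inner_valid) cr$inner_bottom_px - cr$inner_top_px else NA_real_)
  }
  per_line <- vapply(xs, measure_line, numeric(8))
  lines <- tibble(scanline_x = xs,
                  outer_top_px = per_line[1, ], inner_top_px = per_line[2, ],
                  inner_bottom_px = per_line[3, ],
                  outer_bottom_px = per_line[4, ],
                  outer_valid = per_line[5, ] == 1,
                  inner_valid = per_line[6, ] == 1,
                  od_px = per_line[7, ], id_px = per_line[8, ])

  lines$outlier_od <- if (filter_on) {
    flag_outliers(lines$od_px, zscore_threshold)
  } else {
    is.na(lines$od_px)
  }
  lines$outlier_id <- if (filter_on) {
    flag_outliers(lines$id_px, zscore_threshold)
  } else {
    is.na(lines$id_px)
  }

  mean_of <- function(v, flag) {
    keep <- !flag & !is.na(v)
    if (!any(keep)) NA_real_ else mean(v[keep]) * mpp
  }
  mean_od <- mean_of(lines$od_px, lines$outlier_od)
  mean_id <- mean_of(lines$id_px, lines$outlier_id)
  wall <- if (!is.na(mean_od) && !is.na(mean_id)) {
    (mean_od - mean_id) / (if (wall_total) 1 else 2)
  } else {
    NA_real_
  }
  structure(
    list(lines = lines,
         mean_od_um = mean_od, mean_id_um = mean_id,
         wall_thickness_um = wall,
         n_valid_od = sum(!lines$outlier_od & !is.na(lines$od_px)),
         n_valid_id = sum(!lines$outlier_id & !is.na(lines$id_px)),
         microns_per_px = mpp, roi = r, filter_on = filter_on,
         frame_index = frame_index, time_s = time_s),
    class = "frame_measurement")
}

roi_full <- function(image) roi(0L, ncol(image), 0L, nrow(image))

check_scanline_count <- function(n) {
  n <- check_count(n, "n_lines", min = 1L)
  if (n > 50L) stop_validation("at most 50 scan lines are supported")
  n
}

#' @export
print.frame_measurement <- function(x, ...) {
  cat(sprintf(
    "<frame_measurement: OD %s um (n=%d), ID %s um (n=%d), wall %s um>\n",
    fmt_or_na(x$mean_od_um), x$n_valid_od,
    fmt_or_na(x$mean_id_um), x$n_valid_id, fmt_or_na(x$wall_thickness_um)))
  invisible(x)
}

fmt_or_na <- function(x) if (is.na(x)) "--" else sprintf("%.2f", x)

#' Per-scan-line measurements as a tibble
#'
#' @param x A `frame_measurement`.
#' @param ... Unused.
#' @return Tibble with one row per scan line: edge positions (px), per-line
#'   `od_px` / `id_px` plus calibrated `od_um` / `id_um`, and outlier flags.
#' @method tidy frame_measurement
#' @export
tidy.frame_measurement <- function(x, ...) {
  mutate(x$lines,
         od_um = .data$od_px * x$microns_per_px,
         id_um = .data$id_px * x$microns_per_px)
}

#' One-row summary of a frame measurement
#'
#' @param x A `frame_measurement`.
#' @param ... Unused.
#' @return One-row tibble with the calibrated means, wall thickness and
#'   valid-line counts.
#' @method glance frame_measurement
#' @export
glance.frame_measurement <- function(x, ...) {
  tibble(frame_index = x$frame_index, time_s = x$time_s,
         mean_od_um = x$mean_od_um, mean_id_um = x$mean_id_um,
         wall_thickness_um = x$wall_thickness_um,
         n_valid_od = x$n_valid_od, n_valid_id = x$n_valid_id)
}

#' Percent of the reference diameter
#'
#' Converts a current outer diameter to a percentage of a previously set
#' reference diameter, the conventional readout of arterial tone.
#'
#' @param current_od_um Current outer diameter, micron.
#' @param ref A reference state from [set_reference()], or a bare positive
#'   number of microns.
#' @return `100 * current / reference`.
#' @export
percent_of_reference <- function(current_od_um, ref) {
  check_number(current_od_um, "current_od_um", min = 0)
  ref_um <- if (is.numeric(ref) && length(ref) == 1L) {
    ref
  } else if (is.list(ref) && !is.null(ref$reference_od_um)) {
    ref$reference_od_um
  } else {
    NA_real_
  }
  if (is.null(ref_um) || is.na(ref_um) || ref_um <= 0) {
    stop_validation("reference not set")
  }
  100 * current_od_um / ref_um
}
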