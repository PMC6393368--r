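#' Extract a transmural intensity profile
#'
#' Reads one image column (a scan line perpendicular to the vessel's long
#' axis) over a half-open row range. Coordinates are 0-based: `column_x = 0`
#' is the leftmost column, `rows = c(y0, y1)` selects rows `y0 ... y1 - 1`.
#' No interpolation is performed.
#'
#' @param image Numeric matrix (rows x columns, gray levels).
#' @param column_x Column index, 0-based.
#' @param rows Length-2 vector `c(y0, y1)`, half-open row range; default the
#'   full image height.
#' @return Tibble with `pos` (0-based row) and `value` (gray level), carrying
#'   the source column as attribute `column_x`.
#' @export
extract_profile <- function(image, column_x, rows = c(0L, nrow(image))) {
  if (!is.matrix(image)) stop_validation("`image` must be a matrix")
  column_x <- check_count(column_x, "column_x")
  if (column_x < 0 || column_x >= ncol(image)) {
    stop_validation(sprintf("`column_x` = %d is outside the image (0..%d)",
                            column_x, ncol(image) - 1L))
  }
  y0 <- check_count(rows[1], "rows[1]")
  y1 <- check_count(rows[2], "rows[2]")
  if (y1 <= y0 || y0 < 0 || y1 > nrow(image)) {
    stop_validation(sprintf("row range [%d, %d) is empty or outside the image",
                            y0, y1))
  }
  pos <- y0:(y1 - 1L)
  out <- tibble(pos = pos, value = as.numeric(image[pos + 1L, column_x + 1L]))
  attr(out, "column_x") <- column_x
  out
}

# Transverse integration: one scan line's profile as the mean over a band of
# neighbouring columns centered on column_x (shrunk symmetrically near the
# x-bounds). This is what suppresses pixel noise without blurring the profile
# along the scan direction, so the wall transitions stay sharp.
integrate_profile <- function(image, column_x, rows, width_px = 25L,
                              x_bounds = c(0L, ncol(image))) {
  half <- min((width_px - 1L) %/% 2L,
              column_x - x_bounds[1],
              x_bounds[2] - 1L - column_x)
  cols <- (column_x - half):(column_x + half)
  pos <- rows[1]:(rows[2] - 1L)
  vals <- rowMeans(image[pos + 1L, cols + 1L, drop = FALSE])
  out <- tibble(pos = pos, value = as.numeric(vals))
  attr(out, "column_x") <- column_x
  out
}

#' Smooth an intensity profile with a centered moving average
#'
#' Window must be odd; near the profile ends the window shrinks symmetrically
#' so the output stays centered and keeps the input length. An even window is
#' rejected (it is not silently incremented).
#'
#' @param profile Tibble with `pos` and `value`, as from [extract_profile()].
#' @param window_px Odd window width in pixels (default 25).
#' @return Tibble of the same shape with smoothed `value`.
#' @export
smooth_profile <- function(profile, window_px = 25L) {
  window_px <- check_count(window_px, "window_px", min = 1L)
  if (window_px %% 2L == 0L) {
    stop_validation("`window_px` must be odd")
  }
  if (window_px > length(profile$value)) {
    stop_validation("`window_px` must not exceed the profile length")
  }
  profile$value <- smooth_vec(profile$value, window_px)
  profile
}

smooth_vec <- function(v, window_px) {
  if (window_px == 1L) return(v)
  n <- length(v)
  half <- (window_px - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- sum(v[(i - h):(i + h)]) / (2 * h + 1)
  }
  out
}

#' First derivative of an intensity profile
#'
#' Central differences at interior points, one-sided differences at the two
#' endpoints; positions are preserved. Exact (to machine precision) on linear
#' ramps at interior points.
#'
#' @param profile Tibble with `pos` and `value`.
#' @return Tibble with `pos` and `value` (gray levels per pixel).
#' @export
profile_derivative <- function(profile) {
  if (length(profile$value) < 3L) {
    stop_validation("profile must have at least 3 samples")
  }
  tibble(pos = profile$pos, value = deriv_vec(profile$value))
}

deriv_vec <- function(v) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  idx <- 2:(n - 1)
  d[idx] <- (v[idx + 1] - v[idx - 1]) / 2
  d
}

#' Detect edge peaks in a derivative profile
#'
#' Finds local extrema of both signs and keeps those whose topographic
#' prominence reaches `min_prominence_frac` times the maximum absolute
#' derivative over the profile. Runs of exactly equal values (plateaus, which
#' arise from noise-free step edges) are treated as single extrema located at
#' the plateau midpoint; single-sample extrema are refined to subpixel
#' position with a 3-point parabolic fit. A derivative that is zero (or below
#' `zero_tol` in absolute value) everywhere yields an empty result.
#'
#' Prominence of a maximum is its height above the higher of the two lowest
#' points separating it from larger values (or the profile ends); minima are
#' scored on the negated profile.
#'
#' @param deriv Tibble with `pos` and `value`, as from [profile_derivative()].
#' @param min_prominence_frac Fraction of max |derivative| a peak's prominence
#'   must reach (default 0.15); must be in (0, 1).
#' @param zero_tol Absolute floor (gray levels / px) below which the profile
#'   is considered flat; guards against floating-point jitter on uniform
#'   images.
#' @return Tibble sorted by position with `position_px` (subpixel), `sign`
#'   (+1 rising, -1 falling), `magnitude` (|derivative| at the extremum) and
#'   `prominence`.
#' @export
detect_edge_peaks <- function(deriv, min_prominence_frac = 0.15,
                              zero_tol = 1e-9) {
  check_number(min_prominence_frac, "min_prominence_frac")
  if (min_prominence_frac <= 0 || min_prominence_frac >= 1) {
    stop_validation("`min_prominence_frac` must be strictly between 0 and 1")
  }
  pk <- peaks_vec(deriv$pos, deriv$value, min_prominence_frac, zero_tol)
  tibble(position_px = pk$position_px, sign = pk$sign,
         magnitude = pk$magnitude, prominence = pk$prominence)
}

peaks_vec <- function(pos, v, min_prominence_frac, zero_tol) {
  empty <- list(position_px = numeric(), sign = numeric(),
                magnitude = numeric(), prominence = numeric())
  if (length(v) < 3L) return(empty)
  vmax <- max(abs(v))
  if (vmax <= zero_tol) return(empty)
  threshold <- min_prominence_frac * vmax

  runs <- rle(v)
  m <- length(runs$values)
  if (m < 3L) return(empty)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rv <- runs$values

  p_pos <- p_sign <- p_mag <- p_prom <- numeric(0)
  for (j in 2:(m - 1L)) {
    is_max <- rv[j] > rv[j - 1] && rv[j] > rv[j + 1]
    is_min <- rv[j] < rv[j - 1] && rv[j] < rv[j + 1]
    if (!is_max && !is_min) next
    w <- if (is_max) rv else -rv   # score minima on the negated profile
    # walk outward over runs until a higher run; base = lowest value passed
    lbase <- w[j]
    k <- j - 1L
    while (k >= 1L && w[k] <= w[j]) {
      lbase <- min(lbase, w[k])
      k <- k - 1L
    }
    rbase <- w[j]
    k <- j + 1L
    while (k <= m && w[k] <= w[j]) {
      rbase <- min(rbase, w[k])
      k <- k + 1L
    }
    prom <- w[j] - max(lbase, rbase)
    if (prom < threshold) next
    if (runs$lengths[j] == 1L) {
      i <- starts[j]
      denom <- v[i - 1] - 2 * v[i] + v[i + 1]
      offset <- if (denom == 0) 0 else 0.5 * (v[i - 1] - v[i + 1]) / denom
      offset <- max(-0.5, min(0.5, offset))
      p <- pos[i] + offset
    } else {
      p <- mean(pos[starts[j]:ends[j]])   # plateau midpoint
    }
    p_pos <- c(p_pos, p)
    p_sign <- c(p_sign, if (is_max) 1 else -1)
    p_mag <- c(p_mag, abs(rv[j]))
    p_prom <- c(p_prom, prom)
  }
  if (length(p_pos) == 0L) return(empty)
  ord <- order(p_pos)
  list(position_px = p_pos[ord], sign = p_sign[ord],
       magnitude = p_mag[ord], prominence = p_prom[ord])
}

#' Classify derivative peaks into the four wall edges
#'
#' On a transmural scan (top to bottom) the idealized derivative shows four
#' peaks with signs (-, +, -, +): bright background into dark wall, wall into
#' brighter lumen, lumen into the far wall, and wall back out into the
#' background. Roles are assigned by magnitude within halves of the span the
#' peaks cover: the strongest falling peak in the top half is the outer-top
#' edge, the strongest rising peak in the bottom half the outer-bottom edge,
#' and the strongest rising / falling peaks strictly between those and the
#' midpoint are the inner edges. Ties break toward the outermost candidate
#' for outer roles and the innermost for inner roles.
#'
#' @param peaks Tibble from [detect_edge_peaks()] (sorted by position).
#' @return One-row tibble with `outer_top_px`, `inner_top_px`,
#'   `inner_bottom_px`, `outer_bottom_px`, `outer_valid`, `inner_valid`.
#'   Fewer than 2 peaks (or no candidate for a role) clears the corresponding
#'   validity flag; positions for unassigned roles are `NA`.
#' @export
classify_wall_edges <- function(peaks) {
  cr <- classify_vec(peaks$position_px, peaks$sign, peaks$magnitude)
  tibble(outer_top_px = cr$outer_top_px, inner_top_px = cr$inner_top_px,
         inner_bottom_px = cr$inner_bottom_px,
         outer_bottom_px = cr$outer_bottom_px,
         outer_valid = cr$outer_valid, inner_valid = cr$inner_valid)
}

classify_vec <- function(ppos, psign, pmag) {
  na_out <- list(outer_top_px = NA_real_, inner_top_px = NA_real_,
                 inner_bottom_px = NA_real_, outer_bottom_px = NA_real_,
                 outer_valid = FALSE, inner_valid = FALSE)
  if (length(ppos) < 2L) return(na_out)
  mid <- (min(ppos) + max(ppos)) / 2

  # strongest candidate for a role; `toward` = +1 prefers the largest
  # position on magnitude ties, -1 the smallest
  pick <- function(sel, toward) {
    if (!any(sel)) return(NA_real_)
    pos <- ppos[sel]
    mag <- pmag[sel]
    ord <- order(-mag, toward * -pos)
    pos[ord[1]]
  }
  ot <- pick(psign == -1 & ppos <= mid, toward = -1)  # outermost on ties
  ob <- pick(psign == 1 & ppos >= mid, toward = 1)
  outer_valid <- !is.na(ot) && !is.na(ob)
  it <- ib <- NA_real_
  if (outer_valid) {
    it <- pick(psign == 1 & ppos > ot & ppos < mid, toward = 1)   # innermost
    ib <- pick(psign == -1 & ppos > mid & ppos < ob, toward = -1)
  }
  list(outer_top_px = ot, inner_top_px = it,
       inner_bottom_px = ib, outer_bottom_px = ob,
       outer_valid = outer_valid,
       inner_valid = outer_valid && !is.na(it) && !is.na(ib))
}

#' Diameters from a classified wall crossing
#'
#' @param crossing One-row tibble from [classify_wall_edges()].
#' @return One-row tibble with `od_px` and `id_px` (NA when the corresponding
#'   pair of edges is not valid).
#' @export
diameters_from_crossing <- function(crossing) {
  tibble(
    od_px = if (isTRUE(crossing$outer_valid)) {
      crossing$outer_bottom_px - crossing$outer_top_px
    } else NA_real_,
    id_px = if (isTRUE(crossing$inner_valid)) {
      crossing$inner_bottom_px - crossing$inner_top_px
    } else NA_real_)
}
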