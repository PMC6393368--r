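#' Specify a synthetic vessel phantom
#'
#' A phantom is a parametric model of a transilluminated pressurized vessel
#' seen in brightfield: a bright background, two dark wall bands and an
#' intermediate-intensity lumen (only the vessel mid-plane is in focus, so the
#' walls appear as dark stripes flanking the lumen). Rendered frames carry
#' known ground-truth diameters, which is what makes the downstream tracking
#' pipeline testable without experimental recordings.
#'
#' Intensities must satisfy the transmural ordering
#' `intensity_wall < intensity_lumen < intensity_background`. The vessel axis
#' runs horizontally (along image columns) at `centerline_row`, optionally
#' tilted by a few degrees. Pixel coordinates are 0-based throughout the
#' package: pixel centers sit at integer (row, column) positions.
#'
#' @param width_px,height_px Frame size in pixels. Defaults match the
#'   recommended 1280 x 1024 8-bit monochrome camera.
#' @param microns_per_px Projected pixel size (micron / pixel). The default,
#'   1.3, corresponds to a 5.2 micron sensor pixel behind a 4x objective.
#' @param outer_diameter_um,inner_diameter_um Baseline outer and inner (lumen)
#'   diameters in micron. Defaults are a typical rat posterior cerebral artery
#'   at 60 mmHg (185 / 147 micron).
#' @param centerline_row Row (0-based, may be fractional) of the vessel axis.
#' @param tilt_deg Rotation of the vessel axis from horizontal, degrees.
#'   Scan lines are image columns, so keep this within a few degrees.
#' @param intensity_background,intensity_wall,intensity_lumen Gray levels
#'   (0-255) of the three radial zones.
#' @param blur_sigma_px Gaussian blur applied to the ideal image, pixels.
#' @param noise_sigma Additive Gaussian noise, gray levels.
#' @param debris List of debris blobs, each a list/vector with elements
#'   `x`, `y`, `radius_px`, `intensity` (composited after blur, before noise).
#' @param seed Integer seed making rendered frames reproducible.
#' @return An object of class `phantom_spec`.
#' @seealso [render_frame()], [render_sequence()], [radial_intensity()]
#' @export
phantom_spec <- function(width_px = 1280L, height_px = 1024L,
                         microns_per_px = 1.3,
                         outer_diameter_um = 185, inner_diameter_um = 147,
                         centerline_row = (height_px - 1) / 2,
                         tilt_deg = 0,
                         intensity_background = 220L, intensity_wall = 60L,
                         intensity_lumen = 140L,
                         blur_sigma_px = 1.5, noise_sigma = 3,
                         debris = list(), seed = 1L) {
  width_px <- check_count(width_px, "width_px", min = 8L)
  height_px <- check_count(height_px, "height_px", min = 8L)
  check_number(microns_per_px, "microns_per_px", min = 1e-6)
  check_number(outer_diameter_um, "outer_diameter_um", min = 1e-6)
  check_number(inner_diameter_um, "inner_diameter_um", min = 0)
  check_number(centerline_row, "centerline_row", min = 0, max = height_px - 1)
  check_number(tilt_deg, "tilt_deg", min = -90, max = 90)
  check_number(intensity_background, "intensity_background", min = 0, max = 255)
  check_number(intensity_wall, "intensity_wall", min = 0, max = 255)
  check_number(intensity_lumen, "intensity_lumen", min = 0, max = 255)
  check_number(blur_sigma_px, "blur_sigma_px", min = 0)
  check_number(noise_sigma, "noise_sigma", min = 0)
  seed <- check_count(seed, "seed")
  if (inner_diameter_um >= outer_diameter_um) {
    stop_validation("`inner_diameter_um` must be smaller than `outer_diameter_um`")
  }
  same <- intensity_wall == intensity_lumen &&
    intensity_lumen == intensity_background
  if (!same && !(intensity_wall < intensity_lumen &&
                 intensity_lumen < intensity_background)) {
    stop_validation(paste0(
      "intensities must be ordered wall < lumen < background ",
      "(or all equal for a degenerate no-contrast phantom)"))
  }
  if (outer_diameter_um / microns_per_px >= height_px) {
    stop_validation("vessel does not fit in the frame: outer_diameter_um / microns_per_px must be < height_px")
  }
  if (!is.list(debris)) stop_validation("`debris` must be a list of blobs")
  structure(
    list(width_px = width_px, height_px = height_px,
         microns_per_px = microns_per_px,
         outer_diameter_um = outer_diameter_um,
         inner_diameter_um = inner_diameter_um,
         centerline_row = centerline_row, tilt_deg = tilt_deg,
         intensity_background = intensity_background,
         intensity_wall = intensity_wall,
         intensity_lumen = intensity_lumen,
         blur_sigma_px = blur_sigma_px, noise_sigma = noise_sigma,
         debris = debris, seed = seed),
    class = "phantom_spec")
}

#' Idealized transmural intensity profile
#'
#' The three-level radial step model before blur and noise: lumen intensity
#' inside the inner radius, wall intensity between inner and outer radius,
#' background outside.
#'
#' @param distance_um Non-negative perpendicular distance(s) from the vessel
#'   axis, micron.
#' @param spec A [phantom_spec()].
#' @param od_um,id_um Diameters to evaluate at (default: the spec baselines).
#' @return Numeric vector of gray levels, one per distance.
#' @export
radial_intensity <- function(distance_um, spec,
                             od_um = spec$outer_diameter_um,
                             id_um = spec$inner_diameter_um) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(distance_um < 0)) stop_validation("`distance_um` must be >= 0")
  out <- rep(spec$intensity_background, length(distance_um))
  out[distance_um < od_um / 2] <- spec$intensity_wall
  out[distance_um < id_um / 2] <- spec$intensity_lumen
  out
}

#' Render one phantom frame
#'
#' Evaluates [radial_intensity()] at every pixel's perpendicular distance to
#' the (possibly tilted) centerline, Gaussian-blurs, composites debris blobs,
#' adds Gaussian noise and quantizes to 8-bit. Deterministic for a given seed.
#'
#' @param spec A [phantom_spec()].
#' @param od_um,id_um Diameters for this frame (default: spec baselines).
#' @param seed Seed for the noise draw; `NULL` uses the current RNG stream
#'   (used by [render_sequence()], which seeds once for the whole stack).
#' @return Integer matrix `height_px x width_px` with values 0-255.
#' @export
render_frame <- function(spec, od_um = spec$outer_diameter_um,
                         id_um = spec$inner_diameter_um, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_number(od_um, "od_um", min = 1e-6)
  check_number(id_um, "id_um", min = 0)
  if (id_um >= od_um) stop_validation("`id_um` must be smaller than `od_um`")
  if (od_um / spec$microns_per_px >= spec$height_px) {
    stop_validation("vessel does not fit in the frame at this outer diameter")
  }
  render <- function() {
    h <- spec$height_px; w <- spec$width_px
    theta <- spec$tilt_deg * pi / 180
    dy <- (seq_len(h) - 1 - spec$centerline_row) * cos(theta)
    dx <- (seq_len(w) - 1 - (w - 1) / 2) * sin(theta)
    dist_px <- abs(matrix(dy, h, w) - matrix(dx, h, w, byrow = TRUE))
    img <- matrix(
      radial_intensity(as.vector(dist_px) * spec$microns_per_px, spec,
                       od_um = od_um, id_um = id_um),
      h, w)
    if (spec$blur_sigma_px > 0) {
      img <- gaussian_blur(img, spec$blur_sigma_px)
    }
    for (blob in spec$debris) {
      blob <- as.list(blob)
      bx <- blob$x; by <- blob$y; br <- blob$radius_px; bi <- blob$intensity
      rows <- max(0, floor(by - br)):min(h - 1, ceiling(by + br))
      cols <- max(0, floor(bx - br)):min(w - 1, ceiling(bx + br))
      for (r in rows) {
        inside <- (r - by)^2 + (cols - bx)^2 <= br^2
        img[r + 1, cols[inside] + 1] <- bi
      }
    }
    if (spec$noise_sigma > 0) {
      img <- img + rnorm(length(img), sd = spec$noise_sigma)
    }
    img <- pmin(pmax(round(img), 0), 255)
    storage.mode(img) <- "integer"
    img
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

# EBImage's Gaussian filter, coerced back to a plain matrix
gaussian_blur <- function(img, sigma) {
  out <- EBImage::gblur(img, sigma = sigma)
  if (methods::is(out, "Image")) out <- EBImage::imageData(out)
  matrix(as.numeric(out), nrow(img), ncol(img))
}

#' Specify diameter dynamics for a phantom sequence
#'
#' Three laws: `constant` (baseline diameters throughout), `step` (diameters
#' switch to `step_od_um` / `step_id_um` at `step_time_s`, emulating a
#' pressure step), and `sinusoid` (outer diameter OD(t) = OD0 +
#' A sin(2 pi t / T), emulating spontaneous vasomotion). Unless a step gives
#' both diameters explicitly, the inner diameter co-varies with the outer so
#' that wall cross-sectional area (proportional to OD^2 - ID^2) is conserved.
#'
#' @param mode One of `"constant"`, `"step"`, `"sinusoid"`.
#' @param n_frames Number of frames.
#' @param fps Frame rate, frames / s (default 2, the acquisition discipline).
#' @param step_time_s,step_od_um,step_id_um Step law parameters.
#' @param sinusoid_amplitude_um,sinusoid_period_s Vasomotion law parameters;
#'   the amplitude must stay below the inner radius so the lumen never closes.
#' @return An object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(mode = c("constant", "step", "sinusoid"),
                          n_frames, fps = 2,
                          step_time_s = NULL, step_od_um = NULL,
                          step_id_um = NULL,
                          sinusoid_amplitude_um = NULL,
                          sinusoid_period_s = NULL) {
  mode <- match.arg(mode)
  n_frames <- check_count(n_frames, "n_frames", min = 1L)
  check_number(fps, "fps", min = 1e-9)
  if (mode == "step") {
    check_number(step_time_s, "step_time_s", min = 0)
    check_number(step_od_um, "step_od_um", min = 1e-6)
    check_number(step_id_um, "step_id_um", min = 0, allow_null = TRUE)
  }
  if (mode == "sinusoid") {
    check_number(sinusoid_amplitude_um, "sinusoid_amplitude_um", min = 0)
    check_number(sinusoid_period_s, "sinusoid_period_s", min = 1e-9)
  }
  structure(
    list(mode = mode, n_frames = n_frames, fps = fps,
         step_time_s = step_time_s, step_od_um = step_od_um,
         step_id_um = step_id_um,
         sinusoid_amplitude_um = sinusoid_amplitude_um,
         sinusoid_period_s = sinusoid_period_s),
    class = "dynamics_spec")
}

#' Render a phantom image sequence with ground truth
#'
#' Applies the dynamics law frame by frame and renders each frame from a
#' single seeded RNG stream, so the whole stack is reproducible bit for bit.
#'
#' @param spec A [phantom_spec()] (baseline diameters = OD(0), ID(0)).
#' @param dyn A [dynamics_spec()].
#' @return A list with `stack` (an [image_stack()]) and `truth`, a tibble with
#'   columns `frame` (1-based), `time_s`, `od_um`, `id_um`.
#' @export
render_sequence <- function(spec, dyn) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(dyn, "dynamics_spec"))
  n <- dyn$n_frames
  times <- (seq_len(n) - 1) / dyn$fps
  od0 <- spec$outer_diameter_um
  id0 <- spec$inner_diameter_um
  wall_area_term <- od0^2 - id0^2   # conserved unless a step overrides ID
  od <- switch(dyn$mode,
    constant = rep(od0, n),
    step = ifelse(times < dyn$step_time_s, od0, dyn$step_od_um),
    sinusoid = {
      if (dyn$sinusoid_amplitude_um >= id0 / 2) {
        stop_validation("sinusoid amplitude must be below the inner radius (lumen must never close)")
      }
      od0 + dyn$sinusoid_amplitude_um * sin(2 * pi * times / dyn$sinusoid_period_s)
    })
  id <- if (dyn$mode == "step" && !is.null(dyn$step_id_um)) {
    ifelse(times < dyn$step_time_s, id0, dyn$step_id_um)
  } else {
    sq <- od^2 - wall_area_term
    if (any(sq <= 0)) {
      stop_validation("dynamics drive the inner diameter to zero or below")
    }
    sqrt(sq)
  }
  if (any(id <= 0) || any(id >= od)) {
    stop_validation("dynamics produce an invalid inner diameter")
  }
  if (max(od) / spec$microns_per_px >= spec$height_px) {
    stop_validation("dynamics drive the vessel out of the frame")
  }
  frames <- withr::with_seed(
    spec$seed,
    lapply(seq_len(n), function(i) {
      render_frame(spec, od_um = od[i], id_um = id[i], seed = NULL)
    }))
  list(stack = image_stack(frames, times),
       truth = tibble(frame = seq_len(n), time_s = times,
                      od_um = od, id_um = id))
}

#' An in-memory image stack
#'
#' @param frames List of same-sized integer matrices (gray levels 0-255).
#' @param times Numeric vector of frame times in seconds, same length.
#' @return An object of class `image_stack` with elements `frames`, `times`.
#' @export
image_stack <- function(frames, times) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_validation("`frames` must be a non-empty list of matrices")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_validation("all frames must share the same dimensions")
  }
  if (length(times) != length(frames) || is.unsorted(times)) {
    stop_validation("`times` must be non-decreasing and match the frame count")
  }
  structure(list(frames = frames, times = as.numeric(times)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack: %d frames, %d x %d px, t = %.1f..%.1f s>\n",
              length(x$frames), d[1], d[2], min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec: %dx%d px @ %.3g um/px, OD %.4g um, ID %.4g um, blur %.2g px, noise %.2g>\n",
    x$width_px, x$height_px, x$microns_per_px, x$outer_diameter_um,
    x$inner_diameter_um, x$blur_sigma_px, x$noise_sigma))
  invisible(x)
}
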