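#' Session configuration
#'
#' Bundles everything an offline analysis run needs: calibration, ROI,
#' scan-line count, filtering, the sampling gate and image-export options.
#' The default 2 Hz gate mirrors the acquisition discipline of the original
#' instrument (imposed to leave processing headroom irrespective of camera
#' exposure); pass `allow_fast = TRUE` to analyse recorded stacks at higher
#' rates.
#'
#' @param calib A [calibration()].
#' @param roi A [roi()] or NULL for the full frame.
#' @param sampling_hz Sampling gate rate, Hz (default 2; capped at 2 unless
#'   `allow_fast`).
#' @param n_lines Scan lines per frame (default 20, max 50).
#' @param filter_on Modified z-score outlier filter (default TRUE).
#' @param record_images Keep overlay-annotated frames for export.
#' @param image_save_interval Save every k-th kept frame (default 1).
#' @param output_directory Optional directory used by the CLI writers.
#' @param allow_fast Lift the 2 Hz compatibility cap.
#' @param integration_px,smooth_px,min_prominence_frac,min_gradient,zscore_threshold,wall_total
#'   Passed through to [measure_frame()].
#' @return An object of class `session_config`.
#' @export
session_config <- function(calib, roi = NULL, sampling_hz = 2, n_lines = 20L,
                           filter_on = TRUE, record_images = FALSE,
                           image_save_interval = 1L, output_directory = NULL,
                           allow_fast = FALSE, integration_px = 25L,
                           smooth_px = 5L, min_prominence_frac = 0.15,
                           min_gradient = 2, zscore_threshold = 3.5,
                           wall_total = FALSE) {
  stopifnot(inherits(calib, "vt_calibration"))
  if (!is.null(roi)) stopifnot(inherits(roi, "vt_roi"))
  check_number(sampling_hz, "sampling_hz", min = 1e-9)
  check_flag(allow_fast, "allow_fast")
  if (sampling_hz > 2 && !allow_fast) {
    stop_validation("`sampling_hz` above 2 Hz requires `allow_fast = TRUE`")
  }
  image_save_interval <- check_count(image_save_interval,
                                     "image_save_interval", min = 1L)
  structure(
    list(calib = calib, roi = roi, sampling_hz = sampling_hz,
         n_lines = check_scanline_count(n_lines),
         filter_on = check_flag(filter_on, "filter_on"),
         record_images = check_flag(record_images, "record_images"),
         image_save_interval = image_save_interval,
         output_directory = output_directory,
         integration_px = integration_px, smooth_px = smooth_px,
         min_prominence_frac = min_prominence_frac,
         min_gradient = min_gradient,
         zscore_threshold = zscore_threshold, wall_total = wall_total),
    class = "session_config")
}

#' Sampling gate
#'
#' Greedily keeps a frame if at least `1/rate_hz - 1 ms` has elapsed since
#' the last kept frame; the first frame is always kept. Frames arriving
#' slower than the rate all pass.
#'
#' @param frame_times_s Non-decreasing frame times, s.
#' @param rate_hz Gate rate, Hz.
#' @return Logical keep-flags, one per frame.
#' @export
sample_gate <- function(frame_times_s, rate_hz) {
  check_number(rate_hz, "rate_hz", min = 1e-9)
  if (length(frame_times_s) == 0L) return(logical(0))
  if (is.unsorted(frame_times_s)) {
    stop_validation("`frame_times_s` must be non-decreasing")
  }
  min_dt <- 1 / rate_hz - 1e-3
  keep <- logical(length(frame_times_s))
  keep[1] <- TRUE
  last <- frame_times_s[1]
  for (i in seq_along(frame_times_s)[-1]) {
    if (frame_times_s[i] - last >= min_dt) {
      keep[i] <- TRUE
      last <- frame_times_s[i]
    }
  }
  keep
}

#' Run an offline analysis session
#'
#' Applies the sampling gate to the stack, measures every kept frame with
#' [measure_frame()], joins telemetry channels by nearest timestamp (within
#' 0.5 s, else absent) and assembles the time series that the three-file CSV
#' export serializes. Measurement failures on individual frames are recorded
#' as absent values; they never abort the session.
#'
#' @param stack An [image_stack()] (e.g. from [render_sequence()] or
#'   [read_stack()]).
#' @param config A [session_config()].
#' @param telemetry Optional tibble with `time_s` and any of `temperature_C`,
#'   `pressure1_mmHg`, `pressure2_mmHg`.
#' @return An object of class `session_result` with `timepoints`,
#'   `scanlines` (wide per-line micron table), `measurements`, `events`,
#'   `reference` and `config`.
#' @export
run_session <- function(stack, config, telemetry = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (!inherits(stack, "image_stack")) {
    if (is.list(stack) && !is.null(stack$frames)) {
      stack <- image_stack(stack$frames, stack$times)
    } else {
      stop_validation("`stack` must be an image_stack")
    }
  }
  keep <- sample_gate(stack$times, config$sampling_hz)
  kept <- which(keep)
  mpp <- microns_per_pixel(config$calib)
  n_lines <- config$n_lines

  measurements <- lapply(kept, function(i) {
    tryCatch(
      measure_frame(stack$frames[[i]], calib = config$calib,
                    roi = config$roi, n_lines = n_lines,
                    filter_on = config$filter_on,
                    integration_px = config$integration_px,
                    smooth_px = config$smooth_px,
                    min_prominence_frac = config$min_prominence_frac,
                    min_gradient = config$min_gradient,
                    zscore_threshold = config$zscore_threshold,
                    wall_total = config$wall_total,
                    frame_index = i, time_s = stack$times[i]),
      error = function(e) NULL)
  })

  tele_at <- function(t) {
    out <- c(temperature_C = NA_real_, pressure1_mmHg = NA_real_,
             pressure2_mmHg = NA_real_)
    if (is.null(telemetry) || nrow(telemetry) == 0L) return(out)
    j <- which.min(abs(telemetry$time_s - t))
    if (abs(telemetry$time_s[j] - t) > 0.5) return(out)
    for (ch in names(out)) {
      if (ch %in% names(telemetry)) out[ch] <- telemetry[[ch]][j]
    }
    out
  }

  rows <- lapply(seq_along(kept), function(k) {
    i <- kept[k]
    m <- measurements[[k]]
    tel <- tele_at(stack$times[i])
    p_mean <- if (!is.na(tel["pressure1_mmHg"]) && !is.na(tel["pressure2_mmHg"])) {
      (tel[["pressure1_mmHg"]] + tel[["pressure2_mmHg"]]) / 2
    } else {
      NA_real_
    }
    tibble(frame_index = i, time_s = stack$times[i],
           temperature_C = tel[["temperature_C"]],
           pressure1_mmHg = tel[["pressure1_mmHg"]],
           pressure2_mmHg = tel[["pressure2_mmHg"]],
           pressure_mean_mmHg = p_mean,
           mean_od_um = if (is.null(m)) NA_real_ else m$mean_od_um,
           mean_id_um = if (is.null(m)) NA_real_ else m$mean_id_um,
           wall_thickness_um = if (is.null(m)) NA_real_ else m$wall_thickness_um,
           n_valid_od = if (is.null(m)) 0L else m$n_valid_od,
           n_valid_id = if (is.null(m)) 0L else m$n_valid_id)
  })
  timepoints <- bind_rows(rows)

  line_row <- function(k) {
    m <- measurements[[k]]
    od <- id <- rep(NA_real_, n_lines)
    if (!is.null(m)) {
      od <- m$lines$od_px * mpp
      id <- m$lines$id_px * mpp
    }
    vals <- c(timepoints$time_s[k], od, id)
    names(vals) <- c("time_s",
                     paste0("od_um_line_", seq_len(n_lines)),
                     paste0("id_um_line_", seq_len(n_lines)))
    as_tibble(as.list(vals))
  }
  scanlines <- bind_rows(lapply(seq_along(kept), line_row))

  structure(
    list(timepoints = timepoints, scanlines = scanlines,
         measurements = measurements, events = empty_events(),
         reference = NULL, config = config, kept_frames = kept),
    class = "session_result")
}

empty_events <- function() {
  tibble(label = character(), time_s = numeric(),
         outer_diameter_um = numeric(), inner_diameter_um = numeric(),
         pressure_mean_mmHg = numeric(), percent_of_reference = numeric())
}

#' Set the reference diameter
#'
#' Stores the most recent mean outer diameter at or before `time_s` as the
#' reference against which subsequent event notes report percent tone.
#' Setting the reference again replaces the previous one.
#'
#' @param session A `session_result`.
#' @param time_s Time at which the reference is taken (default: the last
#'   timepoint).
#' @return The modified `session_result`.
#' @export
set_reference <- function(session, time_s = NULL) {
  stopifnot(inherits(session, "session_result"))
  tp <- session$timepoints
  time_s <- time_s %||% if (nrow(tp)) max(tp$time_s) else NULL
  if (is.null(time_s)) stop_validation("no measurement available to reference")
  check_number(time_s, "time_s")
  ok <- which(tp$time_s <= time_s & !is.na(tp$mean_od_um))
  if (length(ok) == 0L) {
    stop_validation("no measurement at or before `time_s` to use as reference")
  }
  i <- ok[length(ok)]
  session$reference <- list(reference_od_um = tp$mean_od_um[i],
                            set_time_s = time_s)
  session
}

#' Log an experimental event
#'
#' Appends a note (e.g. a drug addition) that snapshots the most recent
#' timepoint at or before `time_s`: diameters, mean pressure and — when a
#' reference diameter has been set — the percent-of-reference tone. Events
#' are kept in time order; simultaneous events keep insertion order.
#'
#' @param session A `session_result`.
#' @param label Free-text note.
#' @param time_s Event time, s.
#' @return The modified `session_result`.
#' @export
append_event <- function(session, label, time_s) {
  stopifnot(inherits(session, "session_result"))
  if (!is.character(label) || length(label) != 1L) {
    stop_validation("`label` must be a single string")
  }
  check_number(time_s, "time_s")
  tp <- session$timepoints
  ok <- which(tp$time_s <= time_s)
  if (length(ok) == 0L) {
    stop_validation("no data at or before `time_s` to snapshot")
  }
  i <- ok[length(ok)]
  pct <- if (!is.null(session$reference) && !is.na(tp$mean_od_um[i])) {
    percent_of_reference(tp$mean_od_um[i], session$reference)
  } else {
    NA_real_
  }
  note <- tibble(label = label, time_s = time_s,
                 outer_diameter_um = tp$mean_od_um[i],
                 inner_diameter_um = tp$mean_id_um[i],
                 pressure_mean_mmHg = tp$pressure_mean_mmHg[i],
                 percent_of_reference = pct)
  ev <- bind_rows(session$events, note)
  session$events <- ev[order(ev$time_s), , drop = FALSE]  # stable: ties keep insertion order
  session
}

#' @export
print.session_result <- function(x, ...) {
  tp <- x$timepoints
  cat(sprintf("<session_result: %d timepoints over %.1f s, %d events%s>\n",
              nrow(tp), if (nrow(tp)) diff(range(tp$time_s)) else 0,
              nrow(x$events),
              if (is.null(x$reference)) "" else
                sprintf(", ref %.1f um", x$reference$reference_od_um)))
  invisible(x)
}

#' Session time series as a tibble
#'
#' @param x A `session_result`.
#' @param ... Unused.
#' @return The `timepoints` tibble (one row per kept frame).
#' @method tidy session_result
#' @export
tidy.session_result <- function(x, ...) x$timepoints

#' One-row session summary
#'
#' @param x A `session_result`.
#' @param ... Unused.
#' @return One-row tibble: timepoint/event counts, duration, grand means and
#'   final diameters.
#' @method glance session_result
#' @export
glance.session_result <- function(x, ...) {
  tp <- x$timepoints
  tibble(n_timepoints = nrow(tp),
         duration_s = if (nrow(tp)) diff(range(tp$time_s)) else 0,
         mean_od_um = mean(tp$mean_od_um, na.rm = TRUE),
         mean_id_um = mean(tp$mean_id_um, na.rm = TRUE),
         final_od_um = if (nrow(tp)) tp$mean_od_um[nrow(tp)] else NA_real_,
         final_id_um = if (nrow(tp)) tp$mean_id_um[nrow(tp)] else NA_real_,
         n_events = nrow(x$events))
}

#' Plot a session's diameter time course
#'
#' Outer and inner mean diameter against time, the standard myography trace.
#'
#' @param object A `session_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot session_result
#' @export
autoplot.session_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$timepoints,
                              cols = c("mean_od_um", "mean_id_um"),
                              names_to = "series", values_to = "diameter_um")
  long$series <- factor(long$series, levels = c("mean_od_um", "mean_id_um"),
                        labels = c("outer", "inner"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$diameter_um,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(outer = "#2166ac", inner = "#b2182b")) +
    ggplot2::labs(x = "time (s)", y = "diameter (µm)", colour = NULL)
}

#' Plot per-scan-line diameters for one frame
#'
#' Per-line outer/inner diameters along the vessel axis; scan lines excluded
#' by the outlier filter are shown in black.
#'
#' @param object A `frame_measurement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frame_measurement
#' @export
autoplot.frame_measurement <- function(object, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(d, cols = c("od_um", "id_um"),
                              names_to = "series", values_to = "diameter_um")
  long$flagged <- ifelse(long$series == "od_um", long$outlier_od,
                         long$outlier_id)
  long$series <- factor(long$series, levels = c("od_um", "id_um"),
                        labels = c("outer", "inner"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scanline_x,
                                     y = .data$diameter_um)) +
    ggplot2::geom_point(ggplot2::aes(colour = ifelse(.data$flagged, "excluded",
                                                     as.character(.data$series)))) +
    ggplot2::scale_colour_manual(values = c(outer = "#2166ac",
                                            inner = "#b2182b",
                                            excluded = "black")) +
    ggplot2::labs(x = "scan line (px)", y = "diameter (µm)", colour = NULL)
}
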