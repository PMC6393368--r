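#' Read an image stack
#'
#' Accepts a multi-page TIFF (8- or 16-bit grayscale) or a directory of
#' numbered single-page TIFFs (read in lexicographic = temporal order).
#' Color input is converted to grayscale by Rec. 709 luminance with a
#' warning. Frame times are synthesized from `fps` (TIFF pages carry no
#' per-frame timestamps) unless `times` is given explicitly.
#'
#' @param path TIFF file or directory.
#' @param fps Frame rate used to synthesize times (default 2).
#' @param times Optional explicit frame times, s.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, fps = 2, times = NULL) {
  check_number(fps, "fps", min = 1e-9)
  if (!file.exists(path)) {
    stop_io(sprintf("cannot read image stack: '%s' does not exist", path))
  }
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop_io(sprintf("no TIFF files found in directory '%s'", path))
    }
    unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  } else {
    read_tiff_pages(path)
  }
  if (length(pages) == 0L) {
    stop_io(sprintf("'%s' contains no readable TIFF pages", path))
  }
  frames <- lapply(pages, page_to_gray)
  times <- times %||% (seq_along(frames) - 1) / fps
  image_stack(frames, times)
}

read_tiff_pages <- function(file) {
  pages <- tryCatch(tiff::readTIFF(file, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop_io(sprintf("failed to read TIFF '%s': %s",
                                      file, conditionMessage(e)))
                    })
  if (!is.list(pages)) pages <- list(pages)
  pages
}

page_to_gray <- function(page) {
  if (length(dim(page)) == 3L) {
    warning("color TIFF page converted to grayscale by luminance",
            call. = FALSE)
    page <- 0.2126 * page[, , 1] + 0.7152 * page[, , 2] + 0.0722 * page[, , 3]
  }
  out <- round(page)
  storage.mode(out) <- "integer"
  out
}

#' Write an image stack to a multi-page TIFF
#'
#' 8-bit grayscale, uncompressed; the exact inverse of [read_stack()] for
#' phantom output.
#'
#' @param stack An [image_stack()] or a list of integer matrices (0-255).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  ok <- tryCatch({
    tiff::writeTIFF(lapply(frames, function(f) f / 255), path,
                    bits.per.sample = 8L, compression = "none")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("failed to write TIFF '%s'", path))
  invisible(path)
}

#' Write the three-file CSV export
#'
#' Serializes a session to the standard three CSVs: a results file (time,
#' temperature, the two transducer pressures, mean pressure, mean outer/inner
#' diameter), a per-scan-line diameter file, and an events file (the data
#' entry table). RFC-4180 dialect: comma-delimited, quoted text where needed,
#' header row, UTF-8, LF line endings. Times are written with 1 decimal,
#' all other reals with 2; absent values are empty fields.
#'
#' @param result A `session_result`.
#' @param directory Output directory (created if missing).
#' @param prefix File-name prefix (default "session").
#' @return Named character vector of the three paths
#'   (`results`, `scanlines`, `events`).
#' @export
write_session_csvs <- function(result, directory, prefix = "session") {
  stopifnot(inherits(result, "session_result"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create output directory '%s'", directory))
  }
  paths <- c(results = file.path(directory, paste0(prefix, "_results.csv")),
             scanlines = file.path(directory, paste0(prefix, "_scanlines.csv")),
             events = file.path(directory, paste0(prefix, "_events.csv")))

  fmt <- function(x, digits) {
    ifelse(is.na(x), NA_character_, sprintf(paste0("%.", digits, "f"), x))
  }
  tp <- result$timepoints
  results_df <- tibble(
    time_s = fmt(tp$time_s, 1),
    temperature_C = fmt(tp$temperature_C, 2),
    pressure1_mmHg = fmt(tp$pressure1_mmHg, 2),
    pressure2_mmHg = fmt(tp$pressure2_mmHg, 2),
    pressure_mean_mmHg = fmt(tp$pressure_mean_mmHg, 2),
    outer_diameter_um = fmt(tp$mean_od_um, 2),
    inner_diameter_um = fmt(tp$mean_id_um, 2))

  sl <- result$scanlines
  scan_df <- as_tibble(c(list(time_s = fmt(sl$time_s, 1)),
                         lapply(sl[setdiff(names(sl), "time_s")], fmt,
                                digits = 2)))
  ev <- result$events
  events_df <- tibble(
    label = ev$label,
    time_s = fmt(ev$time_s, 1),
    outer_diameter_um = fmt(ev$outer_diameter_um, 2),
    inner_diameter_um = fmt(ev$inner_diameter_um, 2),
    pressure_mean_mmHg = fmt(ev$pressure_mean_mmHg, 2),
    percent_of_reference = fmt(ev$percent_of_reference, 2))

  for (nm in names(paths)) {
    df <- switch(nm, results = results_df, scanlines = scan_df,
                 events = events_df)
    ok <- tryCatch({
      readr::write_csv(df, paths[[nm]], na = "")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_io(sprintf("cannot write '%s'", paths[[nm]]))
  }
  paths
}

#' Render a diameter overlay onto a frame
#'
#' Draws, for every scan line with a valid measurement, a blue vertical
#' segment spanning the outer edges and a red segment spanning the inner
#' edges; scan lines excluded by the outlier filter are drawn black. The
#' base image is untouched outside the drawn segments.
#'
#' @param frame Integer matrix (gray levels 0-255).
#' @param m A `frame_measurement` for this frame.
#' @return Integer array `height x width x 3` (RGB, 0-255).
#' @export
render_overlay <- function(frame, m) {
  stopifnot(inherits(m, "frame_measurement"))
  if (!is.matrix(frame)) stop_validation("`frame` must be a matrix")
  h <- nrow(frame); w <- ncol(frame)
  if (any(m$lines$scanline_x < 0) || any(m$lines$scanline_x >= w) ||
      m$roi$y1 > h || m$roi$x1 > w) {
    stop_validation("measurement does not fit this frame's dimensions")
  }
  out <- array(as.numeric(frame), dim = c(h, w, 3))
  paint <- function(rows, col, rgb) {
    rows <- rows[rows >= 1 & rows <= h]
    for (ch in 1:3) out[rows, col, ch] <<- rgb[ch]
  }
  blue <- c(0, 0, 255); red <- c(255, 0, 0); black <- c(0, 0, 0)
  for (i in seq_len(nrow(m$lines))) {
    ln <- m$lines[i, ]
    if (!isTRUE(ln$outer_valid)) next
    col <- ln$scanline_x + 1L
    flagged <- isTRUE(ln$outlier_od) || isTRUE(ln$outlier_id)
    orows <- (round(ln$outer_top_px):round(ln$outer_bottom_px)) + 1L
    paint(orows, col, if (flagged) black else blue)
    if (isTRUE(ln$inner_valid)) {
      irows <- (round(ln$inner_top_px):round(ln$inner_bottom_px)) + 1L
      paint(irows, col, if (flagged) black else red)
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Export frames as TIFF files
#'
#' Saves every `interval`-th frame (default: every frame) under zero-padded
#' sequential names, so lexicographic order is temporal order. With
#' `with_overlay`, an RGB overlay variant is written alongside each raw frame
#' for frames that have a measurement.
#'
#' @param stack An [image_stack()].
#' @param directory Output directory (created if missing).
#' @param measurements Optional list of `frame_measurement`s parallel to the
#'   stack frames (NULL entries allowed).
#' @param interval Save every k-th frame, k >= 1.
#' @param with_overlay Also write overlay-annotated variants.
#' @return Number of files written.
#' @export
write_frames <- function(stack, directory, measurements = NULL,
                         interval = 1L, with_overlay = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  interval <- check_count(interval, "interval", min = 1L)
  check_flag(with_overlay, "with_overlay")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create output directory '%s'", directory))
  }
  idx <- seq(1L, length(stack$frames), by = interval)
  count <- 0L
  for (i in idx) {
    f <- stack$frames[[i]]
    path <- file.path(directory, sprintf("frame_%05d.tif", i))
    write_stack(list(f), path)
    count <- count + 1L
    if (with_overlay && !is.null(measurements) &&
        length(measurements) >= i && !is.null(measurements[[i]])) {
      ov <- render_overlay(f, measurements[[i]])
      opath <- file.path(directory, sprintf("overlay_%05d.tif", i))
      ok <- tryCatch({
        tiff::writeTIFF(ov / 255, opath, bits.per.sample = 8L,
                        compression = "none")
        TRUE
      }, error = function(e) FALSE)
      if (!ok) stop_io(sprintf("failed to write TIFF '%s'", opath))
      count <- count + 1L
    }
  }
  count
}
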