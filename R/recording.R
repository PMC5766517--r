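#' Uniformly sampled 3D position recording
#'
#' A `speakr_recording` holds a hand-position time series on a uniform time
#' grid: time in seconds, three spatial coordinates in meters, the sampling
#' rate in Hz (240 Hz for the electromagnetic-sensor setup this package
#' targets), and the label of the coordinate axis perpendicular to the touch
#' screen (the task axis along which screen touches register as position
#' extremes).
#'
#' @param position numeric matrix with columns `x`, `y`, `z` (meters), one row
#'   per frame.
#' @param time optional numeric vector of frame times in seconds; defaults to
#'   `(0:(n-1))/sample_rate`.
#' @param sample_rate sampling rate in Hz (default 240).
#' @param screen_axis one of `"x"`, `"y"`, `"z"`: the screen-normal axis.
#' @param subject_id free-text identifier.
#' @return an object of class `speakr_recording`.
#' @export
recording <- function(position, time = NULL, sample_rate = 240,
                      screen_axis = "z", subject_id = "") {
  position <- as.matrix(position)
  if (ncol(position) != 3L) stopf("position must have 3 columns, got %d", ncol(position))
  colnames(position) <- c("x", "y", "z")
  storage.mode(position) <- "double"
  n <- nrow(position)
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  rec <- structure(
    list(time = as.double(time), position = position,
         sample_rate = as.double(sample_rate),
         screen_axis = screen_axis, subject_id = as.character(subject_id)),
    class = "speakr_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording against its invariants
#'
#' Checks: at least 2 frames; `time` strictly increasing with successive
#' differences equal to `1/sample_rate` within relative tolerance `1e-6`;
#' all coordinates finite; `screen_axis` a coordinate label.
#'
#' @param rec a `speakr_recording`.
#' @return `rec`, invisibly; errors describe the first offending frame.
#' @export
validate_recording <- function(rec) {
  n <- nrow(rec$position)
  if (length(rec$time) != n)
    stopf("time (%d) and position (%d frames) lengths differ", length(rec$time), n)
  if (n < 2L) stopf("recording must have at least 2 frames, got %d", n)
  if (!rec$screen_axis %in% c("x", "y", "z"))
    stopf("screen_axis must be one of x, y, z; got '%s'", rec$screen_axis)
  if (!is.finite(rec$sample_rate) || rec$sample_rate <= 0)
    stopf("sample_rate must be a positive number")
  if (anyNA(rec$position) || any(!is.finite(rec$position)))
    stopf("non-numeric or non-finite position value at frame %d",
          which(!stats::complete.cases(rec$position) | rowSums(!is.finite(rec$position)) > 0)[1])
  dt <- diff(rec$time)
  if (any(dt <= 0)) stopf("time not strictly increasing at frame %d", which(dt <= 0)[1] + 1L)
  rel <- abs(dt * rec$sample_rate - 1)
  if (any(rel > 1e-6))
    stopf("non-uniform sampling: frame %d has dt = %.9g s, expected %.9g s",
          which(rel > 1e-6)[1] + 1L, dt[which(rel > 1e-6)[1]], 1 / rec$sample_rate)
  invisible(rec)
}

#' @export
print.speakr_recording <- function(x, ...) {
  cat(sprintf("<speakr_recording> %d frames @ %g Hz (%.2f s), screen axis '%s'%s\n",
              nrow(x$position), x$sample_rate, nrow(x$position) / x$sample_rate,
              x$screen_axis,
              if (nzchar(x$subject_id)) paste0(", subject '", x$subject_id, "'") else ""))
  invisible(x)
}

#' Read a kinematics file
#'
#' The on-disk format is a minimal UTF-8 CSV dialect: optional leading comment
#' lines `# key: value` carrying `subject_id`, `sample_rate` and `screen_axis`,
#' then a header line `time,x,y,z`, then one frame per row (time in seconds,
#' positions in meters). Rows with missing or non-numeric fields are rejected.
#'
#' @param path file path.
#' @param config optional [pipeline_config()]; unused by the parser but kept so
#'   readers and analysis steps share one signature.
#' @return a validated [recording()].
#' @export
read_recording <- function(path, config = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list(sample_rate = 240, screen_axis = "z", subject_id = "")
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", cl))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta))
      meta[[m[2]]] <- if (m[2] == "sample_rate") as.numeric(m[3]) else m[3]
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 1L || trimws(body[1]) != "time,x,y,z")
    stopf("malformed header: expected 'time,x,y,z', got '%s'",
          if (length(body)) trimws(body[1]) else "<empty file>")
  dat <- utils::read.csv(textConnection(body), header = TRUE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(dat) < 2L) stopf("recording must have at least 2 frames, got %d", nrow(dat))
  num <- suppressWarnings(vapply(dat, as.numeric, numeric(nrow(dat))))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad)) stopf("missing or non-numeric value in data row %d", bad[1])
  recording(position = num[, c("x", "y", "z"), drop = FALSE], time = num[, "time"],
            sample_rate = meta$sample_rate, screen_axis = meta$screen_axis,
            subject_id = meta$subject_id)
}

#' Write a kinematics file
#'
#' Inverse of [read_recording()]: values are written with 12 significant
#' digits so that a write/read round trip preserves them well beyond the
#' 9-significant-digit contract.
#'
#' @param rec a validated [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  con <- tryCatch(file(path, "w"), condition = function(e)
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id: %s", rec$subject_id),
               sprintf("# sample_rate: %.12g", rec$sample_rate),
               sprintf("# screen_axis: %s", rec$screen_axis),
               "time,x,y,z"), con)
  writeLines(sprintf("%.12g,%.12g,%.12g,%.12g", rec$time,
                     rec$position[, 1], rec$position[, 2], rec$position[, 3]), con)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable constants of the analysis pipeline in one validated container.
#' Defaults are the published operating point of the method at 240 Hz:
#' 25-frame smoothing window, 2-frame interval-histogram bins, 10-frame
#' exponential-fit cutoff, 300-frame minimum touch separation (1.25 s),
#' touch height above the recording mean plus 1 SD, start/stop points at
#' least 100 frames (0.42 s) from the touch, displacement below 1/3 of the
#' reach, cycles dropped when longer than 600 frames (2.5 s) or slower than
#' 0.2 m/s peak speed, and a +-400-frame raster half-width.
#'
#' @param smoothing_window odd frame count for the triangular kernel.
#' @param ipi_bin_width interval-histogram bin width, frames.
#' @param fit_cutoff exponential fit uses bins below this interval value
#'   (frames); residual mass is counted above it.
#' @param touch_min_separation minimum frames between retained touches.
#' @param touch_height_sd touch height threshold = mean + this many SD of the
#'   screen-axis position.
#' @param startstop_min_gap minimum frames between a start/stop point and its
#'   touch (inclusive).
#' @param displacement_fraction start/stop displacement bound as a fraction of
#'   the maximum screen-axis displacement between flanking touches.
#' @param cycle_max_duration maximum cycle duration in frames (inclusive).
#' @param cycle_min_maxspeed minimum peak speed within a cycle, m/s (inclusive).
#' @param raster_halfwidth frames before/after the touch in the touch-aligned
#'   s-Peak matrix.
#' @param displacement_reference `"rest"` (default): displacement for the
#'   start/stop rule is measured from the resting level (segment minimum of
#'   the screen-axis position); `"touch"`: measured from the touch position.
#' @param speed_reference `"recording"` (default): the start/stop speed bound
#'   is the mean speed of the whole recording; `"segment"`: the mean over the
#'   inter-touch segment.
#' @return an object of class `speakr_config` (a validated list).
#' @export
pipeline_config <- function(smoothing_window = 25,
                            ipi_bin_width = 2,
                            fit_cutoff = 10,
                            touch_min_separation = 300,
                            touch_height_sd = 1,
                            startstop_min_gap = 100,
                            displacement_fraction = 1 / 3,
                            cycle_max_duration = 600,
                            cycle_min_maxspeed = 0.2,
                            raster_halfwidth = 400,
                            displacement_reference = c("rest", "touch"),
                            speed_reference = c("recording", "segment")) {
  cfg <- list(smoothing_window = as.integer(smoothing_window),
              ipi_bin_width = ipi_bin_width,
              fit_cutoff = fit_cutoff,
              touch_min_separation = as.integer(touch_min_separation),
              touch_height_sd = touch_height_sd,
              startstop_min_gap = as.integer(startstop_min_gap),
              displacement_fraction = displacement_fraction,
              cycle_max_duration = as.integer(cycle_max_duration),
              cycle_min_maxspeed = cycle_min_maxspeed,
              raster_halfwidth = as.integer(raster_halfwidth),
              displacement_reference = match.arg(displacement_reference),
              speed_reference = match.arg(speed_reference))
  if (cfg$smoothing_window < 3L || cfg$smoothing_window %% 2L == 0L)
    stopf("smoothing_window must be odd and >= 3, got %d", cfg$smoothing_window)
  for (f in c("ipi_bin_width", "fit_cutoff", "touch_min_separation",
              "startstop_min_gap", "cycle_max_duration", "raster_halfwidth"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) stopf("%s must be a positive count", f)
  if (cfg$displacement_fraction <= 0 || cfg$displacement_fraction >= 1)
    stopf("displacement_fraction must be in (0, 1)")
  if (cfg$touch_height_sd < 0 || cfg$cycle_min_maxspeed < 0)
    stopf("touch_height_sd and cycle_min_maxspeed must be nonnegative")
  structure(cfg, class = "speakr_config")
}

#' Read a configuration file
#'
#' Flat `key: value` text (a YAML-style subset); unknown keys error, missing
#' keys take the [pipeline_config()] defaults. Values given in `overrides`
#' (e.g. from CLI flags) win over file values.
#'
#' @param path file path, or `NULL` for pure defaults/overrides.
#' @param overrides named list of config values taking precedence.
#' @return a `speakr_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
      if (length(m) != 3) stopf("malformed config line: '%s'", ln)
      vals[[m[2]]] <- m[3]
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  chr <- c("displacement_reference", "speed_reference")
  vals[setdiff(names(vals), chr)] <-
    lapply(vals[setdiff(names(vals), chr)], function(v) as.numeric(v))
  do.call(pipeline_config, vals)
}
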