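#' Detect s-Peaks within motion cycles
#'
#' s-Peaks are strict local maxima of the speed series (plateaus count once,
#' at their first frame) that fall inside a cycle's `[start, stop]` bounds.
#' Speed fluctuations while the hand is at rest, between cycles, are excluded
#' by construction.
#'
#' @param speed a `speakr_speed`.
#' @param cs a `speakr_cycles`.
#' @return an object of class `speakr_train`: `peaks_by_cycle` (list of
#'   strictly increasing absolute frame indices, one element per cycle) and
#'   `cycles` (the owning cycle set).
#' @export
detect_speaks <- function(speed, cs) {
  pk <- local_maxima(speed$speed)
  peaks_by_cycle <- lapply(seq_len(cs$n_cycles), function(i)
    pk[pk >= cs$cycles$start[i] & pk <= cs$cycles$stop[i]])
  speak_train(peaks_by_cycle, cs)
}

#' Construct an s-Peak train
#'
#' @param peaks_by_cycle list of strictly increasing integer frame vectors.
#' @param cycles the owning `speakr_cycles` (or `NULL` for simulated trains
#'   whose cycle windows are known a priori).
#' @return an object of class `speakr_train`.
#' @export
speak_train <- function(peaks_by_cycle, cycles = NULL) {
  stopifnot(all(vapply(peaks_by_cycle, function(p) !is.unsorted(p, strictly = TRUE),
                       logical(1))))
  structure(list(peaks_by_cycle = peaks_by_cycle, cycles = cycles),
            class = "speakr_train")
}

#' @export
print.speakr_train <- function(x, ...) {
  cat(sprintf("<speakr_train> %d cycles, %d s-Peaks\n",
              length(x$peaks_by_cycle), sum(lengths(x$peaks_by_cycle))))
  invisible(x)
}

#' Speed inter-peak intervals (s-IPIs)
#'
#' Differences between consecutive s-Peaks within the same cycle, in frames.
#' No interval ever spans a cycle boundary (and hence no inter-cycle rest
#' period); cycles with at most one peak contribute nothing.
#'
#' @param train a `speakr_train`.
#' @return numeric vector of intervals in frames (possibly empty).
#' @export
compute_sipis <- function(train) {
  as.numeric(unlist(lapply(train$peaks_by_cycle, diff), use.names = FALSE))
}

#' Binary s-Peak matrix (raster)
#'
#' Rows are cycles, columns cycle-relative frames; entry `M[i, j] = 1` iff at
#' least one s-Peak of cycle `i` falls at that frame. With `alignment =
#' "touch"` columns span `raster_halfwidth` frames before and after the touch
#' (`N_j = 2 * raster_halfwidth`, default 800, the touch at column
#' `raster_halfwidth`); with `"mean-length"` cycles are aligned on their start
#' and `N_j` is the rounded mean cycle length.
#'
#' @param train a `speakr_train` whose `cycles` carry touch frames (required
#'   for touch alignment).
#' @param alignment `"touch"` (default) or `"mean-length"`.
#' @param cfg a [pipeline_config()].
#' @return an object of class `speakr_matrix`: binary `matrix` (`N_i x N_j`),
#'   `alignment`, and `touch_column` (touch alignment only).
#' @export
build_speak_matrix <- function(train, alignment = c("touch", "mean-length"),
                               cfg = pipeline_config()) {
  alignment <- match.arg(alignment)
  if (sum(lengths(train$peaks_by_cycle)) == 0L) stopf("empty s-Peak train")
  cyc <- train$cycles$cycles
  ni <- length(train$peaks_by_cycle)
  if (alignment == "touch") {
    nj <- 2L * cfg$raster_halfwidth
    ref <- cyc$touch
    off <- cfg$raster_halfwidth  # column `off` is the touch frame
  } else {
    nj <- as.integer(round(mean(cyc$stop - cyc$start + 1L)))
    ref <- cyc$start
    off <- 1L
  }
  M <- matrix(0L, nrow = ni, ncol = nj)
  for (i in seq_len(ni)) {
    j <- train$peaks_by_cycle[[i]] - ref[i] + off
    j <- j[j >= 1L & j <= nj]
    M[i, j] <- 1L
  }
  structure(list(matrix = M, alignment = alignment,
                 touch_column = if (alignment == "touch") off else NA_integer_),
            class = "speakr_matrix")
}

#' @export
print.speakr_matrix <- function(x, ...) {
  cat(sprintf("<speakr_matrix> %d cycles x %d frames (%s-aligned), %d marks\n",
              nrow(x$matrix), ncol(x$matrix), x$alignment, sum(x$matrix)))
  invisible(x)
}

#' Bin s-IPIs into the interval histogram
#'
#' Bins have edges `(2(i-1), 2i]` frames for the default 2-frame bin width;
#' the representative interval value of bin `i` is its upper edge (`2i`
#' frames), the value used in all interval weightings. Trailing empty bins
#' are trimmed.
#'
#' @param intervals numeric vector of positive intervals in frames.
#' @param cfg a [pipeline_config()].
#' @return an object of class `speakr_hist`: `bin_value`, `count`,
#'   `bin_width`, `n_intervals`; fit fields are added by [fit_exponential()].
#' @export
build_ipi_histogram <- function(intervals, cfg = pipeline_config()) {
  if (any(intervals <= 0)) stopf("intervals must be positive")
  bw <- cfg$ipi_bin_width
  idx <- ceiling(intervals / bw)
  counts <- if (length(idx)) tabulate(idx) else integer(0)
  structure(list(bin_value = bw * seq_along(counts), count = as.integer(counts),
                 bin_width = bw, n_intervals = length(intervals),
                 fit_cutoff = cfg$fit_cutoff,
                 A = NA_real_, lambda = NA_real_, degenerate = NA,
                 fitted = NULL, residual = NULL, R = NA_real_),
            class = "speakr_hist")
}

#' Fit the exponential null to the short-interval region
#'
#' Linear least squares of `log(count)` against the bin interval value over
#' nonzero bins strictly below `fit_cutoff` frames, giving
#' `n_hat(sIPI) = A exp(-lambda sIPI)`. With fewer than two nonzero bins in
#' the fit region the fit is degenerate (`A = 0`, `lambda = 0`) and all mass
#' above the cutoff becomes residual. Residual counts per bin are
#' `max(0, count - n_hat)`, clipped so the randomness statistic stays
#' nonnegative.
#'
#' @param hist a `speakr_hist` from [build_ipi_histogram()].
#' @param cfg a [pipeline_config()] (its `fit_cutoff` wins over the one stored
#'   in `hist`).
#' @return `hist` with `A`, `lambda`, `degenerate`, `fitted`, `residual`.
#' @export
fit_exponential <- function(hist, cfg = pipeline_config()) {
  hist$fit_cutoff <- cfg$fit_cutoff
  reg <- which(hist$count > 0 & hist$bin_value < hist$fit_cutoff)
  if (length(reg) < 2L) {
    hist$A <- 0; hist$lambda <- 0; hist$degenerate <- TRUE
    if (hist$n_intervals > 0)
      speakr_log("degenerate exponential fit: fewer than 2 nonzero bins below the cutoff",
                 verbose_only = TRUE)
  } else {
    fit <- stats::lm(log(hist$count[reg]) ~ hist$bin_value[reg])
    hist$lambda <- -unname(stats::coef(fit)[2])
    hist$A <- exp(unname(stats::coef(fit)[1]))
    hist$degenerate <- FALSE
  }
  hist$fitted <- hist$A * exp(-hist$lambda * hist$bin_value)
  hist$residual <- pmax(0, hist$count - hist$fitted)
  hist
}

#' The R-parameter: interval-weighted non-exponential mass
#'
#' `R = sum_j n_out_j * sIPI_j^2 / sum_i n_i * sIPI_i`, where the numerator
#' runs over bins with interval value strictly above the fit cutoff (residual
#' counts after subtracting the fitted exponential, clipped at zero) and the
#' denominator over all bins. R is 0 when the s-IPIs are fully exponential
#' (total randomness of the s-Peaks) and grows with structured, long
#' intervals; weighting by the squared interval value makes one gap of `2t`
#' score twice two gaps of `t`. Units: frames (1 frame = 1/240 s at the
#' default rate). The ratio form makes R independent of the number of cycles.
#'
#' @param hist a `speakr_hist` that went through [fit_exponential()].
#' @return R in frames (scalar >= 0); errors when no intervals exist.
#' @export
compute_R <- function(hist) {
  if (is.null(hist$residual)) stopf("run fit_exponential() before compute_R()")
  den <- sum(hist$count * hist$bin_value)
  if (den <= 0) stopf("R is undefined: the recording produced no s-IPIs")
  out <- hist$bin_value > hist$fit_cutoff
  sum(hist$residual[out] * hist$bin_value[out]^2) / den
}

#' R from a raw interval set
#'
#' Convenience composition histogram -> exponential fit -> R.
#'
#' @param intervals numeric vector of positive intervals in frames.
#' @param cfg a [pipeline_config()].
#' @return list with `R` and the fitted `hist`.
#' @export
r_from_intervals <- function(intervals, cfg = pipeline_config()) {
  h <- fit_exponential(build_ipi_histogram(intervals, cfg), cfg)
  list(R = compute_R(h), hist = h)
}

#' @export
print.speakr_hist <- function(x, ...) {
  cat(sprintf("<speakr_hist> %d intervals in %d bins (width %g)", x$n_intervals,
              length(x$count), x$bin_width))
  if (!is.na(x$A))
    cat(sprintf("; fit A = %.4g, lambda = %.4g%s", x$A, x$lambda,
                if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  if (!is.na(x$R)) cat(sprintf("; R = %.4g frames", x$R))
  cat("\n")
  invisible(x)
}

#' Histogram/fit export table
#'
#' @param hist a fitted `speakr_hist`.
#' @return data frame `bin_value`, `count`, `fitted`, `residual`.
#' @export
histogram_table <- function(hist) {
  data.frame(bin_value = hist$bin_value, count = hist$count,
             fitted = if (is.null(hist$fitted)) NA_real_ else hist$fitted,
             residual = if (is.null(hist$residual)) NA_real_ else hist$residual)
}

#' End-to-end analysis of a recording
#'
#' Runs the full pipeline: speed profile (triangular smoothing), touch
#' detection, cycle selection, outlier removal, s-Peak extraction, raster
#' matrix, interval histogram with exponential fit, and the R-parameter.
#' Deterministic given the recording and configuration.
#'
#' @param rec a [recording()].
#' @param cfg a [pipeline_config()].
#' @return an object of class `speakr_report` with fields `recording_info`,
#'   `kernel`, `speed`, `touches`, `cycles`, `train`, `matrix`, `hist`, `R`,
#'   `config`.
#' @export
analyze_recording <- function(rec, cfg = pipeline_config()) {
  kernel <- make_kernel(cfg$smoothing_window)
  speakr_log(sprintf("smoothing window %d frames; response %.1f dB @ 20 Hz, %.1f dB @ 60 Hz",
                     cfg$smoothing_window,
                     frequency_response_db(kernel, rec$sample_rate, min(20, rec$sample_rate / 2)),
                     frequency_response_db(kernel, rec$sample_rate, min(60, rec$sample_rate / 2))),
             verbose_only = TRUE)
  speed <- speed_profile(rec, kernel)
  touches <- detect_touches(rec, cfg)
  if (length(touches) < 2L)
    stopf("found %d touch point(s); need at least 2 to delimit cycles. %s",
          length(touches),
          "Check the screen_axis declaration and that the recording spans several reaches.")
  cs <- select_cycles(rec, speed, touches, cfg)
  cs <- remove_outlier_cycles(cs, speed, cfg)
  if (cs$n_cycles == 0L)
    stopf("no motion cycles survived selection; %s",
          "inspect the per-cycle rejection log with options(speakr.verbose = TRUE)")
  train <- detect_speaks(speed, cs)
  hist <- fit_exponential(build_ipi_histogram(compute_sipis(train), cfg), cfg)
  structure(list(
    recording_info = list(subject_id = rec$subject_id, n_frames = nrow(rec$position),
                          sample_rate = rec$sample_rate, screen_axis = rec$screen_axis),
    kernel = kernel, speed = speed, touches = touches, cycles = cs, train = train,
    matrix = build_speak_matrix(train, "touch", cfg), hist = hist,
    R = compute_R(hist), config = cfg), class = "speakr_report")
}

#' @export
print.speakr_report <- function(x, ...) {
  cat(sprintf(paste0("<speakr_report> subject '%s': %d touches, %d cycles ",
                     "(mean %.0f frames), %d s-Peaks, %d s-IPIs\n  R = %.3f frames%s\n"),
              x$recording_info$subject_id, length(x$touches), x$cycles$n_cycles,
              x$cycles$mean_cycle_length, sum(lengths(x$train$peaks_by_cycle)),
              x$hist$n_intervals, x$R,
              if (isTRUE(x$hist$degenerate)) " (degenerate exponential fit)" else ""))
  invisible(x)
}
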