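#' Triangular smoothing kernel
#'
#' The moving triangular window of length `2d+1` with weight proportional to
#' `d + 1 - |k|` at offset `k`, normalized to unit sum. This is the
#' self-convolution of a `(d+1)`-tap rectangular window, which is what makes
#' its exact discrete frequency response a squared Dirichlet kernel (see
#' [frequency_response_db()]).
#'
#' @param window odd window length in frames, >= 3 (default 25, i.e. d = 12).
#' @return an object of class `speakr_kernel` with fields `window`,
#'   `half_width_d`, `weights` (normalized, symmetric), and `tau_frames`
#'   (`d + 1`, the half-base of the continuous triangle in frames; divide by
#'   the sample rate for tau in seconds).
#' @export
make_kernel <- function(window = 25) {
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stopf("window must be an odd integer >= 3, got %s", window)
  d <- (window - 1L) %/% 2L
  k <- -d:d
  w <- (d + 1 - abs(k)) / (d + 1)^2
  structure(list(window = window, half_width_d = d, weights = w,
                 tau_frames = d + 1), class = "speakr_kernel")
}

#' @export
print.speakr_kernel <- function(x, ...) {
  cat(sprintf("<speakr_kernel> %d-tap triangle (d = %d), central weight %.6g\n",
              x$window, x$half_width_d, x$weights[x$half_width_d + 1L]))
  invisible(x)
}

#' Smooth a series with a triangular kernel
#'
#' Linear convolution with the normalized kernel. Near the boundaries the
#' kernel is truncated to the available samples and renormalized, preserving
#' the unit DC gain everywhere; boundary frames are later excluded by cycle
#' selection, so the edge rule never reaches the statistics.
#'
#' @param x numeric vector, length >= `kernel$window`.
#' @param kernel a [make_kernel()] object.
#' @return numeric vector, same length as `x`.
#' @export
smooth_series <- function(x, kernel) {
  n <- length(x)
  d <- kernel$half_width_d
  if (n < kernel$window)
    stopf("series length %d is shorter than the %d-frame window", n, kernel$window)
  y <- as.numeric(stats::filter(x, kernel$weights, sides = 2))
  for (i in seq_len(d)) {                    # leading edge: offsets -(i-1)..d
    w <- kernel$weights[(d + 2L - i):(2L * d + 1L)]
    y[i] <- sum(w * x[1:(i + d)]) / sum(w)
    w <- kernel$weights[1:(d + i)]           # trailing edge, mirrored
    y[n - i + 1L] <- sum(w * x[(n - i + 1L - d):n]) / sum(w)
  }
  y
}

#' Power frequency response of the smoothing kernel, in dB
#'
#' The exact discrete-time transfer function of the symmetric FIR kernel is
#' `H(f) = sum_k w_k cos(2 pi f k / fs)`; the power response is
#' `10 log10(H^2)`. For the `2d+1`-tap triangle this equals the fourth power
#' of the (d+1)-point Dirichlet kernel, so at 240 Hz with a 25-tap window the
#' response is `20 log10(1/169) = -44.56` dB at both 20 Hz and 60 Hz,
#' comfortably inside the design bounds (-20 dB at 20 Hz, -39 dB at 60 Hz).
#' `method = "continuous"` returns the continuous-triangle approximation
#' `sin^4(pi f tau) / (pi f tau)^4` with `tau = (d+1)/fs`, for comparison.
#'
#' @param kernel a [make_kernel()] object.
#' @param sample_rate sampling rate in Hz.
#' @param f frequency in Hz; must lie in `[0, sample_rate/2]`.
#' @param method `"discrete"` (exact, default) or `"continuous"`.
#' @return power response in dB (vectorized over `f`).
#' @export
frequency_response_db <- function(kernel, sample_rate, f, method = c("discrete", "continuous")) {
  method <- match.arg(method)
  if (any(f < 0 | f > sample_rate / 2))
    stopf("f must lie in [0, %g] (the Nyquist band)", sample_rate / 2)
  if (method == "discrete") {
    d <- kernel$half_width_d
    H <- vapply(f, function(fi)
      sum(kernel$weights * cos(2 * pi * fi * (-d:d) / sample_rate)), numeric(1))
    10 * log10(H^2)
  } else {
    tau <- kernel$tau_frames / sample_rate
    a <- pi * f * tau
    p <- ifelse(f == 0, 1, (sin(a) / a)^4)
    10 * log10(p)
  }
}

#' Component velocities by finite differencing
#'
#' Central differences on the interior (second-order accurate), one-sided at
#' the two ends, at `dt = 1/sample_rate`.
#'
#' @param rec a [recording()].
#' @return numeric n x 3 matrix of velocities in m/s (columns `x`, `y`, `z`).
#' @export
differentiate <- function(rec) {
  validate_recording(rec)
  dt <- 1 / rec$sample_rate
  apply(rec$position, 2, function(p) {
    n <- length(p)
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    v[1] <- (p[2] - p[1]) / dt
    v[n] <- (p[n] - p[n - 1]) / dt
    v
  })
}

#' Smoothed speed profile of a recording
#'
#' Differentiates each coordinate, smooths the three component velocities
#' independently with the triangular kernel, and takes the per-frame Euclidean
#' norm. Smoothing velocities is equivalent (up to edge frames) to smoothing
#' the positions first and then differencing, since both operations are
#' linear shift-invariant.
#'
#' @param rec a [recording()].
#' @param kernel a [make_kernel()] object (default: the 25-tap kernel).
#' @return an object of class `speakr_speed`: `speed` (m/s per frame),
#'   `velocity` (smoothed n x 3 matrix), `sample_rate`, `screen_axis`.
#' @export
speed_profile <- function(rec, kernel = make_kernel()) {
  v <- differentiate(rec)
  vs <- apply(v, 2, smooth_series, kernel = kernel)
  speed_series(speed = sqrt(rowSums(vs^2)), velocity = vs,
               sample_rate = rec$sample_rate, screen_axis = rec$screen_axis)
}

#' Construct a speed series
#'
#' Container for a per-frame speed magnitude with (optionally) the component
#' velocities it was derived from. The invariant `speed = ||velocity||` per
#' frame is enforced when both are supplied.
#'
#' @param speed nonnegative numeric vector, m/s per frame.
#' @param velocity optional n x 3 matrix of component velocities, m/s.
#' @param sample_rate sampling rate in Hz.
#' @param screen_axis screen-normal axis label, if known.
#' @return an object of class `speakr_speed`.
#' @export
speed_series <- function(speed, velocity = NULL, sample_rate = 240, screen_axis = NA) {
  if (any(speed < 0)) stopf("speed must be nonnegative")
  if (!is.null(velocity)) {
    velocity <- as.matrix(velocity)
    if (nrow(velocity) != length(speed)) stopf("speed and velocity lengths differ")
    nv <- sqrt(rowSums(velocity^2))
    if (max(abs(nv - speed) / pmax(1, abs(speed))) > 1e-9)
      stopf("speed is not the norm of the component velocities")
    colnames(velocity) <- c("x", "y", "z")
  }
  structure(list(speed = as.double(speed), velocity = velocity,
                 sample_rate = sample_rate, screen_axis = screen_axis),
            class = "speakr_speed")
}

#' @export
print.speakr_speed <- function(x, ...) {
  cat(sprintf("<speakr_speed> %d frames @ %g Hz, peak %.3g m/s\n",
              length(x$speed), x$sample_rate, max(x$speed)))
  invisible(x)
}
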