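#' Simulation configuration
#'
#' Defaults are the validation setup of the method: 300 forward-and-backward
#' cycles, 480-frame cycles (240-frame forward and backward strokes), 20-frame
#' rests before/after each cycle and between the two strokes (the rest after
#' one cycle is the rest before the next), unit peak speed. The bell asymmetry
#' defaults to a 0.4/0.6 split (T1 = 96, T2 = 144): the strokes are
#' asymmetric but the exact split is a free choice, fixed here once.
#'
#' @param n_cycles number of forward-and-backward cycles (default 300).
#' @param T1 frames from stroke onset to the speed peak (default 96).
#' @param T2 frames from the peak to stroke end (default 144).
#' @param rest rest length in frames inserted before the first stroke, between
#'   the two strokes of a cycle, and after each cycle (default 20).
#' @param snr_db signal-to-noise ratio in dB for additive white Gaussian
#'   noise; `Inf` (default) means noiseless.
#' @param amplitude peak speed in m/s (default 1).
#' @param seed integer RNG seed for the noise (default `NULL`: current RNG).
#' @return an object of class `speakr_simconfig`.
#' @export
sim_config <- function(n_cycles = 300, T1 = 96, T2 = 144, rest = 20,
                       snr_db = Inf, amplitude = 1, seed = NULL) {
  cfg <- list(n_cycles = as.integer(n_cycles), T1 = as.integer(T1),
              T2 = as.integer(T2), stroke_T = as.integer(T1 + T2),
              rest = as.integer(rest), snr_db = snr_db,
              amplitude = amplitude, seed = seed)
  if (cfg$n_cycles < 1L) stopf("n_cycles must be >= 1")
  if (cfg$T1 < 2L || cfg$T2 < 2L) stopf("T1 and T2 must both be >= 2 frames")
  if (cfg$rest < 0L) stopf("rest must be >= 0")
  if (cfg$amplitude <= 0) stopf("amplitude must be positive")
  structure(cfg, class = "speakr_simconfig")
}

#' Asymmetric minimum-jerk bell speed profile of one stroke
#'
#' The stroke speed is `v = (4 tau (1 - tau))^2` with the phase `tau` running
#' over `[0, 1/2]` during the first `T1` frames and `[1/2, 1]` during the last
#' `T2` frames, so the profile starts and ends at 0 and peaks at exactly 1 at
#' frame `T1` -- T1 is the time to peak, T2 the time after it. Setting
#' `literal = TRUE` instead applies `tau = t/T1` then `tau = (t - T1)/T2`
#' without rescaling, which produces two full bells (and a zero at `T1`); it
#' is kept only for comparison with that alternative reading.
#'
#' @param T1 frames before the peak (>= 2).
#' @param T2 frames after the peak (>= 2).
#' @param literal use the unrescaled two-bell phase mapping.
#' @return numeric vector of length `T1 + T2`, peak value 1.
#' @export
bell_stroke <- function(T1, T2, literal = FALSE) {
  T1 <- as.integer(T1); T2 <- as.integer(T2)
  if (is.na(T1) || is.na(T2) || T1 < 2L || T2 < 2L)
    stopf("T1 and T2 must both be >= 2 frames")
  if (literal) {
    t <- seq_len(T1 + T2) - 1L
    tau <- ifelse(t < T1, t / T1, (t - T1) / T2)
    return((4 * tau * (1 - tau))^2)
  }
  tau1 <- (seq_len(T1) - 1) / (T1 - 1) / 2          # [0, 1/2] over T1 frames
  tau2 <- 0.5 + seq_len(T2) / T2 / 2                 # (1/2, 1] over T2 frames
  tau <- c(tau1, tau2)
  (4 * tau * (1 - tau))^2
}

#' Simulate a speed session of repeated reach cycles
#'
#' Lays out `rest` frames, then for each cycle a forward stroke, a rest (hand
#' at the screen), a backward stroke, and a trailing rest shared with the
#' next cycle's lead-in. Optionally corrupts the whole session with additive
#' white Gaussian noise at `cfg$snr_db` (see [add_awgn()]). Ground-truth
#' annotations are attached so segmentation and peak statistics can be
#' checked against the generator.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `speakr_session`: `speed` (noisy if requested),
#'   `clean` (noiseless speed), `cfg`, `cycle_id` (per-frame owning cycle, 0
#'   for rest), `in_stroke` (per-frame logical), and a `cycles` data frame
#'   with `fwd_start`, `fwd_end`, `touch` (= `fwd_end`), `bwd_start`,
#'   `bwd_end`, `peak_fwd`, `peak_bwd` ground-truth frames.
#' @export
simulate_speed_session <- function(cfg = sim_config()) {
  stroke <- cfg$amplitude * bell_stroke(cfg$T1, cfg$T2)
  Ts <- cfg$stroke_T; r <- cfg$rest
  block <- Ts + r + Ts + r                    # fwd, mid rest, bwd, trailing rest
  n <- r + cfg$n_cycles * block
  clean <- numeric(n)
  cycle_id <- integer(n)
  in_stroke <- logical(n)
  fwd_start <- r + (seq_len(cfg$n_cycles) - 1L) * block + 1L
  cyc <- data.frame(fwd_start = fwd_start,
                    fwd_end = fwd_start + Ts - 1L,
                    bwd_start = fwd_start + Ts + r,
                    bwd_end = fwd_start + 2L * Ts + r - 1L)
  cyc$touch <- cyc$fwd_end
  cyc$peak_fwd <- cyc$fwd_start + cfg$T1 - 1L
  cyc$peak_bwd <- cyc$bwd_start + cfg$T1 - 1L
  for (i in seq_len(cfg$n_cycles)) {
    fw <- cyc$fwd_start[i]:cyc$fwd_end[i]
    bw <- cyc$bwd_start[i]:cyc$bwd_end[i]
    clean[fw] <- stroke
    clean[bw] <- stroke
    cycle_id[cyc$fwd_start[i]:cyc$bwd_end[i]] <- i   # mid rest belongs to the cycle
    in_stroke[c(fw, bw)] <- TRUE
  }
  speed <- if (is.finite(cfg$snr_db)) add_awgn(clean, cfg$snr_db, cfg$seed) else clean
  structure(list(speed = speed, clean = clean, cfg = cfg, cycle_id = cycle_id,
                 in_stroke = in_stroke, cycles = cyc),
            class = "speakr_session")
}

#' @export
print.speakr_session <- function(x, ...) {
  cat(sprintf("<speakr_session> %d cycles, %d frames, SNR %s dB\n",
              x$cfg$n_cycles, length(x$speed),
              if (is.finite(x$cfg$snr_db)) format(x$cfg$snr_db) else "Inf (noiseless)"))
  invisible(x)
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise variance is `P_signal / 10^(snr_db/10)` with `P_signal` the mean
#' square of the input over the whole series, rest frames included (the noise
#' is homogeneous over the whole process). Values are used as-is afterwards
#' -- no clipping at zero, since clipping creates artificial plateaus that
#' bias the inter-peak intervals.
#'
#' @param series numeric vector (noiseless signal).
#' @param snr_db target SNR in dB; `Inf` returns the series unchanged.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return the noisy series.
#' @export
add_awgn <- function(series, snr_db, seed = NULL) {
  if (length(series) == 0L) stopf("series must be nonempty")
  if (!is.finite(snr_db)) return(series)
  p_sig <- mean(series^2)
  sigma <- sqrt(p_sig / 10^(snr_db / 10))
  with_local_seed(seed, function() series + stats::rnorm(length(series), 0, sigma))
}

#' s-Peak train of a simulated session
#'
#' Mirrors the empirical exclusion of rest-period fluctuations using the
#' generator's ground truth: local speed maxima are kept only inside the
#' known stroke windows, grouped by their owning cycle (so the
#' forward-to-backward peak interval within a cycle is retained, but nothing
#' crosses the inter-cycle rest).
#'
#' @param session a [simulate_speed_session()] result.
#' @param smooth apply the triangular kernel to the (noisy) speed before peak
#'   detection (default `FALSE`: peaks are read off the raw simulated speed).
#' @param kernel kernel used when `smooth = TRUE`.
#' @return a `speakr_train` (its `cycles` field holds the ground-truth table).
#' @export
session_speak_train <- function(session, smooth = FALSE, kernel = make_kernel()) {
  x <- if (smooth) smooth_series(session$speed, kernel) else session$speed
  pk <- local_maxima(x)
  pk <- pk[session$in_stroke[pk]]
  id <- session$cycle_id[pk]
  by_cycle <- split(pk, factor(id, levels = seq_len(session$cfg$n_cycles)))
  speak_train(unname(by_cycle), cycles = NULL)
}

#' R-parameter of a simulated session
#'
#' @inheritParams session_speak_train
#' @param cfg a [pipeline_config()] for the histogram/fit constants.
#' @return R in frames (`NA` when the session yields no s-IPIs).
#' @export
session_R <- function(session, cfg = pipeline_config(), smooth = FALSE) {
  ipis <- compute_sipis(session_speak_train(session, smooth = smooth))
  if (length(ipis) == 0L) return(NA_real_)
  r_from_intervals(ipis, cfg)$R
}

#' Sweep the R-parameter across simulated SNR levels
#'
#' For each SNR and seed, simulates a session, extracts the s-Peak train from
#' the known stroke windows, and computes R. Within the tested range the mean
#' R grows monotonically with SNR: cleaner signals have fewer spurious peaks,
#' hence longer, more structured intervals.
#'
#' @param cfg a [sim_config()] template (its `snr_db`/`seed` are overridden).
#' @param snr_list numeric vector of SNR levels in dB.
#' @param n_seeds seeds per level.
#' @param base_seed first seed; seed for run `k` of a level is `base_seed + k - 1`.
#' @param pipeline a [pipeline_config()].
#' @param smooth smooth the simulated speed with the triangular kernel before
#'   peak detection, exactly as the empirical pipeline does (default `TRUE`).
#'   Raw white noise produces local maxima at a rate (about one per three
#'   frames) that is independent of its amplitude, so without the filter the
#'   interval statistics barely respond to SNR; the smoothed pipeline is the
#'   one the simulation is meant to validate.
#' @return tidy data frame with columns `snr_db`, `seed`, `R` (`NA` when R was
#'   undefined for a run).
#' @export
snr_sweep <- function(cfg = sim_config(), snr_list = c(0, 10, 15), n_seeds = 20,
                      base_seed = 1, pipeline = pipeline_config(), smooth = TRUE) {
  if (length(snr_list) == 0L) stopf("snr_list must be nonempty")
  grid <- expand.grid(seed = base_seed + seq_len(n_seeds) - 1L, snr_db = snr_list)
  grid$R <- vapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg; ci$snr_db <- grid$snr_db[i]; ci$seed <- grid$seed[i]
    session_R(simulate_speed_session(ci), pipeline, smooth = smooth)
  }, numeric(1))
  grid[, c("snr_db", "seed", "R")]
}

#' Synthesize a 3D recording from the stroke model
#'
#' Builds the position analogue of a simulated session so that the
#' segmentation stage is testable end to end: the screen-axis coordinate is
#' the running integral of the signed stroke speed (forward strokes approach
#' the screen, backward strokes return to rest), scaled so the reach spans
#' `reach_amplitude_m`; the two in-plane axes get small smooth arcs (a few mm
#' of curvature per stroke, as real reaches are never perfectly straight).
#' Optional white positional noise emulates sensor jitter.
#'
#' @param cfg a [sim_config()].
#' @param reach_amplitude_m screen-axis reach in meters (default 0.5).
#' @param seed optional seed for the positional noise.
#' @param pos_noise_sd positional noise SD in meters (default 0, noiseless).
#' @return a [recording()] with attribute `ground_truth`: the session cycle
#'   table plus `touch` frames and the peak stroke speed in m/s.
#' @export
synth_recording <- function(cfg = sim_config(), reach_amplitude_m = 0.5,
                            seed = NULL, pos_noise_sd = 0) {
  session <- simulate_speed_session(within_noiseless(cfg))
  dt <- 1 / 240
  # signed screen-axis velocity: + toward the screen on forward strokes
  sgn <- numeric(length(session$clean))
  for (i in seq_len(cfg$n_cycles)) {
    sgn[session$cycles$fwd_start[i]:session$cycles$fwd_end[i]] <- 1
    sgn[session$cycles$bwd_start[i]:session$cycles$bwd_end[i]] <- -1
  }
  v <- session$clean * sgn
  scale <- reach_amplitude_m / (sum(session$clean[session$cycles$fwd_start[1]:
                                                    session$cycles$fwd_end[1]]) * dt)
  z <- cumsum(v * dt) * scale
  t01 <- seq_along(z) / length(z)
  x <- 0.003 * sin(2 * pi * z / max(abs(z) + 1e-12))   # small in-plane arc tied to the reach
  y <- 0.002 * sin(4 * pi * t01)
  pos <- cbind(x = x, y = y, z = z)
  if (pos_noise_sd > 0)
    pos <- pos + with_local_seed(seed, function()
      matrix(stats::rnorm(length(pos), 0, pos_noise_sd), ncol = 3))
  rec <- recording(pos, sample_rate = 240, screen_axis = "z",
                   subject_id = sprintf("synthetic-%d-cycles", cfg$n_cycles))
  gt <- session$cycles
  gt$peak_speed <- max(session$clean) * scale
  attr(rec, "ground_truth") <- gt
  rec
}

within_noiseless <- function(cfg) { cfg$snr_db <- Inf; cfg }
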