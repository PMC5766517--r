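# Independent brute-force oracle for the R statistic: explicit per-interval
# binning, explicit bin-by-bin sums.  Deliberately written as loops so it
# shares no code path with the package's vectorized histogram pipeline.
oracle_R <- function(intervals, bin_width = 2, cutoff = 10) {
  stopifnot(all(intervals > 0))
  nb <- ceiling(max(intervals) / bin_width)
  counts <- numeric(nb)
  vals <- bin_width * seq_len(nb)          # bin value = upper edge of (2(i-1), 2i]
  for (x in intervals) {
    i <- ceiling(x / bin_width)
    counts[i] <- counts[i] + 1
  }
  fit_bins <- which(counts > 0 & vals < cutoff)
  if (length(fit_bins) >= 2) {
    fit <- stats::lm(log(counts[fit_bins]) ~ vals[fit_bins])
    A <- exp(unname(coef(fit)[1])); lam <- -unname(coef(fit)[2])
  } else {
    A <- 0; lam <- 0
  }
  num <- 0
  for (i in seq_len(nb)) {
    if (vals[i] > cutoff)
      num <- num + max(0, counts[i] - A * exp(-lam * vals[i])) * vals[i]^2
  }
  den <- 0
  for (i in seq_len(nb)) den <- den + counts[i] * vals[i]
  num / den
}

# naive quadratic-time local-maximum finder (plateau -> first frame)
oracle_local_maxima <- function(x) {
  out <- integer(0)
  n <- length(x)
  for (i in 2:(n - 1)) {
    j <- i - 1
    while (j >= 1 && x[j] == x[i]) j <- j - 1   # walk left over the plateau
    if (j < 1 || x[j] >= x[i]) next
    if (j < i - 1) next                          # not the first frame of its plateau
    k <- i + 1
    while (k <= n && x[k] == x[i]) k <- k + 1
    if (k <= n && x[k] < x[i]) out <- c(out, i)
  }
  out
}

# a tiny hand-assembled recording: screen axis rises to a touch and returns
make_test_recording <- function(n_cycles = 5, seed = NULL) {
  synth_recording(sim_config(n_cycles = n_cycles), reach_amplitude_m = 0.5, seed = seed)
}

expect_same_R <- function(intervals, cfg = pipeline_config()) {
  expect_equal(r_from_intervals(intervals, cfg)$R,
               oracle_R(intervals, cfg$ipi_bin_width, cfg$fit_cutoff),
               tolerance = 1e-12)
}
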