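---
title: "speakr: methods, parameter choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{speakr: methods, parameter choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speakr)
```

## The model

`speakr` treats the stream of local maxima of the hand-speed profile
(s-Peaks) during a repetitive reach-to-touch task as a point process and asks
how far it departs from a fully random (Poisson-like) process. For a Poisson
process the inter-event intervals are exponential; the biomarker R is the
interval-weighted mass of the s-IPI histogram that an exponential null cannot
account for:

$$R = \frac{\sum_j n_{j,\mathrm{out}}\; \mathrm{sIPI}_j^2}{\sum_i n_i\;
\mathrm{sIPI}_i}, \qquad \mathrm{sIPI}_j > 10\ \text{frames},$$

with $n_{j,\mathrm{out}} = \max(0,\; n_j - A e^{-\lambda\,\mathrm{sIPI}_j})$
and $(A, \lambda)$ fitted on the short-interval bins. R has units of frames
(1 frame = 1/240 s). R = 0 means the intervals are fully exponential; the
$\mathrm{sIPI}^2$ weighting encodes that a single long smooth stretch (one
gap of $2t$) is stronger evidence of structure than two gaps of $t$. The
denominator runs over *all* bins (including the fit region) — this is what
makes R insensitive to the number of recorded cycles, since both sums scale
linearly with trial count.

### Assumptions

* The recording is a uniform 240 Hz grid (validated at relative tolerance
  1e-6) with a declared screen-normal axis. The sensor-to-screen coordinate
  frame is not inferred; the user (or the simulator) declares it.
* Movement structure is cyclic: reach, touch, return, rest. Fluctuations
  while the hand rests in the lap are physiologically different and are
  excluded by only counting peaks inside detected cycles; intervals never
  span cycle boundaries.
* Electronic sensor noise lives at higher frequencies than the physiological
  signal, so a low-pass FIR with strong attenuation at 20--60 Hz separates
  them without destroying the fluctuation timing.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `smoothing_window` | 25 (d = 12) | frames | ~104 ms triangle; exact power response $20\log_{10}(1/169) \approx -44.6$ dB at 20 and 60 Hz, inside the −20/−39 dB design bounds |
| `ipi_bin_width` | 2 | frames | finest binning that keeps per-bin counts stable for exponential fitting |
| `fit_cutoff` | 10 | frames | fit below 10 frames (~40 ms), residuals counted above; separates electronic-noise-scale intervals from structured gaps |
| `touch_min_separation` | 300 | frames | 1.25 s: faster than any plausible full reach cycle |
| `touch_height_sd` | 1 | SD | touch = screen-axis extreme above mean + 1 SD of the whole recording |
| `startstop_min_gap` | 100 | frames | 0.42 s guard band between a start/stop point and its touch (inclusive) |
| `displacement_fraction` | 1/3 | — | start/stop must sit in the lower third of the reach |
| `cycle_max_duration` | 600 | frames | 2.5 s: longer "cycles" are hesitations or lost tracking |
| `cycle_min_maxspeed` | 0.2 | m/s | slower cycles are not reaches |
| `raster_halfwidth` | 400 | frames | ±1.7 s raster window around the touch ($N_j = 800$) |

Simulator defaults: 300 cycles, 240-frame strokes split T1 = 96 / T2 = 144,
20-frame rests, unit peak speed. The stroke speed is the asymmetric
minimum-jerk bell $v = (4\tau(1-\tau))^2$ with $\tau$ rescaled to $[0,
\tfrac12]$ over T1 and $[\tfrac12, 1]$ over T2, so the profile peaks at 1 at
frame T1. (Applying the phase maps $\tau = t/T_1$, $\tau = (t-T_1)/T_2$
*without* rescaling makes the speed vanish at $T_1$ — two bells per stroke —
contradicting T1's meaning as time-to-peak; that literal variant remains
available as `bell_stroke(..., literal = TRUE)`.) The 0.4/0.6 asymmetry
split is a fixed choice: real reach profiles are left-skewed, and only
"asymmetric" is specified by the source analyses.

## Design choices that were genuinely open

**Bin representative.** Intervals are binned into $(2(i-1), 2i]$; the value
$\mathrm{sIPI}_i$ entering the weightings is the bin's *upper edge* $2i$.
This is the unique fixed representative under which the hand-computable
cases come out exactly (ten 20-frame intervals give R = 20; $\{t,t\}$ vs
$\{2t\}$ give $t$ vs $2t$ for $t$ on the bin grid), and it makes
$\log E[n_i]$ exactly linear in $\mathrm{sIPI}_i$ for exponential intervals,
so the fitted $\lambda$ is unbiased.

**Displacement reference in cycle selection.** The "displacement below 1/3
of the maximum" rule for start/stop points is measured from the *resting
level* (the minimum of the screen-axis position between the flanking
touches): start and stop points are where the hand idles in the lap, at
near-full distance from the screen. Measuring from the touch instead keeps
only near-screen candidates, which are all inside the 100-frame guard band —
no cycle would ever be found. The touch-referenced variant is still
available (`pipeline_config(displacement_reference = "touch")`), as is a
per-segment mean-speed reference for the speed rule (`speed_reference =
"segment"`).

**Touch conflicts.** Two touch candidates closer than 300 frames are
resolved by keeping the higher one — height is the touch signature.

**Direction changes.** Start/stop candidates are strict sign changes of the
screen-axis velocity; a zero run resolves to its first frame; a pause
without reversal (+, 0, +) is not a change; zero runs at the series
boundaries count as motion onset/cessation so the first and last cycles are
not lost.

**Smoothing in the SNR sweep.** The simulated noisy speed is passed through
the same 25-tap filter as empirical data before peak detection. This is not
cosmetic: the local maxima of an *unsmoothed* white-noise-corrupted series
occur at a rate (about one per three frames) that is independent of the
noise amplitude, so R would be flat across SNR and the sweep would validate
nothing. With the filter in place mean R rises strictly with SNR (about 0,
54, 125 frames at 0/10/15 dB, 300 cycles), which is the behavior the
statistic is meant to capture. `snr_sweep(..., smooth = FALSE)` exposes the
unfiltered route.

**Exponential fit.** Linear least squares on log counts over nonzero bins
below the cutoff; with fewer than two such bins the fit is degenerate
(A = 0) and all mass above the cutoff is residual — the correct limit for
noiseless sessions, where every interval is a deterministic stroke spacing.
The slope is not sign-constrained; interval distributions peaked *above*
the cutoff can fit a rising "exponential" and then legitimately produce
zero residual mass.

**Logistic fit.** Unregularized maximum likelihood by BFGS plus damped
Newton polish, converged at gradient norm $10^{-8}$; `stats::glm` is used
as an independent oracle in the tests, never as the implementation. In one
dimension perfect separation is decidable exactly (the classes occupy
disjoint half-lines), and is reported as a warning while returning the
(large, finite) coefficients — their ratio, the decision boundary, is still
well defined. Note that published coefficient pairs rounded to two decimals
need not reproduce a published boundary exactly: g(0.30R − 20.89) puts the
boundary at 69.63 frames, while 69.47 is only consistent with unrounded
coefficients; `decision_boundary()` always reports the value implied by the
coefficients it is given.

**Synthetic cohort for protocol tests.** The split-evaluation and recovery
tests draw the predictor from N(70, 15): most observations then carry
non-negligible logistic Fisher information around the boundary, which is
what makes 10% coefficient recovery at n = 2000 a fair bar. A uniform
predictor over a wide range wastes most samples in the saturated tails.

## What the simulator does and does not emulate

It emulates: fixed-pace cyclic reaching with asymmetric bell strokes, rests
(including the hold at the screen), additive white Gaussian sensor noise at
a controlled SNR measured over the whole process, and — in
`synth_recording()` — the 3D geometry needed by segmentation (screen-axis
displacement as the integral of the signed speed, touches as position
plateaus, small in-plane curvature).

It does not emulate: pace variability and drift, colored or
movement-correlated noise, tremor, hesitations and aborted reaches, marker
dropout, or any between-subject physiological differences. A green
simulator test therefore establishes that the *pipeline* is correct
(segmentation recovers known cycles; R responds to noise randomness as
designed), not that the biomarker separates clinical groups — the published
per-subject R values and cohort accuracies depend on undeposited recordings
and are deliberately not reproduced here.

## Numerical notes

* Smoothing truncates and renormalizes the kernel at the series edges,
  preserving unit DC gain; edge frames are excluded by cycle selection
  anyway.
* Velocities use central differences (one-sided at the ends), second-order
  accurate and symmetric like the kernel; smoothing and differencing
  commute on the interior to 1e-9.
* Peak plateaus (exactly equal consecutive samples) count once, at their
  first frame; simulated noise makes them measure-zero, but noiseless
  sessions and integer-valued fixtures hit them.
* Thresholds are inclusive on the kept side (≥ 100 frames from the touch,
  ≤ 600 frames duration, ≥ 0.2 m/s peak speed).
* Noisy simulated speed is not clipped at zero before peak detection;
  clipping manufactures plateaus and biases the intervals.
* All randomness is seed-scoped (`add_awgn`, `split_evaluate`, the CLI
  `--seed`); library calls never disturb the caller's RNG state.

## Known limitations

* One sensor, one marker; no proprietary capture formats (Polhemus, C3D,
  BVH) — convert to the package's CSV dialect first.
* The screen-normal axis must be declared, not inferred.
* R for a recording with no s-IPIs (e.g. fewer than two peaks per cycle
  everywhere) is undefined and raised as an error, not returned as 0: zero
  asserts exponentially distributed intervals, which is not what an empty
  interval set shows.
* The exponential fit uses at most a handful of bins; with very few
  intervals the fitted $(A, \lambda)$ are noisy. The statistic is designed
  for sessions with on the order of 100 cycles.
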