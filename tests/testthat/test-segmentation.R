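test_that("local_maxima matches a brute-force finder, plateaus count once", {
  expect_equal(local_maxima(c(1, 2, 1)), 2L)
  expect_equal(local_maxima(c(1, 2, 2, 1)), 2L)       # plateau -> first frame
  expect_equal(local_maxima(c(1, 2, 2, 3, 1)), 4L)    # rising plateau is not a max
  expect_equal(local_maxima(c(3, 2, 2, 3)), integer(0))
  expect_equal(local_maxima(rep(1, 10)), integer(0))
  expect_equal(local_maxima(c(1, 2, 2)), integer(0))  # boundary plateau
  set.seed(42)
  for (i in 1:25) {
    x <- sample(0:5, 60, replace = TRUE)
    expect_equal(local_maxima(x), oracle_local_maxima(x))
  }
})

test_that("touch detection recovers simulated touches and applies height/separation rules", {
  rec <- make_test_recording(n_cycles = 8)
  gt <- attr(rec, "ground_truth")
  touches <- detect_touches(rec)
  expect_length(touches, 8L)
  expect_true(all(abs(touches - gt$touch) <= 12))  # within the smoothing half-width

  # constant position: zero touches, warning not error
  flat <- recording(matrix(0.1, nrow = 400, ncol = 3))
  expect_warning(t0 <- detect_touches(flat), "no touch")
  expect_length(t0, 0L)

  # two peaks 200 frames apart: only the higher survives the 300-frame rule
  z <- numeric(1200)
  z[300:340] <- 0.8 * sin(seq(0, pi, length.out = 41))          # lower peak
  z[500:540] <- 1.0 * sin(seq(0, pi, length.out = 41))          # higher peak, 200 later
  rec2 <- recording(cbind(0, 0, z))
  touches2 <- detect_touches(rec2)
  expect_length(touches2, 1L)
  expect_equal(touches2, 520L)
  # brute force over the candidate set confirms the greedy-by-height rule
  cand <- local_maxima(z)
  cand <- cand[z[cand] >= mean(z) + sd(z)]
  expect_equal(touches2, cand[which.max(z[cand])])
})

test_that("cycle selection recovers every simulated cycle with starts/stops in rest windows", {
  for (K in c(3, 10)) {
    rec <- make_test_recording(n_cycles = K)
    gt <- attr(rec, "ground_truth")
    speed <- speed_profile(rec)
    touches <- detect_touches(rec)
    cs <- select_cycles(rec, speed, touches, pipeline_config())
    expect_equal(cs$n_cycles, K)
    # starts precede the forward stroke, stops follow the backward stroke
    expect_true(all(cs$cycles$start <= gt$fwd_start + 12))
    expect_true(all(cs$cycles$stop >= gt$bwd_end - 12))
    expect_true(all(cs$cycles$start < cs$cycles$touch & cs$cycles$touch < cs$cycles$stop))
    if (K > 1) expect_true(all(head(cs$cycles$stop, -1) <= tail(cs$cycles$start, -1)))
  }
})

test_that("a single touch yields an empty cycle set", {
  rec <- make_test_recording(n_cycles = 3)
  speed <- speed_profile(rec)
  cs <- select_cycles(rec, speed, detect_touches(rec)[2], pipeline_config())
  expect_equal(cs$n_cycles, 0L)
})

test_that("the 100-frame start/stop gap threshold is inclusive", {
  # two triangular reaches peaking at frames 400 and 800; the rest between
  # them begins exactly 100 frames after the first touch, so the only stop
  # candidate for touch 1 sits at distance exactly startstop_min_gap
  z <- numeric(1200)
  z[301:400] <- seq_len(100) / 100
  z[401:499] <- rev(seq_len(99) - 1) / 100   # hits 0 at frame 499
  z[701:800] <- seq_len(100) / 100
  z[801:899] <- rev(seq_len(99) - 1) / 100
  rec <- recording(cbind(0, 0, z))
  v <- c(0, diff(z)) * 240
  sp <- speed_series(abs(v), cbind(0, 0, v), 240, "z")
  cand <- speakr:::direction_changes(v)
  expect_true(500L %in% cand)  # first frame of the zero run after the reach
  cs <- select_cycles(rec, sp, c(400L, 800L), pipeline_config())
  expect_equal(cs$n_cycles, 2L)
  expect_equal(cs$cycles$stop[1], 500L)  # distance exactly 100: accepted
  # both stop candidates sit exactly 100 frames from their touches, so with
  # the gap raised to 101 neither touch keeps a stop point: exclusivity would
  # have produced zero cycles above as well
  cs2 <- select_cycles(rec, sp, c(400L, 800L),
                       pipeline_config(startstop_min_gap = 101))
  expect_equal(cs2$n_cycles, 0L)
})

test_that("outlier removal drops long and slow cycles, keeps compliant ones, and is idempotent", {
  set.seed(7)
  n <- 4000L
  spd <- runif(n, 0.25, 1)
  sp <- speed_series(spd, sample_rate = 240)
  cyc <- data.frame(start = c(1L, 700L, 1500L, 2500L),
                    touch = c(300L, 1000L, 1800L, 2800L),
                    stop = c(590L, 1300L, 2099L, 3100L))
  cyc$stop[2] <- cyc$start[2] + 600L       # 601 frames -> removed
  sp$speed[2500:3100] <- 0.19              # slow cycle -> removed
  cs <- cycle_set(cyc, sp)
  kept <- remove_outlier_cycles(cs, sp, pipeline_config())
  expect_equal(kept$n_cycles, 2L)
  expect_equal(kept$cycles$touch, c(300L, 1800L))
  again <- remove_outlier_cycles(kept, sp, pipeline_config())
  expect_equal(again$cycles, kept$cycles)
  # boundary cases stay: exactly 600 frames and exactly 0.2 m/s are kept
  sp2 <- speed_series(rep(0.2, 700), sample_rate = 240)
  cs2 <- cycle_set(data.frame(start = 1L, touch = 300L, stop = 600L), sp2)
  expect_equal(remove_outlier_cycles(cs2, sp2, pipeline_config())$n_cycles, 1L)
})

test_that("recovered cycles exclude rest-only frames beyond their bounds", {
  rec <- make_test_recording(n_cycles = 4)
  gt <- attr(rec, "ground_truth")
  speed <- speed_profile(rec)
  cs <- remove_outlier_cycles(select_cycles(rec, speed, detect_touches(rec)),
                              speed, pipeline_config())
  # no cycle starts before the previous cycle's strokes are over
  for (i in 2:cs$n_cycles) expect_gte(cs$cycles$start[i], gt$bwd_end[i - 1])
})
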