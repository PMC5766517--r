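test_that("s-Peak detection respects cycle bounds, plateau ties, and rest exclusion", {
  # one asymmetric bell inside a cycle: exactly one peak at the known frame
  spd <- c(numeric(30), bell_stroke(40, 60), numeric(30))
  sp <- speed_series(spd, sample_rate = 240)
  cs <- cycle_set(data.frame(start = 5L, touch = 70L, stop = 155L), sp)
  tr <- detect_speaks(sp, cs)
  expect_equal(tr$peaks_by_cycle[[1]], 70L)  # 30 rest + T1 = 40 -> frame 70

  # two equal consecutive maximum samples count once, at the first
  spd2 <- c(0, 1, 2, 2, 1, 0, 0.5, 0)
  sp2 <- speed_series(spd2, sample_rate = 240)
  cs2 <- cycle_set(data.frame(start = 1L, touch = 4L, stop = 8L), sp2)
  expect_equal(detect_speaks(sp2, cs2)$peaks_by_cycle[[1]], c(3L, 7L))

  # peaks during rest (outside every cycle) never enter the train
  spd3 <- rep(c(0, 1, 0), 40)
  sp3 <- speed_series(spd3, sample_rate = 240)
  cs3 <- cycle_set(data.frame(start = 10L, touch = 15L, stop = 20L), sp3)
  tr3 <- detect_speaks(sp3, cs3)
  expect_true(all(unlist(tr3$peaks_by_cycle) >= 10 & unlist(tr3$peaks_by_cycle) <= 20))
})

test_that("s-IPIs are within-cycle nearest-neighbor differences only", {
  tr <- speak_train(list(c(10L, 14L, 30L)))
  expect_equal(compute_sipis(tr), c(4, 16))
  expect_equal(compute_sipis(speak_train(list(5L, integer(0), 400L))), numeric(0))
  a <- list(c(1L, 5L), c(100L, 103L, 110L))
  b <- list(c(500L, 520L))
  expect_equal(sort(compute_sipis(speak_train(c(a, b)))),
               sort(c(compute_sipis(speak_train(a)), compute_sipis(speak_train(b)))))
})

test_that("histogram binning: edges (2(i-1), 2i], upper-edge values, count conservation", {
  h <- build_ipi_histogram(c(1, 2, 3))
  expect_equal(h$count, c(2L, 1L))       # {1,2} in (0,2], {3} in (2,4]
  expect_equal(h$bin_value, c(2, 4))
  h0 <- build_ipi_histogram(numeric(0))
  expect_equal(sum(h0$count), 0L)
  set.seed(31)
  for (i in 1:10) {
    iv <- sample(1:60, sample(1:200, 1), replace = TRUE)
    expect_equal(sum(build_ipi_histogram(iv)$count), length(iv))
  }
  expect_error(build_ipi_histogram(c(2, -1)), "positive")
})

test_that("exponential fit recovers exact exponentials and degenerates gracefully", {
  cfg <- pipeline_config()
  # counts exactly A exp(-lambda v) on the fit bins -> exact recovery
  A <- 200; lam <- 0.35
  v <- c(2, 4, 6, 8, 12, 16)
  h <- build_ipi_histogram(rep(2, 2), cfg)   # shell, then overwrite
  h$bin_value <- v; h$count <- A * exp(-lam * v); h$n_intervals <- sum(h$count)
  hf <- fit_exponential(h, cfg)
  expect_equal(hf$lambda, lam, tolerance = 1e-9)
  expect_equal(hf$A, A, tolerance = 1e-9)
  expect_false(hf$degenerate)
  # all intervals above the cutoff: degenerate fit, everything is residual
  hd <- fit_exponential(build_ipi_histogram(c(20, 24, 30), cfg), cfg)
  expect_true(hd$degenerate)
  expect_equal(hd$A, 0)
  expect_equal(hd$residual, as.numeric(hd$count))
})

test_that("fitted rate is consistent with a known Poisson generator", {
  # i.i.d. exponential intervals, rate rho: lambda-hat within 3 MC standard errors
  rho <- 0.25
  set.seed(99)
  lams <- replicate(30, {
    iv <- rexp(5000, rho)
    iv <- iv[iv > 0]
    fit_exponential(build_ipi_histogram(iv), pipeline_config())$lambda
  })
  expect_lt(abs(mean(lams) - rho), 3 * sd(lams) / sqrt(length(lams)))
})

test_that("R equals the brute-force oracle on random interval sets and hand cases", {
  expect_equal(r_from_intervals(rep(20, 10))$R, 20)
  t0 <- 30
  expect_equal(r_from_intervals(c(t0, t0))$R, t0)
  expect_equal(r_from_intervals(2 * t0)$R, 2 * t0)
  set.seed(17)
  for (i in 1:100) {
    iv <- sample(1:80, sample(2:120, 1), replace = TRUE)
    expect_same_R(iv)
  }
  # perfectly exponential counts on every bin -> zero residual -> R = 0
  h <- build_ipi_histogram(rep(2, 3))
  h$bin_value <- seq(2, 40, by = 2)
  h$count <- 500 * exp(-0.3 * h$bin_value)
  h$n_intervals <- sum(h$count)
  hf <- fit_exponential(h, pipeline_config())
  expect_equal(compute_R(hf), 0, tolerance = 1e-9)
  expect_error(compute_R(fit_exponential(build_ipi_histogram(numeric(0)),
                                         pipeline_config())), "undefined")
})

test_that("R is invariant to cycle relabeling and scales with interval dilation", {
  set.seed(23)
  cycles <- replicate(12, sort(sample(1:500, sample(2:6, 1))), simplify = FALSE)
  r1 <- r_from_intervals(compute_sipis(speak_train(cycles)))$R
  r2 <- r_from_intervals(compute_sipis(speak_train(sample(cycles))))$R
  expect_equal(r1, r2)
  # dilation: with a degenerate fit (all mass above cutoff), t -> 2t doubles R
  for (i in 1:20) {
    iv <- 2 * sample(6:60, sample(2:40, 1), replace = TRUE)  # even, all > cutoff
    expect_equal(r_from_intervals(2 * iv)$R, 2 * r_from_intervals(iv)$R,
                 tolerance = 1e-12)
  }
})

test_that("the s-Peak matrix realizes the raster contract", {
  cfg <- pipeline_config()
  sp <- speed_series(rep(0.5, 2000), sample_rate = 240)
  cs <- cycle_set(data.frame(start = c(100L, 1000L), touch = c(500L, 1400L),
                             stop = c(900L, 1800L)), sp)
  tr <- speak_train(list(c(500L), c(1200L, 1400L, 1400L + 399L)), cycles = cs)
  m <- build_speak_matrix(tr, "touch", cfg)
  expect_equal(dim(m$matrix), c(2L, 800L))
  expect_equal(m$touch_column, 400L)
  expect_equal(which(m$matrix[1, ] == 1L), 400L)               # peak at the touch
  expect_equal(which(m$matrix[2, ] == 1L), c(200L, 400L, 799L))
  expect_true(all(m$matrix %in% c(0L, 1L)))
  # column sums equal the per-column peak-count histogram
  expect_equal(colSums(m$matrix),
               tabulate(unlist(Map(function(p, tc) p - tc + 400L,
                                   tr$peaks_by_cycle, cs$cycles$touch)), 800))
  # mean-length alignment: N_j is the rounded mean cycle length
  m2 <- build_speak_matrix(tr, "mean-length", cfg)
  expect_equal(ncol(m2$matrix), as.integer(round(mean(c(801, 801)))))
})

test_that("analyze_recording is deterministic and reports a coherent end-to-end result", {
  rec <- make_test_recording(n_cycles = 6)
  rep1 <- analyze_recording(rec)
  rep2 <- analyze_recording(rec)
  expect_identical(rep1$R, rep2$R)
  expect_equal(rep1$cycles$n_cycles, 6L)
  # noiseless: one peak per stroke, all s-IPIs equal T2 + rest + T1 = 260
  expect_equal(compute_sipis(rep1$train), rep(260, 6))
  expect_equal(rep1$R, 260)
  expect_true(rep1$hist$degenerate)
  # fewer than 2 touches errors with an actionable message
  short <- recording(matrix(rnorm(300), ncol = 3) / 1000)
  expect_error(suppressWarnings(analyze_recording(short)), "touch point")
})
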