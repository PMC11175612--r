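test_that("an on-bin sinusoid reads its amplitude exactly; zero reads zero", {
  fr <- 4
  n <- 3600 * fr
  t_s <- (seq_len(n) - 1) / fr
  zero <- make_movement_trace(rep(0, n), frame_rate = fr)
  sp0 <- sliding_fft(zero, window_length = 3600, step = 1800)
  expect_true(all(sp0$amplitudes == 0))
  a <- 0.37
  sine <- make_movement_trace(a * sin(2 * pi * t_s / 120), frame_rate = fr)
  sp <- sliding_fft(sine, window_length = 3600, step = 1800)
  k <- which.min(abs(sp$frequencies - 1 / 120))
  expect_equal(sp$frequencies[k], 1 / 120, tolerance = 1e-12)
  expect_equal(sp$amplitudes[1, k], a, tolerance = 1e-9)
  expect_lt(max(sp$amplitudes[1, -k]), 1e-9)
})

test_that("Parseval's relation holds per window under the rectangular taper", {
  set.seed(11)
  fr <- 4
  x <- rnorm(3600 * fr + 2000)
  tr <- make_movement_trace(x, frame_rate = fr)
  sp <- sliding_fft(tr, window_length = 3600, step = 1800)
  win <- 3600 * fr
  seg <- x[1:win]
  v <- mean((seg - mean(seg))^2)
  a <- sp$amplitudes[1, ]
  k_nyq <- length(a)  # even window: last bin is the unpaired Nyquist bin
  expect_equal(sum(a[-k_nyq]^2) / 2 + a[k_nyq]^2, v, tolerance = 1e-6)
})

test_that("spectral amplitudes are linear in the trace and windows counted", {
  set.seed(12)
  fr <- 4
  x <- abs(rnorm(10000))
  tr <- make_movement_trace(x, frame_rate = fr)
  sp1 <- sliding_fft(tr, window_length = 600, step = 300)
  tr2 <- tr; tr2$values <- 2.5 * x
  sp2 <- sliding_fft(tr2, window_length = 600, step = 300)
  expect_equal(sp2$amplitudes, 2.5 * sp1$amplitudes, tolerance = 1e-12)
  # window accounting: floor((N - win)/step) + 1, trailing partial dropped
  expect_equal(nrow(sp1$amplitudes), (10000 - 2400) %/% 1200 + 1)
  expect_error(sliding_fft(make_movement_trace(rep(0, 100)), 3600, 1800),
               "shorter")
})

test_that("synthetic wild-type bouts put every neurogenic window peak at the bout period", {
  p <- test_preset(bout_period = 180, bout_duration = 60, bout_jitter_sd = 0)
  res <- generate_trace(p, frame_rate = 4, record_start = 15,
                        record_duration = 5, seed = 31)
  mt <- crop_at_hatch(detrend_rectify(res$trace), p$hatch_time)
  sp <- sliding_fft(mt, window_length = 3600, step = 1800)
  neuro <- which(sp$window_centers >= p$rhythmic_onset &
                   sp$window_centers < p$hatch_time)
  expect_gt(length(neuro), 0)
  band <- sp$frequencies >= 1 / 1800 & sp$frequencies <= 1 / 4
  df <- sp$frequencies[2] - sp$frequencies[1]
  for (j in neuro) {
    f_peak <- sp$frequencies[band][which.max(sp$amplitudes[j, band])]
    expect_lte(abs(f_peak - 1 / 180), df + 1e-12)
  }
})

test_that("averaging spectrograms is the element-wise mean with embryo counts", {
  p <- test_preset()
  specs <- lapply(1:4, function(s) {
    res <- generate_trace(p, record_start = 15, record_duration = 5, seed = s)
    sliding_fft(detrend_rectify(res$trace), 3600, 1800)
  })
  avg <- average_spectrogram(specs)
  stack <- simplify2array(lapply(specs, `[[`, "amplitudes"))
  expect_equal(avg$amplitudes, apply(stack, c(1, 2), mean), tolerance = 1e-12)
  expect_true(all(avg$n_contributing == 4L))
  solo <- average_spectrogram(specs[1])
  expect_equal(solo$amplitudes, specs[[1]]$amplitudes)
  # incompatible grids rejected
  short <- sliding_fft(make_movement_trace(rep(0, 4800)), 600, 300)
  expect_error(average_spectrogram(list(specs[[1]], short)), "incompatible")
})

test_that("period-amplitude re-indexes by p = 1/f within the band", {
  fr <- 4
  t_s <- (seq_len(3600 * fr) - 1) / fr
  tr <- make_movement_trace(0.4 * sin(2 * pi * t_s / 180), frame_rate = fr,
                            record_start = 18)
  sp <- sliding_fft(tr, 3600, 1800)
  pa <- period_amplitude(sp)
  expect_true(all(diff(pa$periods) > 0))
  expect_true(all(pa$periods >= 4 & pa$periods <= 1800))
  expect_equal(pa$periods[which.max(pa$amplitudes)], 180, tolerance = 1e-9)
  expect_equal(max(pa$amplitudes), 0.4, tolerance = 1e-9)
  # a band excluding the driving period hides the peak
  pa2 <- period_amplitude(sp, band = c(4, 100))
  expect_lt(max(pa2$amplitudes), 1e-6)
  expect_error(period_amplitude(sp, band = c(100, 100)), "empty")
  s <- summarise_periods(pa)
  expect_equal(unname(s["modal_period"]), 180, tolerance = 1e-9)
})

test_that("bout detection recovers square-wave activity exactly at zero noise", {
  fr <- 4
  cycle <- c(rep(0.5, 60 * fr), rep(0, 120 * fr))
  x <- rep(cycle, 10)
  tr <- make_movement_trace(x, frame_rate = fr, record_start = 18)
  bouts <- detect_bouts(tr, smooth_window = 0, bout_threshold = 0.25,
                        min_duration = 5, merge_gap = 10)
  expect_equal(nrow(bouts), 10L)
  expect_true(all(bouts$duration == 60))
  truth_starts <- 18 + (0:9) * 180 / 3600
  expect_equal(bouts$start, truth_starts, tolerance = 1e-9)
  st <- bout_stats(bouts)
  expect_equal(st$count, 10L)
  expect_equal(st$mean_duration, 60)
  expect_equal(st$mean_interval, 180)
  # zero trace: no bouts; empty stats flagged as NA
  none <- detect_bouts(make_movement_trace(rep(0, 1000)), bout_threshold = 0.1)
  expect_equal(nrow(none), 0L)
  expect_true(is.na(bout_stats(none)$mean_duration))
  expect_error(detect_bouts(tr, bout_threshold = 0), "positive")
})

test_that("runs separated by short gaps merge into one bout", {
  fr <- 4
  x <- c(rep(0, 40), rep(1, 60 * fr), rep(0, 5 * fr), rep(1, 60 * fr),
         rep(0, 40))
  tr <- make_movement_trace(x, frame_rate = fr, record_start = 18)
  bouts <- detect_bouts(tr, smooth_window = 0, bout_threshold = 0.5,
                        min_duration = 5, merge_gap = 10)
  expect_equal(nrow(bouts), 1L)
  expect_equal(bouts$duration, 125)
  # with merge_gap below the gap, the two bouts stay separate
  two <- detect_bouts(tr, smooth_window = 0, bout_threshold = 0.5,
                      min_duration = 5, merge_gap = 4)
  expect_equal(nrow(two), 2L)
  expect_true(all(two$duration == 60))
})

test_that("sub-threshold noise between bouts does not change detection", {
  fr <- 4
  cycle <- c(rep(0.5, 60 * fr), rep(0, 120 * fr))
  x <- rep(cycle, 5)
  clean <- detect_bouts(make_movement_trace(x, frame_rate = fr),
                        bout_threshold = 0.2)
  set.seed(41)
  noisy_x <- x + ifelse(x == 0, runif(length(x), 0, 0.2 / 2), 0)
  noisy <- detect_bouts(make_movement_trace(noisy_x, frame_rate = fr),
                        bout_threshold = 0.2)
  expect_equal(nrow(noisy), nrow(clean))
  expect_equal(noisy$duration, clean$duration, tolerance = 0.05)
})

test_that("mutant-like cohorts show shorter bouts and smaller weighted periods", {
  wt <- test_preset("wt")
  mut <- preset_mutant(movement_onset = 16, rhythmic_onset = 17,
                       hatch_time = 19, gasfill_time = 18)
  spec <- cohort_spec(list(wt, mut), n_embryos = 6, record_start = 15,
                      record_duration = 5, seed = 55)
  coh <- generate_cohort(spec)
  stats_by <- lapply(coh$traces, function(tr) {
    mt <- crop_at_hatch(detrend_rectify(tr), 19)
    bouts <- detect_bouts(mt, time_window = c(17, 19))
    sp <- sliding_fft(mt, 3600, 1800)
    pa <- period_amplitude(sp, time_window = c(17, 19))
    c(dur = bout_stats(bouts)$mean_duration,
      wp = unname(summarise_periods(pa)["weighted_period"]))
  })
  m <- do.call(rbind, stats_by)
  is_wt <- coh$genotype == "wt"
  expect_gt(mean(m[is_wt, "dur"]), mean(m[!is_wt, "dur"]))
  expect_gt(mean(m[is_wt, "wp"]), mean(m[!is_wt, "wp"]))
})
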