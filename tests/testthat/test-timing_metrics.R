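# build an epoch_set directly from per-trial step latencies (seconds)
step_epochs <- function(onsets_s, rate = 250, amplitude = 10) {
  pre <- round(0.2 * rate)
  post <- round(0.8 * rate)
  rel <- ((-pre):(post - 1)) / rate
  trials <- t(vapply(onsets_s, function(o) {
    ifelse(rel >= o, amplitude, 0)
  }, numeric(pre + post)))
  epoch_set(rel, trials, trial_t0 = seq_along(onsets_s), nominal_rate = rate)
}

test_that("extract_epochs cuts aligned half-open windows around markers", {
  ts <- (0:2499) / 250                  # 10 s at 250 Hz, exact grid
  s <- sampled_stream(rnorm(2500), ts, nominal_rate = 250,
                      corrected_timestamps = ts)
  ep <- extract_epochs(s, marker_stream(5.0))
  expect_equal(ncol(ep$trials), 250L)   # 1.0 s x 250 Hz
  expect_equal(ep$rel_times[1], -0.2)
  expect_equal(ep$rel_times[250], 0.8 - 1 / 250)  # end-exclusive
  expect_equal(unique(round(diff(ep$rel_times), 12)), 1 / 250)
  # the epoch contains the samples at the right absolute times
  expect_equal(ep$trials[1, ], s$data[(5 - 0.2) * 250 + (1:250), 1])
})

test_that("markers with incomplete windows are dropped and counted", {
  ts <- (0:2499) / 250
  s <- sampled_stream(rnorm(2500), ts, nominal_rate = 250,
                      corrected_timestamps = ts)
  ep <- extract_epochs(s, marker_stream(c(0.05, 5.0)))  # pre-window cut off
  expect_equal(nrow(ep$trials), 1L)
  expect_equal(ep$n_dropped, 1L)
  expect_error(extract_epochs(s, marker_stream(2000)), "no epochs")
})

test_that("all simulator markers inside the recording become trials", {
  cfg <- sim_config(rate = 250, duration = 41.5, n_trials = 400, seed = 2)
  rec <- simulate_clean_recording(cfg)
  ep <- extract_epochs(regular_dejitter(rec$stream), rec$markers)
  expect_equal(nrow(ep$trials), 400L)
  expect_equal(ep$n_dropped, 0L)
})

test_that("identical step trials give exact latency and zero jitter", {
  ep <- step_epochs(rep(0.100, 5))
  r <- detect_latencies(ep)
  expect_equal(r$latencies_ms, rep(100, 5))
  expect_equal(r$lag_ms, 100)
  expect_equal(r$jitter_ms, 0)
})

test_that("half-maximum latencies average to lag with sample-SD jitter", {
  # 500 Hz grid so the 40/50/60 ms crossings are exactly representable
  r <- detect_latencies(step_epochs(c(0.040, 0.050, 0.060), rate = 500))
  expect_equal(r$lag_ms, 50)
  expect_equal(r$jitter_ms, 10)
  expect_equal(r$n_trials_used, 3L)
})

test_that("trials without a threshold crossing are missing, not zero", {
  ep <- step_epochs(c(0.040, 0.060))
  ep$trials[2, ] <- 0                  # flat trial: no crossing
  r <- detect_latencies(ep)
  expect_true(is.na(r$latencies_ms[2]))
  expect_equal(r$n_trials_used, 1L)
  expect_equal(r$lag_ms, 40)
})

test_that("detect_latencies errors without a positive response or 2 trials", {
  ep <- step_epochs(c(0.04, 0.05))
  ep$trials[] <- 0
  expect_error(detect_latencies(ep), "no response detected")
  expect_error(detect_latencies(step_epochs(0.04)), "at least 2 trials")
})

test_that("latencies never precede the marker", {
  rec <- simulate_recording(quick_chunked_cfg(seed = 11))
  r <- detect_latencies(extract_epochs(chunk_dejitter(rec$stream)$stream,
                                       rec$markers))
  expect_true(all(r$latencies_ms >= 0, na.rm = TRUE))
})

test_that("injected constant hardware lag is recovered to one sample", {
  # clean transport with zero transport delay: measured lag is the hardware
  # lag plus sub-sample quantization, so within one sample interval (4 ms)
  cfg <- quick_clean_cfg(seed = 3, hardware_lag = 0.030, onset_jitter_sd = 0)
  rec <- simulate_clean_recording(cfg)
  r <- detect_latencies(extract_epochs(regular_dejitter(rec$stream),
                                       rec$markers))
  expect_lt(abs(r$lag_ms - 30), sample_interval_ms(250))
  expect_lte(r$jitter_ms, 3 * sample_interval_ms(250) / sqrt(12))
})

test_that("correct_lag shifts corrected timestamps only", {
  ts <- (0:99) / 250
  s <- sampled_stream(rnorm(100), ts, nominal_rate = 250,
                      corrected_timestamps = ts)
  expect_equal(correct_lag(s, 0)$corrected_timestamps, ts)
  shifted <- correct_lag(s, 500)
  expect_equal(shifted$corrected_timestamps, ts - 0.5)
  expect_identical(shifted$data, s$data)
  expect_identical(shifted$raw_timestamps, s$raw_timestamps)
})

test_that("lag correction is self-consistent to one sample interval", {
  # small chunks keep the total lag below the 100 ms stimulus period, so
  # latencies are unambiguous before and after correction
  rec <- simulate_recording(quick_chunked_cfg(seed = 13, rate = 250,
                                              chunk_size_choices = 12,
                                              transport_delay = 0.02,
                                              hardware_lag = 0.01,
                                              onset_jitter_sd = 0))
  corr <- chunk_dejitter(rec$stream)$stream
  r1 <- detect_latencies(extract_epochs(corr, rec$markers))
  r2 <- detect_latencies(extract_epochs(correct_lag(corr, r1$lag_ms),
                                        rec$markers))
  expect_lt(abs(r2$lag_ms), sample_interval_ms(250))
})

test_that("summarize_runs averages across runs without weighting", {
  one <- summarize_runs(timing_result(c(20, 24)))
  expect_equal(one$mean_lag_ms, 22)
  expect_equal(one$lag_sd_ms, 0)       # single-run convention
  expect_equal(one$jitter_sd_ms, 0)
  two <- summarize_runs(list(timing_result(rep(20, 3)),
                             timing_result(rep(24, 3))))
  expect_equal(two$mean_lag_ms, 22)
  expect_equal(two$lag_sd_ms, sd(c(20, 24)))
  expect_error(summarize_runs(list()), "no runs")
})
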