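test_that("detect_chunks splits at large raw gaps and partitions all samples", {
  raw <- c(0.0000, 0.0002, 0.0004, 0.4800, 0.4802, 0.4804)
  s <- sampled_stream(rnorm(6), raw, nominal_rate = 125)
  cm <- detect_chunks(s)   # boundary threshold 2/125 = 16 ms
  expect_equal(nrow(cm), 2L)
  expect_equal(cm$start_index, c(1L, 4L))
  expect_equal(cm$end_index, c(3L, 6L))
  expect_equal(cm$reception_time, c(0.0, 0.48))
  expect_equal(cm$n_samples, c(3L, 3L))
})

test_that("a perfectly regular stream is one chunk", {
  s <- sampled_stream(rnorm(10), (0:9) / 125, nominal_rate = 125)
  cm <- detect_chunks(s)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$n_samples, 10L)
})

test_that("detect_chunks rejects streams with fewer than 2 samples", {
  s <- sampled_stream(1, 0, nominal_rate = 125)
  expect_error(detect_chunks(s), "stream too short")
})

test_that("detect_chunks recovers the simulator's emitted partition", {
  for (rate in c(125, 250)) {
    rec <- simulate_recording(quick_chunked_cfg(seed = 1, rate = rate))
    cm <- detect_chunks(rec$stream)
    expect_identical(cm$n_samples, rec$truth$emitted_chunk_sizes)
    expect_identical(cm$start_index, rec$truth$chunk_start_index)
  }
})

test_that("regular_dejitter reproduces an exact linear grid", {
  s <- sampled_stream(rnorm(100), (0:99) / 250, nominal_rate = 250)
  out <- regular_dejitter(s)
  expect_lt(max(abs(out$corrected_timestamps - s$raw_timestamps)), 1e-9)
})

test_that("regular_dejitter equals the closed-form OLS fit", {
  set.seed(42)
  e <- rnorm(200, 0, 5e-4)
  e <- e - mean(e)                       # known zero-mean perturbations
  ts <- (0:199) / 250 + e
  s <- sampled_stream(rnorm(200), ts, nominal_rate = 250)
  out <- regular_dejitter(s)
  expect_lt(max(abs(out$corrected_timestamps - ols_oracle(ts))), 1e-9)
})

test_that("segments separated by a gap are fitted independently", {
  ts <- c((0:49) / 250, 5 + 17.3 + (0:49) / 250)
  s <- sampled_stream(rnorm(100), ts, nominal_rate = 250)
  out <- regular_dejitter(s, gap_threshold = 1.0)
  expect_lt(max(abs(out$corrected_timestamps - ts)), 1e-9)
})

test_that("a single-sample segment keeps its raw timestamp", {
  ts <- c(0, 10, 10.004, 10.008)        # first segment has one sample
  s <- sampled_stream(rnorm(4), ts, nominal_rate = 250)
  out <- regular_dejitter(s)
  expect_equal(out$corrected_timestamps[1], 0)
})

test_that("chunk_dejitter extrapolates from the chunk reception timestamp", {
  raw <- 10.0 + (0:2) * 2e-4
  s <- sampled_stream(rnorm(3), raw, nominal_rate = 125)
  out <- chunk_dejitter(s)
  expect_equal(out$stream$corrected_timestamps, c(10.000, 10.008, 10.016))
  expect_false(any(out$chunks$shifted))
})

test_that("an overlapping short chunk is shifted in place by the stated delta", {
  # chunk A: 60 samples received at 0.0 (corrected last = 0.472 at 125 Hz);
  # chunk B: 10 samples received at 0.300 -> overlaps A after extrapolation;
  # delta = (0.472 + 0.008) - 0.300 = 0.180, so B spans [0.480, 0.552]
  raw <- clustered_raw(c(0.0, 0.3), c(60, 10))
  s <- sampled_stream(rnorm(70), raw, nominal_rate = 125)
  out <- chunk_dejitter(s)
  expect_equal(out$chunks$shifted, c(FALSE, TRUE))
  expect_equal(out$chunks$shift_s[2], 0.180, tolerance = 1e-12)
  b <- out$stream$corrected_timestamps[61:70]
  expect_equal(b[1], 0.480, tolerance = 1e-12)
  expect_equal(b[10], 0.552, tolerance = 1e-12)
  expect_true(all(diff(out$stream$corrected_timestamps) > 0))
})

test_that("consecutive short chunks cascade through the shift pass", {
  raw <- clustered_raw(c(0.0, 0.3, 0.35, 1.0), c(60, 10, 10, 60))
  s <- sampled_stream(rnorm(140), raw, nominal_rate = 125)
  out <- chunk_dejitter(s)
  expect_equal(out$chunks$shifted, c(FALSE, TRUE, TRUE, FALSE))
  ct <- out$stream$corrected_timestamps
  expect_true(all(diff(ct) > 0))
  # second short chunk starts one nominal interval after the first
  expect_equal(ct[71], ct[70] + 1 / 125, tolerance = 1e-12)
})

test_that("both dejitter methods are the identity on an exact grid", {
  ts <- (0:499) / 250
  s <- sampled_stream(rnorm(500), ts, nominal_rate = 250)
  expect_lt(max(abs(regular_dejitter(s)$corrected_timestamps - ts)), 1e-9)
  expect_lt(max(abs(chunk_dejitter(s)$stream$corrected_timestamps - ts)),
            1e-9)
})

test_that("chunk_dejitter yields a constant offset under constant transport", {
  # fixed chunk size and constant delay: corrected = truth + (d + (n-1)/rate)
  cfg <- quick_chunked_cfg(seed = 5, chunk_size_choices = 60,
                           short_chunk_prob = 0)
  rec <- simulate_recording(cfg)
  out <- chunk_dejitter(rec$stream)
  err <- out$stream$corrected_timestamps - rec$truth$true_sample_times
  expect_lt(diff(range(err)), 1e-9)
  expect_equal(err[1], cfg$transport_delay + 59 / 125, tolerance = 1e-9)
})

test_that("corrected timestamps strictly increase and preserve count/values", {
  rec <- simulate_recording(quick_chunked_cfg(seed = 9,
                                              short_chunk_prob = 0.1))
  for (corr in list(chunk_dejitter(rec$stream)$stream,
                    regular_dejitter(rec$stream))) {
    expect_true(all(diff(corr$corrected_timestamps) > 0))
    expect_length(corr$corrected_timestamps,
                  length(rec$stream$raw_timestamps))
    expect_identical(corr$data, rec$stream$data)
  }
})

test_that("chunk_dejitter rejects a nonpositive nominal rate", {
  s <- sampled_stream(rnorm(4), (0:3) / 125, nominal_rate = 0)
  expect_error(chunk_dejitter(s), "invalid rate")
})
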