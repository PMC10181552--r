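#' Epoch window and onset-detection parameters
#'
#' Defaults follow the usual ERP convention of cutting from 200 ms before
#' to 800 ms after the stimulus marker, with the pre-stimulus interval used
#' as baseline.
#'
#' @param window_start seconds relative to the marker (default -0.2).
#' @param window_end seconds relative to the marker (default +0.8); the
#'   window is half-open, `[window_start, window_end)`.
#' @param baseline_end seconds; the per-trial baseline is the mean over
#'   `[window_start, baseline_end)` (default 0).
#' @return An object of class `onset_params`.
#' @export
onset_params <- function(window_start = -0.2, window_end = 0.8,
                         baseline_end = 0) {
  stopifnot(window_start < baseline_end, baseline_end <= 0, window_end > 0)
  structure(list(window_start = window_start, window_end = window_end,
                 baseline_end = baseline_end),
            class = "onset_params")
}

#' Extract per-trial epochs around markers
#'
#' Cuts one window per marker from the (corrected) continuous recording.
#' For each marker time `t0`, the onset sample is the first sample whose
#' corrected timestamp is `>= t0`; the trial row spans
#' `round(-window_start * rate)` samples before it to
#' `round(window_end * rate) - 1` samples after it, so every row has the
#' same length and the rows are aligned on a common relative-time axis
#' spaced at `1/nominal_rate` (half-open window `[start, end)`). Markers
#' whose window is not fully inside the recording are dropped and counted
#' in `n_dropped`.
#'
#' Only the first channel is epoched (the timing test records the square
#' wave on a single channel).
#'
#' @param stream a [sampled_stream()] with `corrected_timestamps`.
#' @param markers a [marker_stream()].
#' @param params an [onset_params()].
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(stream, markers, params = onset_params()) {
  ts <- stream$corrected_timestamps
  if (is.null(ts)) stop("stream has no corrected timestamps; dejitter first")
  rate <- stream$nominal_rate
  n <- length(ts)
  pre <- round(-params$window_start * rate)
  post <- round(params$window_end * rate)
  # first sample with timestamp >= t0 (1e-9 s slack for float grids)
  i_on <- findInterval(markers$timestamps - 1e-9, ts) + 1L
  ok <- i_on - pre >= 1L & i_on + post - 1L <= n & i_on <= n
  if (!any(ok)) stop("no epochs: no marker window inside the recording")
  rows <- lapply(i_on[ok], function(i) {
    stream$data[(i - pre):(i + post - 1L), 1L]
  })
  epoch_set(
    rel_times = ((-pre):(post - 1L)) / rate,
    trials = do.call(rbind, rows),
    trial_t0 = markers$timestamps[ok],
    nominal_rate = rate,
    n_dropped = sum(!ok)
  )
}

#' Half-maximum onset latencies, lag and jitter
#'
#' The square-wave timing oracle: each trial's onset latency is the time
#' between the marker and the recorded amplitude exceeding half the
#' maximum of the trial-averaged response.
#'
#' Each trial is first baseline-corrected by subtracting its pre-stimulus
#' mean (`[window_start, baseline_end)`). The trial-averaged waveform is
#' the per-sample mean across corrected trials; the detection threshold is
#' half its post-stimulus maximum (`rel_time >= 0`). The single-trial
#' latency is the relative time, in milliseconds, of the first
#' post-stimulus sample exceeding the threshold; trials with no crossing
#' are `NA`. Lag is the mean and jitter the sample standard deviation
#' (n - 1) of the non-missing latencies. Latencies are reported at sample
#' resolution with no sub-sample interpolation.
#'
#' @param epochs an [epoch_set()] with at least 2 trials.
#' @param params the [onset_params()] used to cut the epochs.
#' @return A [timing_result()].
#' @export
detect_latencies <- function(epochs, params = onset_params()) {
  if (nrow(epochs$trials) < 2) stop("need at least 2 trials")
  rel <- epochs$rel_times
  base_idx <- rel >= params$window_start & rel < params$baseline_end
  baseline <- rowMeans(epochs$trials[, base_idx, drop = FALSE])
  corrected <- epochs$trials - baseline
  avg <- colMeans(corrected)
  post <- which(rel >= 0)
  peak <- max(avg[post])
  if (peak <= 0) stop("no response detected: nonpositive post-stimulus peak")
  threshold <- 0.5 * peak
  lat <- apply(corrected[, post, drop = FALSE], 1L, function(v) {
    i <- which(v > threshold)
    if (length(i)) rel[post[i[1L]]] * 1000 else NA_real_
  })
  timing_result(unname(lat))
}

#' Shift corrected timestamps by a measured lag
#'
#' Once the run's average lag is known (from [detect_latencies()] on a
#' timing-oracle recording), the constant offset can be removed by
#' subtracting it from the corrected signal timestamps, aligning the
#' signal with the marker clock.
#'
#' @param stream a [sampled_stream()] with `corrected_timestamps`.
#' @param lag_ms lag in milliseconds to subtract.
#' @return the stream with all corrected timestamps reduced by
#'   `lag_ms / 1000`; sample values unchanged.
#' @export
correct_lag <- function(stream, lag_ms) {
  if (is.null(stream$corrected_timestamps)) {
    stop("stream has no corrected timestamps; dejitter first")
  }
  stream$corrected_timestamps <- stream$corrected_timestamps - lag_ms / 1000
  stream
}

#' Summarize timing results across runs
#'
#' Plain (unweighted) averages and standard deviations of the per-run lag
#' and jitter across a set of runs of one configuration. With a single
#' run, the across-run SDs are reported as 0.
#'
#' @param results list of [timing_result()] objects.
#' @return A one-row tibble with `n_runs`, `mean_lag_ms`, `mean_jitter_ms`,
#'   `lag_sd_ms`, `jitter_sd_ms`.
#' @export
summarize_runs <- function(results) {
  if (inherits(results, "timing_result")) results <- list(results)
  if (!length(results)) stop("no runs")
  lags <- vapply(results, function(r) r$lag_ms, numeric(1))
  jits <- vapply(results, function(r) r$jitter_ms, numeric(1))
  tibble::tibble(
    n_runs = length(results),
    mean_lag_ms = mean(lags),
    mean_jitter_ms = mean(jits),
    lag_sd_ms = if (length(lags) > 1) stats::sd(lags) else 0,
    jitter_sd_ms = if (length(jits) > 1) stats::sd(jits) else 0
  )
}
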