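#' Sampled signal stream
#'
#' Container for one amplifier's channel data together with the raw
#' per-sample timestamps assigned at reception and, optionally, a set of
#' corrected (dejittered) timestamps. Timestamps are double-precision
#' seconds on the recorder's clock (the XDF convention); sample values are
#' microvolts.
#'
#' Raw timestamps of a chunked transport cluster at chunk reception time and
#' are therefore only required to be non-decreasing; corrected timestamps,
#' when present, must be strictly increasing.
#'
#' @param data numeric matrix (samples x channels) or vector of sample
#'   values in microvolts.
#' @param raw_timestamps numeric vector of reception timestamps in seconds,
#'   one per sample.
#' @param nominal_rate nominal sampling rate in Hz from stream metadata.
#' @param channel_labels optional character vector of channel names.
#' @param corrected_timestamps optional numeric vector of dejittered
#'   timestamps in seconds.
#' @param name stream name (used when writing XDF).
#'
#' @return An object of class `sampled_stream`.
#' @seealso [validate_stream()], [regular_dejitter()], [chunk_dejitter()]
#' @export
#' @examples
#' s <- sampled_stream(rnorm(10), raw_timestamps = (0:9) / 250,
#'                     nominal_rate = 250)
#' validate_stream(s)
sampled_stream <- function(data, raw_timestamps, nominal_rate,
                           channel_labels = NULL,
                           corrected_timestamps = NULL,
                           name = "EEG") {
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1L)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("Ch", seq_len(ncol(data)))
  }
  structure(
    list(
      data = data,
      raw_timestamps = as.numeric(raw_timestamps),
      corrected_timestamps = if (!is.null(corrected_timestamps)) {
        as.numeric(corrected_timestamps)
      },
      nominal_rate = as.numeric(nominal_rate),
      channel_labels = as.character(channel_labels),
      name = name
    ),
    class = "sampled_stream"
  )
}

#' @export
print.sampled_stream <- function(x, ...) {
  cat(sprintf(
    "<sampled_stream '%s': %d samples x %d channel(s), %g Hz nominal>\n",
    x$name, nrow(x$data), ncol(x$data), x$nominal_rate
  ))
  cat(sprintf("  raw timestamps: [%.4f, %.4f] s\n",
              min(x$raw_timestamps), max(x$raw_timestamps)))
  if (!is.null(x$corrected_timestamps)) {
    cat(sprintf("  corrected timestamps: [%.4f, %.4f] s\n",
                min(x$corrected_timestamps), max(x$corrected_timestamps)))
  } else {
    cat("  corrected timestamps: absent\n")
  }
  invisible(x)
}

#' Event-marker stream
#'
#' Stimulus event labels with their software timestamps. The marker
#' timestamp defines the timing reference (t0) of each trial.
#'
#' @param timestamps numeric vector of marker times in seconds, strictly
#'   increasing.
#' @param labels character vector of marker labels (recycled if length 1).
#' @param name stream name (used when writing XDF).
#'
#' @return An object of class `marker_stream`.
#' @export
marker_stream <- function(timestamps, labels = "stim", name = "Markers") {
  timestamps <- as.numeric(timestamps)
  labels <- rep_len(as.character(labels), length(timestamps))
  structure(
    list(timestamps = timestamps, labels = labels, name = name),
    class = "marker_stream"
  )
}

#' @export
print.marker_stream <- function(x, ...) {
  cat(sprintf("<marker_stream '%s': %d markers>\n", x$name,
              length(x$timestamps)))
  invisible(x)
}

#' Validate a sampled or marker stream
#'
#' Checks the structural invariants of a stream and reports violations as
#' a character vector (empty when the stream is consistent). Validation
#' never throws and never mutates its input, so it can be used to triage
#' questionable recordings before processing.
#'
#' Checked for `sampled_stream`: sample count equals timestamp count;
#' `nominal_rate > 0`; corrected timestamps (when present) match the sample
#' count and are strictly increasing. For `marker_stream`: timestamps
#' strictly increasing and one label per marker.
#'
#' @param stream a [sampled_stream()] or [marker_stream()].
#' @return character vector of violation descriptions; `character(0)` iff
#'   all invariants hold.
#' @export
validate_stream <- function(stream) {
  UseMethod("validate_stream")
}

#' @export
validate_stream.sampled_stream <- function(stream) {
  out <- character(0)
  if (nrow(stream$data) != length(stream$raw_timestamps)) {
    out <- c(out, "length mismatch: sample count != timestamp count")
  }
  if (!is.finite(stream$nominal_rate) || stream$nominal_rate <= 0) {
    out <- c(out, "nonpositive rate")
  }
  if (!is.null(stream$corrected_timestamps)) {
    ct <- stream$corrected_timestamps
    if (length(ct) != length(stream$raw_timestamps)) {
      out <- c(out, "length mismatch: corrected timestamp count")
    } else if (length(ct) > 1 && any(diff(ct) <= 0)) {
      out <- c(out, "corrected timestamps not strictly increasing")
    }
  }
  out
}

#' @export
validate_stream.marker_stream <- function(stream) {
  out <- character(0)
  if (length(stream$timestamps) != length(stream$labels)) {
    out <- c(out, "length mismatch: labels vs timestamps")
  }
  if (length(stream$timestamps) > 1 && any(diff(stream$timestamps) <= 0)) {
    out <- c(out, "marker timestamps not strictly increasing")
  }
  out
}

#' Chunk map constructor
#'
#' Partition of a stream's samples into transmission chunks. Rarely called
#' directly; produced by [detect_chunks()] and annotated by
#' [chunk_dejitter()].
#'
#' @param start,end integer vectors of first/last sample index per chunk
#'   (1-based, `end` inclusive).
#' @param reception numeric vector, reception timestamp (seconds) of each
#'   chunk: the raw timestamp of its first sample.
#' @param short,shifted logical flags per chunk.
#' @return A `chunk_map` tibble with columns `chunk`, `start_index`,
#'   `end_index`, `n_samples`, `reception_time`, `short`, `shifted`.
#' @export
chunk_map <- function(start, end, reception,
                      short = logical(length(start)),
                      shifted = logical(length(start))) {
  n <- as.integer(end) - as.integer(start) + 1L
  stopifnot(all(n >= 1L))
  out <- tibble::tibble(
    chunk = seq_along(start),
    start_index = as.integer(start),
    end_index = as.integer(end),
    n_samples = n,
    reception_time = as.numeric(reception),
    short = short,
    shifted = shifted
  )
  class(out) <- c("chunk_map", class(out))
  out
}

#' Per-trial epoch container
#'
#' Windows of signal cut relative to stimulus markers, aligned on a common
#' relative-time axis.
#'
#' @param rel_times numeric vector of times in seconds relative to the
#'   marker, spaced at `1/nominal_rate`.
#' @param trials numeric matrix (trial x sample) of microvolt values.
#' @param trial_t0 absolute marker timestamps of the retained trials.
#' @param nominal_rate sampling rate in Hz.
#' @param n_dropped number of markers dropped because their window was not
#'   fully inside the recording.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(rel_times, trials, trial_t0, nominal_rate,
                      n_dropped = 0L) {
  stopifnot(ncol(trials) == length(rel_times),
            nrow(trials) == length(trial_t0))
  structure(
    list(rel_times = rel_times, trials = trials, trial_t0 = trial_t0,
         nominal_rate = nominal_rate, n_dropped = as.integer(n_dropped)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set: %d trials x %d samples, rel time [%.3f, %.3f] s, %d dropped>\n",
    nrow(x$trials), ncol(x$trials), min(x$rel_times), max(x$rel_times),
    x$n_dropped
  ))
  invisible(x)
}

#' Timing result for one recording/run
#'
#' Per-trial onset latencies plus their summary statistics. Lag is the mean
#' of the non-missing single-trial latencies and jitter their sample
#' standard deviation (n - 1 denominator); trials with no threshold
#' crossing are `NA` and excluded from both.
#'
#' @param latencies_ms numeric vector of per-trial latencies in
#'   milliseconds; `NA` marks trials with no threshold crossing.
#' @return An object of class `timing_result` with fields `latencies_ms`,
#'   `lag_ms`, `jitter_ms`, `n_trials_used`.
#' @export
timing_result <- function(latencies_ms) {
  used <- latencies_ms[!is.na(latencies_ms)]
  structure(
    list(
      latencies_ms = latencies_ms,
      lag_ms = if (length(used)) mean(used) else NA_real_,
      jitter_ms = if (length(used) > 1) stats::sd(used) else 0,
      n_trials_used = length(used)
    ),
    class = "timing_result"
  )
}

#' @export
print.timing_result <- function(x, ...) {
  cat(sprintf(
    "<timing_result: lag %.2f ms, jitter %.2f ms, %d/%d trials used>\n",
    x$lag_ms, x$jitter_ms, x$n_trials_used, length(x$latencies_ms)
  ))
  invisible(x)
}

#' Nominal sample interval in milliseconds
#'
#' The timing resolution of latency estimates at a given sampling rate,
#' e.g. 8 ms at 125 Hz and 2 ms at 500 Hz.
#'
#' @param rate sampling rate in Hz.
#' @return interval in milliseconds.
#' @export
sample_interval_ms <- function(rate) {
  stopifnot(rate > 0)
  1000 / rate
}
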