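#' Parameters for chunk detection and chunk dejittering
#'
#' @param boundary_factor dimensionless multiplier of the nominal sample
#'   interval: a new chunk starts wherever the raw inter-sample gap exceeds
#'   `boundary_factor / nominal_rate`. Must be > 1. The default 2 separates
#'   the near-zero within-chunk stamp spacing from inter-chunk gaps (which
#'   are on the order of the whole chunk duration) by a wide margin.
#' @param overlap_tolerance seconds of overlap tolerated before a chunk is
#'   declared short/overlapping and shifted; >= 0. The default 0 shifts any
#'   chunk whose extrapolated start does not strictly exceed the previous
#'   chunk's corrected end.
#' @return An object of class `chunk_dejitter_params`.
#' @export
chunk_dejitter_params <- function(boundary_factor = 2, overlap_tolerance = 0) {
  stopifnot(boundary_factor > 1, overlap_tolerance >= 0)
  structure(list(boundary_factor = boundary_factor,
                 overlap_tolerance = overlap_tolerance),
            class = "chunk_dejitter_params")
}

#' Detect transmission chunks from raw timestamps
#'
#' A buffered transport delivers samples in bursts whose raw timestamps
#' cluster at the chunk reception time: tiny sample-to-sample differences
#' within a chunk, and a difference on the order of the buffered duration
#' between chunks. A new chunk therefore begins at sample `i` iff
#' `raw[i] - raw[i-1] > boundary_factor / nominal_rate`; sample 1 always
#' begins a chunk. The reception timestamp of a chunk is the raw timestamp
#' of its first sample. Large negative raw differences (recorder clock
#' resets) also open a new chunk.
#'
#' Chunks whose size is below the modal chunk size are flagged `short`.
#'
#' @param stream a [sampled_stream()] with at least 2 samples.
#' @param params a [chunk_dejitter_params()].
#' @return A [chunk_map()] whose chunks partition all samples.
#' @export
detect_chunks <- function(stream, params = chunk_dejitter_params()) {
  ts <- stream$raw_timestamps
  n <- length(ts)
  if (n < 2) stop("stream too short: need at least 2 samples")
  if (!is.finite(stream$nominal_rate) || stream$nominal_rate <= 0) {
    stop("invalid rate")
  }
  thr <- params$boundary_factor / stream$nominal_rate
  d <- diff(ts)
  starts <- c(1L, which(d > thr | d < -thr) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  sizes <- ends - starts + 1L
  modal <- as.integer(names(which.max(table(sizes))))
  chunk_map(starts, ends, reception = ts[starts], short = sizes < modal)
}

#' Segment-wise linear ("regular") dejitter
#'
#' The conventional timestamp correction used by XDF importers: the
#' recording is split into segments at raw inter-sample gaps larger than
#' `gap_threshold`, and within each segment the timestamps are replaced by
#' the fitted values of an ordinary-least-squares line of raw timestamp
#' versus sample index. Sample values and segment boundaries are
#' unchanged; a single-sample segment keeps its raw timestamp.
#'
#' This global fit assumes stamping noise that is small and symmetric
#' around the true sample times. On chunked transports (where raw stamps
#' cluster at chunk reception) it yields erratic per-sample errors of up
#' to half a chunk duration; use [chunk_dejitter()] there.
#'
#' @param stream a [sampled_stream()] with >= 2 samples.
#' @param gap_threshold seconds; raw gaps larger than this split segments.
#' @return the stream with `corrected_timestamps` filled in.
#' @export
regular_dejitter <- function(stream, gap_threshold = 1.0) {
  ts <- stream$raw_timestamps
  n <- length(ts)
  if (n < 2) stop("stream too short: need at least 2 samples")
  d <- diff(ts)
  starts <- c(1L, which(d > gap_threshold | d < -gap_threshold) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  corrected <- ts
  for (s in seq_along(starts)) {
    idx <- starts[s]:ends[s]
    if (length(idx) >= 2) {
      k <- seq_along(idx)
      fit <- stats::lm.fit(cbind(1, k), ts[idx])
      corrected[idx] <- fit$coefficients[1] + fit$coefficients[2] * k
    }
  }
  stream$corrected_timestamps <- corrected
  stream
}

#' Chunk dejitter with short-chunk shifting
#'
#' Local timestamp correction for chunked transports. Trusting the
#' temporal accuracy of chunk reception timestamps, the algorithm
#' (1) detects chunk boundaries from large sample-to-sample raw timestamp
#' differences ([detect_chunks()]), (2) extrapolates the timestamps of
#' each chunk from its first sample (the original chunk reception
#' timestamp) at the nominal sampling rate, so within chunk `c` starting
#' at index `s` with reception time `T_c`,
#' `corrected[s + k] = T_c + k / nominal_rate`, and (3) repairs short
#' chunks: scanning in temporal order, any chunk whose extrapolated first
#' timestamp is at or before the previous chunk's corrected last timestamp
#' (plus `overlap_tolerance`) is shifted right in place so it begins one
#' nominal interval after the previous chunk's corrected end. Shifts are
#' applied sequentially so consecutive short chunks cascade.
#'
#' The result has strictly increasing corrected timestamps with exactly
#' `1/nominal_rate` spacing inside every chunk; sample order and values
#' are untouched.
#'
#' @param stream a [sampled_stream()].
#' @param params a [chunk_dejitter_params()].
#' @return A list with elements `stream` (with `corrected_timestamps`)
#'   and `chunks` (the [chunk_map()] with `shifted` flags and applied
#'   `shift_s` deltas).
#' @export
chunk_dejitter <- function(stream, params = chunk_dejitter_params()) {
  if (!is.finite(stream$nominal_rate) || stream$nominal_rate <= 0) {
    stop("invalid rate")
  }
  cm <- detect_chunks(stream, params)
  dt <- 1 / stream$nominal_rate
  corrected <- numeric(length(stream$raw_timestamps))
  shift_s <- numeric(nrow(cm))
  shifted <- logical(nrow(cm))
  prev_last <- -Inf
  for (c in seq_len(nrow(cm))) {
    idx <- cm$start_index[c]:cm$end_index[c]
    first <- cm$reception_time[c]
    if (first <= prev_last + params$overlap_tolerance) {
      shift_s[c] <- (prev_last + dt) - first
      shifted[c] <- TRUE
      first <- first + shift_s[c]
    }
    corrected[idx] <- first + (seq_along(idx) - 1) * dt
    prev_last <- corrected[idx[length(idx)]]
  }
  cm$shifted <- shifted
  cm$shift_s <- shift_s
  stream$corrected_timestamps <- corrected
  list(stream = stream, chunks = cm)
}
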