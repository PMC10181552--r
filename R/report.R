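#' Load a recording from an XDF file and apply timestamp correction
#'
#' Finds the first sampled stream (nominal rate > 0, numeric channel
#' format) and the first marker stream (string format) in the file, builds
#' the package's stream objects with raw timestamps preserved, and applies
#' the requested dejitter method.
#'
#' @param path XDF file path.
#' @param method `"chunk"` ([chunk_dejitter()]), `"regular"`
#'   ([regular_dejitter()]) or `"none"` (raw timestamps only).
#' @param params a [chunk_dejitter_params()] (chunk method).
#' @param gap_threshold segment-split threshold in seconds (regular
#'   method).
#' @param stream_name optional regular expression; when several sampled
#'   streams are present, the first whose name matches is used.
#' @return A list with `stream` (corrected unless `method = "none"`),
#'   `markers`, and `chunks` (a [chunk_map()], `NULL` unless
#'   `method = "chunk"`).
#' @export
load_recording <- function(path, method = c("chunk", "regular", "none"),
                           params = chunk_dejitter_params(),
                           gap_threshold = 1.0, stream_name = NULL) {
  method <- match.arg(method)
  raw <- read_xdf(path)
  is_sampled <- vapply(raw, function(s) {
    s$info$nominal_srate > 0 && s$info$channel_format != "string"
  }, logical(1))
  is_marker <- vapply(raw, function(s) {
    s$info$channel_format == "string"
  }, logical(1))
  if (!is.null(stream_name)) {
    nm <- vapply(raw, function(s) s$info$name, character(1))
    is_sampled <- is_sampled & grepl(stream_name, nm)
  }
  if (!any(is_sampled)) stop("stream not found: no sampled stream")
  if (!any(is_marker)) stop("stream not found: no marker stream")
  ss <- raw[[which(is_sampled)[1]]]
  ms <- raw[[which(is_marker)[1]]]
  stream <- sampled_stream(ss$data, ss$timestamps, ss$info$nominal_srate,
                           channel_labels = ss$info$channel_labels,
                           name = ss$info$name)
  markers <- marker_stream(ms$timestamps, ms$labels, name = ms$info$name)
  chunks <- NULL
  if (method == "chunk") {
    res <- chunk_dejitter(stream, params)
    stream <- res$stream
    chunks <- res$chunks
  } else if (method == "regular") {
    stream <- regular_dejitter(stream, gap_threshold)
  }
  list(stream = stream, markers = markers, chunks = chunks)
}

#' Timing report over a set of recordings
#'
#' Runs the full timing-oracle pipeline (load or take a recording,
#' dejitter, epoch around markers, half-maximum latency detection) on each
#' input and summarizes lag and jitter across the runs with
#' [summarize_runs()].
#'
#' @param inputs character vector of XDF paths, or a list of in-memory
#'   recordings as returned by [simulate_recording()] (elements `stream`,
#'   `markers`).
#' @param method,params,gap_threshold passed to [load_recording()] /
#'   the dejitter functions.
#' @param onset the [onset_params()] for epoching and onset detection.
#' @param lag_correct if `TRUE`, each run's measured lag is subtracted
#'   from the corrected timestamps and the latencies re-measured; the
#'   reported lag/jitter are then the post-correction values.
#' @param label configuration label stored in the report.
#' @return A list of class `timing_report` with `runs` (per-run list:
#'   `run_id`, `method`, `result`, `n_dropped`, `chunks`), `trials` (tibble
#'   with one row per trial), and `summary` (one-row tibble from
#'   [summarize_runs()] plus the label and method).
#' @export
run_timing_report <- function(inputs, method = c("chunk", "regular", "none"),
                              params = chunk_dejitter_params(),
                              gap_threshold = 1.0,
                              onset = onset_params(),
                              lag_correct = FALSE,
                              label = "run") {
  method <- match.arg(method)
  if (!length(inputs)) stop("no runs")
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (!is.null(inputs$stream)) inputs <- list(inputs)
  runs <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    x <- inputs[[i]]
    if (is.character(x)) {
      rec <- load_recording(x, method, params, gap_threshold)
      run_id <- basename(x)
    } else {
      stream <- x$stream
      chunks <- NULL
      if (method == "chunk") {
        res <- chunk_dejitter(stream, params)
        stream <- res$stream
        chunks <- res$chunks
      } else if (method == "regular") {
        stream <- regular_dejitter(stream, gap_threshold)
      } else if (is.null(stream$corrected_timestamps)) {
        stream$corrected_timestamps <- stream$raw_timestamps
      }
      rec <- list(stream = stream, markers = x$markers, chunks = chunks)
      run_id <- sprintf("run%02d", i)
    }
    epochs <- extract_epochs(rec$stream, rec$markers, onset)
    result <- detect_latencies(epochs, onset)
    if (lag_correct) {
      corrected <- correct_lag(rec$stream, result$lag_ms)
      epochs <- extract_epochs(corrected, rec$markers, onset)
      result <- detect_latencies(epochs, onset)
    }
    runs[[i]] <- list(run_id = run_id, method = method, result = result,
                      n_dropped = epochs$n_dropped, chunks = rec$chunks)
  }
  trials <- do.call(rbind, lapply(runs, function(r) {
    lat <- r$result$latencies_ms
    tibble::tibble(run_id = r$run_id, trial_index = seq_along(lat),
                   latency_ms = lat, crossed = !is.na(lat))
  }))
  summary <- summarize_runs(lapply(runs, function(r) r$result))
  summary <- tibble::add_column(summary, configuration = label,
                                method = method, .before = 1)
  structure(list(runs = runs, trials = trials, summary = summary),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("<timing_report: %d run(s), method '%s'>\n",
              length(x$runs), x$summary$method[1]))
  print(x$summary)
  invisible(x)
}

#' Write a timing report to disk
#'
#' Writes `trials.csv` (one row per trial: run_id, trial_index,
#' latency_ms, crossed) and `summary.json` (configuration summary plus
#' per-run lag/jitter and the per-chunk audit table when available).
#'
#' @param report a `timing_report` from [run_timing_report()].
#' @param dir output directory (created if needed).
#' @param plot if `TRUE` and ggplot2 is installed, also writes
#'   `latencies.pdf` with per-run latency boxplots.
#' @return `dir`, invisibly.
#' @export
write_timing_report <- function(report, dir, plot = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  per_run <- lapply(report$runs, function(r) {
    out <- list(run_id = r$run_id, method = r$method,
                lag_ms = r$result$lag_ms, jitter_ms = r$result$jitter_ms,
                n_trials_used = r$result$n_trials_used,
                n_dropped = r$n_dropped)
    if (!is.null(r$chunks)) {
      out$chunks <- list(n_chunks = nrow(r$chunks),
                         n_shifted = sum(r$chunks$shifted),
                         sizes = as.integer(r$chunks$n_samples))
    }
    out
  })
  jsonlite::write_json(
    list(summary = report$summary, runs = per_run),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (plot) {
    p <- plot_latencies(report)
    if (!is.null(p)) {
      grDevices::pdf(file.path(dir, "latencies.pdf"), width = 7, height = 4)
      print(p)
      grDevices::dev.off()
    }
  }
  invisible(dir)
}

#' Latency distribution boxplots
#'
#' One box per run of single-trial onset latencies, the standard summary
#' figure of a timing test.
#'
#' @param report a `timing_report`.
#' @return a ggplot object, or `NULL` (with a message) when ggplot2 is not
#'   installed.
#' @export
plot_latencies <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    message("ggplot2 not installed; skipping plot")
    return(NULL)
  }
  d <- report$trials[report$trials$crossed, ]
  ggplot2::ggplot(d, ggplot2::aes(x = run_id, y = latency_ms)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Single-trial latency (ms)",
                  title = sprintf("%s (%s dejitter)",
                                  report$summary$configuration[1],
                                  report$summary$method[1])) +
    ggplot2::theme_minimal()
}
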