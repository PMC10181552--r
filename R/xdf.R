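# Minimal XDF 1.0 reader/writer.
#
# Supports the subset of the format needed for timing-test recordings:
# FileHeader (tag 1), StreamHeader (2), Samples (3), StreamFooter (6)
# chunks; channel formats double64, float32 and string; explicit 8-byte
# per-sample timestamps. ClockOffset and Boundary chunks are skipped on
# read and never written (marker-to-stream clock alignment is assumed to
# be provided by the acquisition layer).

xdf_magic <- charToRaw("XDF:")

# length descriptor: 1 byte NumLengthBytes (1/4/8) + little-endian value
write_varlen <- function(n) {
  if (n <= 255) {
    c(as.raw(1L), writeBin(n, raw(), size = 1, endian = "little"))
  } else {
    c(as.raw(4L), writeBin(as.integer(n), raw(), size = 4, endian = "little"))
  }
}

raw_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

write_chunk <- function(tag, content) {
  c(write_varlen(length(content) + 2L),
    writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    content)
}

stream_header_xml <- function(id, name, type, channel_count, nominal_srate,
                              channel_format, channel_labels = NULL) {
  labels <- if (!is.null(channel_labels)) {
    paste0(vapply(channel_labels, function(l) {
      sprintf("<channel><label>%s</label></channel>", l)
    }, character(1)), collapse = "")
  } else ""
  sprintf(paste0(
    '<?xml version="1.0"?><info><name>%s</name><type>%s</type>',
    "<channel_count>%d</channel_count><nominal_srate>%.6f</nominal_srate>",
    "<channel_format>%s</channel_format><desc><channels>%s</channels></desc>",
    "</info>"),
    name, type, channel_count, nominal_srate, channel_format, labels)
}

# one Samples chunk for a block of numeric samples (double64)
samples_chunk_numeric <- function(id, timestamps, values) {
  n <- length(timestamps)
  ch <- ncol(values)
  ts_raw <- matrix(writeBin(as.numeric(timestamps), raw(), size = 8,
                            endian = "little"), nrow = 8)
  val_raw <- matrix(writeBin(as.numeric(t(values)), raw(), size = 8,
                             endian = "little"), nrow = 8 * ch)
  body <- as.vector(rbind(matrix(as.raw(8L), nrow = 1, ncol = n),
                          ts_raw, val_raw))
  content <- c(writeBin(as.integer(id), raw(), size = 4, endian = "little"),
               write_varlen(n), body)
  write_chunk(3L, content)
}

samples_chunk_string <- function(id, timestamps, values) {
  body <- raw(0)
  parts <- lapply(seq_along(timestamps), function(i) {
    s <- charToRaw(enc2utf8(values[i]))
    c(as.raw(8L),
      writeBin(timestamps[i], raw(), size = 8, endian = "little"),
      write_varlen(length(s)), s)
  })
  content <- c(writeBin(as.integer(id), raw(), size = 4, endian = "little"),
               write_varlen(length(timestamps)), do.call(c, parts))
  write_chunk(3L, content)
}

#' Write streams to an XDF file
#'
#' Writes one or more streams to a multi-stream XDF 1.0 file. Sampled
#' streams are stored with channel format `double64` and explicit 8-byte
#' per-sample timestamps, so timestamps and sample values round-trip
#' bit-exactly; marker streams are stored as string channels with nominal
#' rate 0. The **raw** timestamps of a sampled stream are written
#' (corrected timestamps are a processing product, recomputed on load).
#'
#' @param path output file path.
#' @param streams list of [sampled_stream()] / [marker_stream()] objects.
#' @param chunk_sizes optional list (same length as `streams`) of integer
#'   vectors giving how many samples to place in each Samples chunk, e.g.
#'   the simulator's emitted chunk sizes so the file mirrors the transport
#'   structure; default one chunk per stream.
#' @return `path`, invisibly.
#' @export
write_xdf <- function(path, streams, chunk_sizes = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(xdf_magic, con)
  header <- charToRaw('<?xml version="1.0"?><info><version>1.0</version></info>')
  writeBin(write_chunk(1L, header), con)
  for (i in seq_along(streams)) {
    s <- streams[[i]]
    id <- i
    id_raw <- writeBin(as.integer(id), raw(), size = 4, endian = "little")
    if (inherits(s, "sampled_stream")) {
      hdr <- stream_header_xml(id, s$name, "EEG", ncol(s$data),
                               s$nominal_rate, "double64", s$channel_labels)
      writeBin(write_chunk(2L, c(id_raw, charToRaw(hdr))), con)
      ts <- s$raw_timestamps
      sizes <- if (!is.null(chunk_sizes) && !is.null(chunk_sizes[[i]])) {
        chunk_sizes[[i]]
      } else length(ts)
      ends <- cumsum(sizes)
      starts <- ends - sizes + 1L
      for (c in seq_along(sizes)) {
        idx <- starts[c]:ends[c]
        writeBin(samples_chunk_numeric(id, ts[idx],
                                       s$data[idx, , drop = FALSE]), con)
      }
      n <- length(ts)
    } else if (inherits(s, "marker_stream")) {
      hdr <- stream_header_xml(id, s$name, "Markers", 1L, 0, "string")
      writeBin(write_chunk(2L, c(id_raw, charToRaw(hdr))), con)
      writeBin(samples_chunk_string(id, s$timestamps, s$labels), con)
      ts <- s$timestamps
      n <- length(ts)
    } else {
      stop("format error: unsupported stream object")
    }
    footer <- sprintf(paste0(
      '<?xml version="1.0"?><info><first_timestamp>%.9f</first_timestamp>',
      "<last_timestamp>%.9f</last_timestamp>",
      "<sample_count>%d</sample_count></info>"),
      ts[1], ts[n], n)
    writeBin(write_chunk(6L, c(id_raw, charToRaw(footer))), con)
  }
  invisible(path)
}

read_varlen_con <- function(con) {
  nb <- readBin(con, "integer", 1L, size = 1, signed = FALSE)
  if (!length(nb)) return(NULL)
  raw_uint(readBin(con, "raw", nb))
}

#' Read an XDF file
#'
#' Parses the subset of XDF written by [write_xdf()] (and by standard LSL
#' recorders when restricted to double64/float32/int channel formats and
#' string markers, without clock-offset chunks). Samples split across
#' multiple Samples chunks are concatenated in file order.
#'
#' @param path XDF file path.
#' @return A list of streams; each element has `info` (named list with
#'   `name`, `type`, `channel_count`, `nominal_srate`, `channel_format`,
#'   `channel_labels`), `timestamps` and either `data` (samples x channels
#'   numeric matrix) or `labels` (character, for string streams).
#' @export
read_xdf <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 4L), xdf_magic)) {
    stop("format error: not an XDF file")
  }
  streams <- list()
  repeat {
    len <- read_varlen_con(con)
    if (is.null(len)) break
    tag <- readBin(con, "integer", 1L, size = 2, signed = FALSE,
                   endian = "little")
    body <- readBin(con, "raw", len - 2L)
    if (tag == 2L) {  # StreamHeader
      id <- as.character(raw_uint(body[1:4]))
      info <- xml2::read_xml(rawToChar(body[-(1:4)]))
      labels <- xml2::xml_text(
        xml2::xml_find_all(info, ".//desc/channels/channel/label"))
      streams[[id]] <- list(
        info = list(
          name = xml2::xml_text(xml2::xml_find_first(info, "./name")),
          type = xml2::xml_text(xml2::xml_find_first(info, "./type")),
          channel_count = as.integer(
            xml2::xml_text(xml2::xml_find_first(info, "./channel_count"))),
          nominal_srate = as.numeric(
            xml2::xml_text(xml2::xml_find_first(info, "./nominal_srate"))),
          channel_format = xml2::xml_text(
            xml2::xml_find_first(info, "./channel_format")),
          channel_labels = if (length(labels)) labels else NULL
        ),
        timestamps = list(), values = list()
      )
    } else if (tag == 3L) {  # Samples
      id <- as.character(raw_uint(body[1:4]))
      st <- streams[[id]]
      if (is.null(st)) stop("format error: samples for unknown stream")
      parsed <- parse_samples_body(body[-(1:4)], st$info)
      k <- length(st$timestamps) + 1L
      streams[[id]]$timestamps[[k]] <- parsed$timestamps
      streams[[id]]$values[[k]] <- parsed$values
    }
    # tags 1 (FileHeader), 4 (ClockOffset), 5 (Boundary), 6 (Footer): skip
  }
  lapply(unname(streams), function(st) {
    ts <- unlist(st$timestamps, use.names = FALSE)
    # fill deduced timestamps (flag 0) from the nominal rate
    if (anyNA(ts)) {
      dt <- if (st$info$nominal_srate > 0) 1 / st$info$nominal_srate else 0
      for (i in which(is.na(ts))) {
        ts[i] <- if (i == 1L) 0 else ts[i - 1L] + dt
      }
    }
    out <- list(info = st$info, timestamps = ts)
    if (st$info$channel_format == "string") {
      out$labels <- unlist(st$values, use.names = FALSE)
    } else {
      out$data <- do.call(rbind, st$values)
    }
    out
  })
}

# parse the per-sample payload of one Samples chunk body (stream id removed)
parse_samples_body <- function(body, info) {
  pos <- 1L
  take <- function(k) {
    out <- body[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  nb <- as.integer(body[pos]); pos <- pos + 1L
  n <- raw_uint(take(nb))
  ch <- info$channel_count
  fmt <- info$channel_format
  vsize <- switch(fmt, double64 = 8L, float32 = 4L, int32 = 4L,
                  int16 = 2L, int8 = 1L, string = NA_integer_,
                  stop("format error: unsupported channel format ", fmt))
  ts <- rep(NA_real_, n)
  if (fmt == "string") {
    vals <- character(n)
    for (i in seq_len(n)) {
      tsb <- as.integer(body[pos]); pos <- pos + 1L
      if (tsb == 8L) {
        ts[i] <- readBin(take(8L), "double", 1L, size = 8, endian = "little")
      }
      slen <- {
        snb <- as.integer(body[pos]); pos <- pos + 1L
        raw_uint(take(snb))
      }
      vals[i] <- rawToChar(take(slen))
    }
    return(list(timestamps = ts, values = vals))
  }
  # fast path: uniform timestamp flags let us deblock the payload
  stride <- 1L + 8L + vsize * ch
  flags_all8 <- length(body) - pos + 1L == n * stride &&
    all(body[pos + (seq_len(n) - 1L) * stride] == as.raw(8L))
  if (flags_all8) {
    m <- matrix(body[pos:(pos + n * stride - 1L)], nrow = stride)
    ts <- readBin(as.vector(m[2:9, , drop = FALSE]), "double", n,
                  size = 8, endian = "little")
    vals <- read_values(as.vector(m[-(1:9), , drop = FALSE]), fmt, n * ch)
  } else {
    vals <- numeric(n * ch)
    for (i in seq_len(n)) {
      tsb <- as.integer(body[pos]); pos <- pos + 1L
      if (tsb == 8L) {
        ts[i] <- readBin(take(8L), "double", 1L, size = 8, endian = "little")
      }
      vals[(i - 1L) * ch + seq_len(ch)] <-
        read_values(take(vsize * ch), fmt, ch)
    }
  }
  list(timestamps = ts, values = matrix(vals, ncol = ch, byrow = TRUE))
}

read_values <- function(bytes, fmt, n) {
  switch(fmt,
    double64 = readBin(bytes, "double", n, size = 8, endian = "little"),
    float32 = readBin(bytes, "double", n, size = 4, endian = "little"),
    int32 = as.numeric(readBin(bytes, "integer", n, size = 4,
                               endian = "little")),
    int16 = as.numeric(readBin(bytes, "integer", n, size = 2,
                               endian = "little")),
    int8 = as.numeric(readBin(bytes, "integer", n, size = 1)),
    stop("format error: unsupported channel format ", fmt))
}
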