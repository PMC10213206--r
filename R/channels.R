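# Channel containers and the two-column delimited on-disk format.

#' Construct a single-channel recording
#'
#' A `channel_recording` holds a uniformly sampled series on the channel's own
#' device clock: sample `k` (1-based) lies at `t0 + (k - 1) / fs` seconds.
#' `timing_events` are the shared synchronization pulses expressed in this
#' channel's clock; they are the only cross-channel timing reference.
#'
#' @param name Channel name (e.g. `"acc_x"`, `"tono"`, `"ppg"`, `"abp"`).
#' @param fs Sampling rate in Hz.
#' @param samples Numeric sample vector.
#' @param units Unit string (e.g. `"mG"`, `"mmHg"`, `"au"`, `"m/s"`).
#' @param t0 Device-clock time of the first sample, seconds.
#' @param timing_events Strictly increasing event times, device clock, seconds.
#' @return An object of class `channel_recording`.
#' @export
channel_recording <- function(name, fs, samples, units = "au", t0 = 0,
                              timing_events = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1, fs > 0,
            is.numeric(samples), all(is.finite(samples)))
  if (length(timing_events) > 1 && any(diff(timing_events) <= 0))
    stop("timing_events must be strictly increasing")
  structure(list(name = name, fs = as.numeric(fs),
                 samples = as.numeric(samples), units = units,
                 t0 = as.numeric(t0),
                 timing_events = as.numeric(timing_events)),
            class = "channel_recording")
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("<channel_recording> %s: %d samples @ %g Hz [%s], t0 = %.3f s, %d timing events\n",
              x$name, length(x$samples), x$fs, x$units, x$t0,
              length(x$timing_events)))
  invisible(x)
}

# Device-clock sample times of a channel.
channel_times <- function(ch) ch$t0 + (seq_along(ch$samples) - 1) / ch$fs

#' Write a channel recording to the delimited text format
#'
#' The format is two tab-separated numeric columns (`time_s`, `value`) preceded
#' by a header line `# channel=<name> fs=<Hz> units=<u> t0=<s>` and, when
#' timing events exist, a second line `# events=<comma-separated seconds>`.
#'
#' @param ch A [channel_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(ch, path) {
  stopifnot(inherits(ch, "channel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel=%s fs=%.10g units=%s t0=%.10g",
                     ch$name, ch$fs, ch$units, ch$t0), con)
  if (length(ch$timing_events))
    writeLines(paste0("# events=",
                      paste(sprintf("%.9g", ch$timing_events), collapse = ",")),
               con)
  writeLines(sprintf("%.9f\t%.9g", channel_times(ch), ch$samples), con)
  invisible(path)
}

#' Read a channel recording from the delimited text format
#'
#' Malformed data rows (wrong field count or non-numeric fields) are dropped
#' with a warning reporting their count. The time column must be strictly
#' increasing; the sampling rate is taken from the header.
#'
#' @param path Path to a file written by [write_channel()].
#' @return A [channel_recording()].
#' @export
read_channel <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# *channel=", lines[1]))
    stop("format error: missing '# channel=...' header in ", path)
  hdr <- lines[1]
  get_field <- function(key, required = TRUE) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1]]
    if (length(m) < 2) {
      if (required) stop("format error: header lacks '", key, "=' in ", path)
      return(NA_character_)
    }
    m[2]
  }
  name <- get_field("channel")
  fs <- as.numeric(get_field("fs"))
  units <- get_field("units")
  t0 <- as.numeric(get_field("t0", required = FALSE))
  if (is.na(t0)) t0 <- 0
  if (!is.finite(fs) || fs <= 0) stop("format error: bad fs in header of ", path)
  events <- numeric(0)
  body_start <- 2L
  if (length(lines) >= 2 && grepl("^# *events=", lines[2])) {
    events <- as.numeric(strsplit(sub("^# *events=", "", lines[2]), ",")[[1]])
    body_start <- 3L
  }
  body <- lines[seq.int(body_start, length.out = max(0L, length(lines) - body_start + 1L))]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "[\t ]+")
  ok <- lengths(parts) == 2L
  tv <- suppressWarnings(vapply(parts, function(p)
    if (length(p) == 2L) as.numeric(p) else c(NA_real_, NA_real_), numeric(2)))
  ok <- ok & is.finite(tv[1, ]) & is.finite(tv[2, ])
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(sprintf("%d malformed row(s) dropped while reading %s", n_bad, path))
  times <- tv[1, ok]
  vals <- tv[2, ok]
  if (!length(vals)) stop("format error: no valid data rows in ", path)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("format error: non-monotone time column in ", path)
  channel_recording(name, fs, vals, units = units, t0 = times[1],
                    timing_events = events)
}
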