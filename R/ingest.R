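# Clock alignment of multi-rate channels via the shared timing signal, and
# anti-aliased resampling to a common rate.

#' Estimate per-channel clock offsets (and drift) from timing events
#'
#' The first channel's clock is the reference. For each other channel the
#' offset is the mean difference of matched timing-event times; with three or
#' more events a linear clock drift is also estimated by least squares, so the
#' mapping from a channel's clock to the reference clock is
#' `t_ref = (t - intercept) / slope`.
#'
#' @param channels List of [channel_recording()]s, each with >= 2 timing
#'   events; events must correspond one-to-one across channels.
#' @return A list with `offset` (named seconds, mean event mismatch versus the
#'   reference) and `clock` (named list of `c(slope, intercept)` mappings).
#' @export
estimate_offsets <- function(channels) {
  stopifnot(length(channels) >= 1)
  nm <- vapply(channels, function(ch) ch$name, character(1))
  ev_ref <- channels[[1]]$timing_events
  if (length(ev_ref) < 2)
    stop("synchronization error: reference channel has fewer than 2 timing events")
  offset <- numeric(length(channels))
  clock <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    ev <- channels[[i]]$timing_events
    if (length(ev) != length(ev_ref))
      stop("synchronization error: timing event count mismatch (",
           nm[i], ": ", length(ev), " vs ", length(ev_ref), ")")
    offset[i] <- mean(ev - ev_ref)
    if (length(ev) >= 3) {
      fit <- stats::lm.fit(cbind(1, ev_ref), ev)
      clock[[i]] <- c(slope = unname(fit$coefficients[2]),
                      intercept = unname(fit$coefficients[1]))
    } else {
      clock[[i]] <- c(slope = 1, intercept = offset[i])
    }
  }
  names(offset) <- nm
  names(clock) <- nm
  list(offset = offset, clock = clock)
}

#' Resample aligned channels onto a common time base
#'
#' Each channel's sample times are mapped to the reference clock using the
#' offsets/drift from [estimate_offsets()], low-pass filtered (zero-phase
#' Butterworth at 90% of the target Nyquist) when the native rate exceeds the
#' target, and interpolated with a cubic spline onto a shared uniform grid
#' spanning the overlap of all channels. Edges beyond a channel's support are
#' dropped, not padded.
#'
#' @param channels List of [channel_recording()]s.
#' @param offsets Result of [estimate_offsets()] on the same channels, or
#'   `NULL` to estimate here.
#' @param fs_common Target rate in Hz (>= 100; default 500, preserving the
#'   10-40 Hz BCG band with ample margin).
#' @return An object of class `synced_recording`: `fs`, `time` (reference
#'   clock), `channels` (named list of equal-length series), `offset`, and
#'   `residual` (worst timing-event mismatch after alignment, seconds).
#' @export
resample_common <- function(channels, offsets = NULL, fs_common = 500) {
  stopifnot(fs_common >= 100)
  if (is.null(offsets)) offsets <- estimate_offsets(channels)
  nm <- vapply(channels, function(ch) ch$name, character(1))
  to_ref <- function(i, t) {
    cl <- offsets$clock[[nm[i]]]
    (t - cl["intercept"]) / cl["slope"]
  }
  starts <- ends <- numeric(length(channels))
  for (i in seq_along(channels)) {
    tt <- to_ref(i, range(channel_times(channels[[i]])))
    starts[i] <- tt[1]; ends[i] <- tt[2]
  }
  t_start <- ceiling(max(starts) * fs_common) / fs_common
  t_end <- floor(min(ends) * fs_common) / fs_common
  if (t_end - t_start <= 0)
    stop("synchronization error: channels have no common time overlap")
  grid <- seq(t_start, t_end, by = 1 / fs_common)
  out <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    x <- ch$samples
    if (ch$fs > fs_common) {
      bf <- signal::butter(6, 0.9 * fs_common / ch$fs, type = "low")
      x <- signal::filtfilt(bf, x)
    }
    t_ref <- to_ref(i, channel_times(ch))
    out[[i]] <- stats::spline(t_ref, x, xout = grid, method = "fmm")$y
  }
  names(out) <- nm
  # alignment residual: worst corrected event mismatch against the reference
  ev_ref <- channels[[1]]$timing_events
  resid <- 0
  for (i in seq_along(channels)) {
    ev <- to_ref(i, channels[[i]]$timing_events)
    if (length(ev) && length(ev) == length(ev_ref))
      resid <- max(resid, max(abs(ev - ev_ref)))
  }
  structure(list(fs = fs_common, time = grid, channels = out,
                 offset = offsets$offset, residual = resid),
            class = "synced_recording")
}

#' @export
print.synced_recording <- function(x, ...) {
  cat(sprintf("<synced_recording> %d channels @ %g Hz, %.1f s (%d samples), worst event residual %.2g ms\n",
              length(x$channels), x$fs, diff(range(x$time)),
              length(x$time), 1000 * x$residual))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synced recording as one multi-column delimited file
#'
#' @param sync A `synced_recording`.
#' @param path Output path; tab-separated with a `time_s` column.
#' @return `path`, invisibly.
#' @export
write_synced <- function(sync, path) {
  df <- data.frame(time_s = sync$time)
  for (nm in names(sync$channels)) df[[nm]] <- sync$channels[[nm]]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
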