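# Tonometry-gated beat segmentation and ensemble averaging.

#' Detect tonometry systolic peaks
#'
#' Local maxima whose topographic prominence reaches 40% of the local (rolling
#' median) beat amplitude, with a refractory period of one minimum beat
#' interval (`60 / hr_bounds[2]`). The local beat amplitude is the rolling
#' median (5 blocks) of the strongest candidate prominence in consecutive 2 s
#' blocks. When two candidates fall within the refractory period the larger
#' prominence wins; exact ties go to the earlier sample.
#'
#' @param x Tonometry series (common-rate).
#' @param fs Sampling rate, Hz.
#' @param hr_bounds_bpm Plausible heart-rate range, beats/min.
#' @return Peak times in seconds (relative to the first sample).
#' @export
detect_systolic_peaks <- function(x, fs, hr_bounds_bpm = c(40, 220)) {
  stopifnot(fs > 0, length(x) >= 5 * fs)
  ext <- find_extrema(x)
  if (length(ext$maxima) < 3)
    stop("segmentation failure: fewer than 3 candidate peaks")
  prom <- peak_prominence(x, ext$maxima)
  keep0 <- prom > 1e-12
  cand <- ext$maxima[keep0]
  prom <- prom[keep0]
  if (length(cand) < 3) stop("segmentation failure: fewer than 3 candidate peaks")
  # rolling local beat-amplitude estimate from 2 s blocks
  block <- floor((cand - 1) / (2 * fs))
  block_amp <- tapply(prom, block, max)
  k <- length(block_amp)
  roll <- vapply(seq_len(k), function(i)
    stats::median(block_amp[max(1, i - 2):min(k, i + 2)]), numeric(1))
  amp_at <- roll[match(block, as.integer(names(block_amp)))]
  sel <- prom >= 0.4 * amp_at
  cand <- cand[sel]; prom <- prom[sel]
  if (length(cand) < 3) stop("segmentation failure: fewer than 3 peaks found")
  # refractory enforcement, larger prominence first, ties to earlier sample
  refr <- 60 / hr_bounds_bpm[2] * fs
  ord <- order(-prom, cand)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(cand[i] - accepted) >= refr))
      accepted <- c(accepted, cand[i])
  }
  accepted <- sort(accepted)
  if (length(accepted) < 3) stop("segmentation failure: fewer than 3 peaks found")
  (accepted - 1) / fs
}

#' Cut fixed-length beat segments around reference peaks
#'
#' Segments span `pre_ms` before to `post_ms` after each peak, inclusive of
#' both endpoints (`round((pre + post) / 1000 * fs) + 1` samples, so 401
#' samples for the default 400/400 ms window at 500 Hz). Peaks whose window
#' crosses a record boundary are skipped and counted.
#'
#' @param x Series to segment (common-rate).
#' @param fs Sampling rate, Hz.
#' @param peak_times_s Reference peak times in seconds.
#' @param pre_ms,post_ms Window before/after the peak, ms.
#' @return A beats-by-samples matrix with attributes `center` (1-based index
#'   of the peak sample), `fs`, `peak_times_s` (retained peaks) and
#'   `n_skipped`.
#' @export
segment_beats <- function(x, fs, peak_times_s, pre_ms = 400, post_ms = 400) {
  stopifnot(fs > 0)
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  centers <- round(peak_times_s * fs) + 1L
  ok <- centers - npre >= 1L & centers + npost <= length(x)
  if (!any(ok)) stop("segmentation failure: all peak windows cross the record boundary")
  idx <- outer(centers[ok], (-npre):npost, `+`)
  seg <- matrix(x[idx], nrow = sum(ok))
  attr(seg, "center") <- npre + 1L
  attr(seg, "fs") <- fs
  attr(seg, "peak_times_s") <- peak_times_s[ok]
  attr(seg, "n_skipped") <- sum(!ok)
  seg
}

#' Select the head-foot accelerometer axis
#'
#' Returns the index of the axis whose ensemble average carries the most
#' 10-30 Hz band power (Welch estimate), i.e. the axis aligned with the
#' head-foot BCG. With no distinguishable band energy (relative spread of the
#' axis energies below 1e-6) the configured default axis is returned.
#'
#' @param acc List (or 3 columns) of axis series at a common rate.
#' @param fs Sampling rate, Hz.
#' @param peak_times_s Tonometry peak times for segmentation.
#' @param f_band Analysis band, Hz.
#' @param default_axis Tie-break axis index.
#' @return Integer axis index (1-based).
#' @export
select_headfoot_axis <- function(acc, fs, peak_times_s, f_band = c(10, 30),
                                 default_axis = 1L) {
  if (is.matrix(acc)) acc <- lapply(seq_len(ncol(acc)), function(j) acc[, j])
  stopifnot(length(acc) >= 2)
  energy <- vapply(acc, function(x) {
    ens <- ensemble_average(segment_beats(x, fs, peak_times_s))
    w <- welch_psd(ens$average, fs, nperseg = min(length(ens$average), 256L))
    in_band <- w$freq >= f_band[1] & w$freq <= f_band[2]
    sum(w$psd[in_band])
  }, numeric(1))
  if (max(energy) <= 0 ||
      (max(energy) - min(energy)) <= 1e-6 * max(energy)) return(default_axis)
  which.max(energy)
}

#' Ensemble average with robust artifact rejection
#'
#' Segments whose RMS exceeds `median + k * MAD` of the segment RMS values are
#' excluded before averaging (set `rejection_k = Inf` to disable and average
#' every beat).
#'
#' @param segments Beats-by-samples matrix from [segment_beats()].
#' @param rejection_k MAD multiplier for the RMS rejection rule.
#' @return A list with `average`, `n_used`, `n_rejected`, `used` (logical),
#'   and the segment matrix attributes (`center`, `fs`).
#' @export
ensemble_average <- function(segments, rejection_k = 3.0) {
  stopifnot(is.matrix(segments), nrow(segments) >= 1)
  rms <- sqrt(rowMeans(segments^2))
  if (is.finite(rejection_k) && nrow(segments) >= 3) {
    thr <- stats::median(rms) + rejection_k * stats::mad(rms)
    used <- rms <= thr
    if (!any(used)) used <- rep(TRUE, length(rms))
  } else {
    used <- rep(TRUE, length(rms))
  }
  avg <- colMeans(segments[used, , drop = FALSE])
  list(average = avg, n_used = sum(used), n_rejected = sum(!used),
       used = used, center = attr(segments, "center"),
       fs = attr(segments, "fs"))
}
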