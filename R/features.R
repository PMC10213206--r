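# Physiological feature extraction from ensemble averages: AVO onset in the
# EEMD-filtered BCG, PPG foot by intersecting tangents, PTT, systolic BCG
# amplitude, blood-pressure metrics, heart rate, Doppler VTI and stroke
# volume.

#' Detect the aortic-valve-opening onset in the filtered BCG
#'
#' The systolic-complex onset is the peak immediately preceding the first
#' major negative deflection of the EEMD-filtered BCG segment: "major" is
#' quantified as a local minimum whose negative prominence reaches
#' `min_rel_prominence` (default 50%) of the largest negative prominence in
#' the search window; the returned time is the local maximum immediately
#' before that minimum (ties to the earlier sample).
#'
#' @param x Filtered BCG segment (selected IMF of the ensemble average).
#' @param fs Sampling rate, Hz.
#' @param search_window Two-element window (seconds within the segment) to
#'   search, typically from the segment start to the tonometry peak sample.
#' @param min_rel_prominence Relative negative-prominence threshold defining a
#'   "major" deflection.
#' @param peak_guard The preceding maximum must itself have (positive)
#'   prominence of at least this fraction of the largest negative prominence,
#'   so residual decomposition-noise wiggles riding the downslope are not
#'   mistaken for the onset peak.
#' @return Onset time in seconds within the segment, or `NA_real_` (feature
#'   failure) when no qualifying minimum or preceding maximum exists.
#' @export
detect_avo_onset <- function(x, fs, search_window = NULL,
                             min_rel_prominence = 0.5, peak_guard = 0.05) {
  n <- length(x)
  if (is.null(search_window)) search_window <- c(0, (n - 1) / fs)
  lo <- max(1L, floor(search_window[1] * fs) + 1L)
  hi <- min(n, ceiling(search_window[2] * fs) + 1L)
  if (hi - lo < 4) return(NA_real_)
  seg <- x[lo:hi]
  ext <- find_extrema(seg)
  if (!length(ext$minima) || !length(ext$maxima)) return(NA_real_)
  neg_prom <- peak_prominence(-seg, ext$minima)
  if (max(neg_prom) <= 0) return(NA_real_)
  qual <- ext$minima[neg_prom >= min_rel_prominence * max(neg_prom)]
  if (!length(qual)) return(NA_real_)
  first_min <- min(qual)
  prev_max <- ext$maxima[ext$maxima < first_min]
  if (!length(prev_max)) return(NA_real_)
  pos_prom <- peak_prominence(seg, prev_max)
  prev_max <- prev_max[pos_prom >= peak_guard * max(neg_prom)]
  if (!length(prev_max)) return(NA_real_)
  (lo - 1L + max(prev_max) - 1L) / fs
}

#' Pulse foot by the intersecting-tangents method
#'
#' The foot is the abscissa where the tangent at the steepest point of the
#' systolic upstroke (first derivative from a 5-point quadratic
#' Savitzky-Golay filter) crosses the horizontal line through the
#' pre-upstroke minimum.
#'
#' @param x Pulse segment (e.g. ensemble-averaged PPG).
#' @param fs Sampling rate, Hz.
#' @param search_window Two-element window (seconds within the segment) that
#'   contains the diastolic minimum and the upstroke.
#' @return Foot time in seconds within the segment, or `NA_real_` when the
#'   upstroke slope is not positive.
#' @export
foot_intersecting_tangents <- function(x, fs, search_window = NULL) {
  n <- length(x)
  if (is.null(search_window)) search_window <- c(0, (n - 1) / fs)
  lo <- max(1L, floor(search_window[1] * fs) + 1L)
  hi <- min(n, ceiling(search_window[2] * fs) + 1L)
  if (hi - lo < 6) return(NA_real_)
  seg <- x[lo:hi]
  deriv <- signal::sgolayfilt(seg, p = 2, n = 5, m = 1, ts = 1 / fs)
  # exclude the smoothing edge samples from the slope search
  core <- 3:(length(seg) - 2)
  imax <- core[which.max(deriv[core])]
  slope <- deriv[imax]
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  baseline <- min(seg[1:imax])
  t_star <- (imax - 1) / fs
  foot <- t_star - (seg[imax] - baseline) / slope
  foot <- max(foot, 0)
  (lo - 1L) / fs + foot
}

#' Pulse transit time from AVO onset and PPG foot
#'
#' @param avo_onset_s Systolic-complex onset time, seconds (segment clock).
#' @param ppg_foot_s Foot time of the following PPG systole, seconds (same
#'   clock).
#' @return PTT in ms, or `NA_real_` (feature failure) when the difference is
#'   not positive.
#' @export
compute_ptt <- function(avo_onset_s, ppg_foot_s) {
  if (is.na(avo_onset_s) || is.na(ppg_foot_s)) return(NA_real_)
  d <- (ppg_foot_s - avo_onset_s) * 1000
  if (d <= 0) return(NA_real_)
  d
}

#' Systolic BCG amplitude
#'
#' Topographic prominence (measured within the whole segment) of the largest
#' local maximum within `window_ms` after the systolic-complex onset.
#'
#' @param x Filtered BCG segment.
#' @param fs Sampling rate, Hz.
#' @param avo_onset_s Onset time within the segment, seconds.
#' @param window_ms Search window after the onset, ms.
#' @return Amplitude (prominence, signal units), or `NA_real_` when no local
#'   maximum lies in the window.
#' @export
bcg_amplitude <- function(x, fs, avo_onset_s, window_ms = 120) {
  if (is.na(avo_onset_s)) return(NA_real_)
  lo <- floor(avo_onset_s * fs) + 1L
  hi <- min(length(x), ceiling((avo_onset_s + window_ms / 1000) * fs) + 1L)
  ext <- find_extrema(x)
  peaks <- ext$maxima[ext$maxima >= lo & ext$maxima <= hi]
  if (!length(peaks)) return(NA_real_)
  best <- peaks[which.max(x[peaks])]
  peak_prominence(x, best)
}

#' Blood-pressure metrics from the arterial-line waveform
#'
#' Beats are delimited peak-to-peak by the reference peak times; per-beat
#' maxima (SBP), minima (DBP) and trapezoid time-averages (MAP, the
#' arterial-line monitor convention) are averaged over the record.
#'
#' @param x ABP series, mmHg.
#' @param fs Sampling rate, Hz.
#' @param peak_times_s Reference (tonometry or ABP) peak times, seconds.
#' @return A list with `sbp`, `dbp`, `map` (mmHg) and `quality_flag`
#'   (non-physiological values or a constant signal).
#' @export
bp_metrics <- function(x, fs, peak_times_s) {
  if (length(peak_times_s) < 4)
    stop("feature failure: fewer than 3 complete beats")
  idx <- round(peak_times_s * fs) + 1L
  idx <- idx[idx >= 1 & idx <= length(x)]
  sbp <- dbp <- mp <- numeric(0)
  for (b in seq_len(length(idx) - 1L)) {
    seg <- x[idx[b]:(idx[b + 1L] - 1L)]
    if (length(seg) < 3) next
    sbp <- c(sbp, max(seg))
    dbp <- c(dbp, min(seg))
    # MAP over the full inclusive peak-to-peak span
    full <- x[idx[b]:idx[b + 1L]]
    mp <- c(mp, trapz_int(full, 1 / fs) / ((length(full) - 1) / fs))
  }
  if (length(sbp) < 3) stop("feature failure: fewer than 3 complete beats")
  out <- list(sbp = mean(sbp), dbp = mean(dbp), map = mean(mp))
  out$quality_flag <- out$sbp > 300 || out$dbp < 10 ||
    (out$sbp - out$dbp) < 1e-6 * max(1, abs(out$sbp))
  out
}

#' Heart rate from reference peak intervals
#'
#' `60 / median(inter-peak interval)`, robust to isolated missed or spurious
#' beats.
#'
#' @param peak_times_s Peak times, seconds (>= 3 peaks).
#' @return Heart rate in beats/min.
#' @export
heart_rate <- function(peak_times_s) {
  stopifnot(length(peak_times_s) >= 3)
  60 / stats::median(diff(peak_times_s))
}

#' Doppler velocity-time integral
#'
#' Trapezoid integral of the LVOT velocity (m/s) from ejection onset to valve
#' closure, in cm.
#'
#' @param v Velocity series, m/s.
#' @param fs Sampling rate, Hz.
#' @param avo_time_s,closure_time_s Integration bounds, seconds (series
#'   clock).
#' @return VTI in cm, or an error for a negative integral.
#' @export
doppler_vti <- function(v, fs, avo_time_s, closure_time_s) {
  stopifnot(closure_time_s > avo_time_s)
  lo <- max(1L, floor(avo_time_s * fs) + 1L)
  hi <- min(length(v), ceiling(closure_time_s * fs) + 1L)
  vti <- trapz_int(v[lo:hi], 1 / fs) * 100
  if (vti < 0) stop("feature failure: negative velocity-time integral")
  vti
}

#' Stroke volume from VTI and LVOT diameter
#'
#' `SV = VTI x pi (d/2)^2` (LVOT cross-sectional area). The diameter variant
#' (`SV = VTI x d`), which some reports use, is available via
#' `use_area = FALSE`.
#'
#' @param vti_cm Velocity-time integral, cm.
#' @param lvot_diameter_cm LVOT diameter, cm (1.5-3.0).
#' @param use_area Multiply by the LVOT area (default) rather than diameter.
#' @return Stroke volume in mL.
#' @export
stroke_volume <- function(vti_cm, lvot_diameter_cm, use_area = TRUE) {
  if (lvot_diameter_cm < 1.5 || lvot_diameter_cm > 3.0)
    stop("configuration error: LVOT diameter outside 1.5-3.0 cm")
  if (use_area) vti_cm * pi * (lvot_diameter_cm / 2)^2
  else vti_cm * lvot_diameter_cm
}
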