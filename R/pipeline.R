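# End-to-end orchestration: synchronize -> segment -> decompose -> extract
# features per condition, then the study-level statistical report.

#' Process one condition recording into beat features
#'
#' Runs the full measurement chain on one participant-condition: synchronize
#' and resample all channels to the common rate; detect tonometry systolic
#' peaks; cut +/-400 ms segments; select the head-foot accelerometer axis and
#' ensemble-average it; decompose the average with EEMD and select the
#' 10-30 Hz systolic IMF; locate the AVO onset (before the tonometry peak) and
#' the foot of the following PPG systole (after it, intersecting tangents);
#' derive PTT, systolic amplitude, SBP/DBP/MAP, HR, and - when an LVOT
#' channel is present - the ejection VTI and stroke volume from the
#' ensemble-averaged Doppler velocity.
#'
#' @param channels Named list of [channel_recording()]s; needs `tono`, `ppg`,
#'   `abp` and at least one `acc_*` axis; `lvot` and `ecg` are optional.
#' @param fs_common Common analysis rate, Hz.
#' @param lvot_diameter_cm LVOT diameter for stroke volume, cm.
#' @param n_ensembles,noise_sigma_ratio EEMD parameters.
#' @param seed Seed for the EEMD noise ensembles.
#' @param pre_ms,post_ms Segment window, ms.
#' @param rejection_k Ensemble artifact-rejection MAD multiplier.
#' @return One-row `data.frame` of beat features (`hr_bpm`, `sbp_mmHg`,
#'   `dbp_mmHg`, `map_mmHg`, `ptt_ms`, `amp_mg`, `vti_cm`, `sv_ml`,
#'   `avo_onset_s`, `ppg_foot_s`, `n_beats`, `n_used`, `flags`).
#' @export
process_condition <- function(channels, fs_common = 500,
                              lvot_diameter_cm = NULL,
                              n_ensembles = 200L, noise_sigma_ratio = 0.2,
                              seed = 1, pre_ms = 400, post_ms = 400,
                              rejection_k = 3.0) {
  flags <- character(0)
  sync <- resample_common(channels, fs_common = fs_common)
  fs <- sync$fs
  peaks <- detect_systolic_peaks(sync$channels$tono, fs)
  acc_names <- grep("^acc", names(sync$channels), value = TRUE)
  stopifnot(length(acc_names) >= 1, "ppg" %in% names(sync$channels),
            "abp" %in% names(sync$channels))
  axis <- if (length(acc_names) > 1)
    select_headfoot_axis(sync$channels[acc_names], fs, peaks)
  else 1L
  seg_acc <- segment_beats(sync$channels[[acc_names[axis]]], fs, peaks,
                           pre_ms, post_ms)
  ens_acc <- ensemble_average(seg_acc, rejection_k)
  imfset <- eemd(ens_acc$average, n_ensembles = n_ensembles,
                 noise_sigma_ratio = noise_sigma_ratio, seed = seed)
  imfset <- select_systolic_imf(imfset, fs)
  if (isTRUE(attr(imfset, "low_confidence")))
    flags <- c(flags, "low_confidence_imf")
  filtered <- filtered_bcg(imfset)
  center_s <- (ens_acc$center - 1) / fs
  onset <- detect_avo_onset(filtered, fs, search_window = c(0, center_s))
  ens_ppg <- ensemble_average(segment_beats(sync$channels$ppg, fs, peaks,
                                            pre_ms, post_ms), rejection_k)
  foot <- foot_intersecting_tangents(ens_ppg$average, fs,
                                     search_window = c(center_s,
                                                       (length(ens_ppg$average) - 1) / fs))
  ptt <- compute_ptt(onset, foot)
  amp <- bcg_amplitude(filtered, fs, onset)
  if (is.na(ptt)) flags <- c(flags, "ptt_failure")
  if (is.na(amp)) flags <- c(flags, "amp_failure")
  bp <- bp_metrics(sync$channels$abp, fs, peaks)
  if (bp$quality_flag) flags <- c(flags, "bp_quality")
  hr <- heart_rate(peaks)
  vti <- sv <- NA_real_
  if ("lvot" %in% names(sync$channels)) {
    ens_lvot <- ensemble_average(segment_beats(sync$channels$lvot, fs, peaks,
                                               pre_ms, post_ms), rejection_k)
    ej <- ejection_window(ens_lvot$average, fs)
    if (!is.null(ej)) {
      vti <- doppler_vti(ens_lvot$average, fs, ej[1], ej[2])
      if (!is.null(lvot_diameter_cm)) sv <- stroke_volume(vti, lvot_diameter_cm)
    } else flags <- c(flags, "vti_failure")
  }
  data.frame(hr_bpm = hr, sbp_mmHg = bp$sbp, dbp_mmHg = bp$dbp,
             map_mmHg = bp$map, ptt_ms = ptt, amp_mg = amp,
             vti_cm = vti, sv_ml = sv,
             avo_onset_s = onset, ppg_foot_s = foot,
             n_beats = length(peaks), n_used = ens_acc$n_used,
             flags = paste(flags, collapse = ";"))
}

# Contiguous ejection window (seconds) around the velocity maximum, delimited
# where the ensemble-averaged velocity falls below 2% of its peak.
ejection_window <- function(v, fs, threshold = 0.02) {
  if (max(v) <= 0) return(NULL)
  imax <- which.max(v)
  above <- v >= threshold * v[imax]
  lo <- imax
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- imax
  while (hi < length(v) && above[hi + 1]) hi <- hi + 1
  if (hi - lo < 3) return(NULL)
  c(lo - 1, hi - 1) / fs
}

#' Run the full cohort pipeline and statistical report
#'
#' Applies [process_condition()] to every participant-condition of a
#' generated (or loaded) cohort, then reproduces the study-level analyses:
#' a per-condition summary table (mean and SD of HR, SBP, DBP, MAP, PTT,
#' amplitude), paired Wilcoxon posture comparisons per load, Pearson
#' correlations of PTT with SBP and HR (per posture and pooled), and the
#' stroke-volume versus amplitude correlation with and without robust
#' Mahalanobis outlier exclusion (on z-scored values). Stage failures are
#' recorded per condition and the pipeline continues.
#'
#' @param cohort A cohort from [generate_cohort()] (or a directory path of
#'   channel files written by it).
#' @param fs_common,n_ensembles,noise_sigma_ratio,rejection_k Pipeline
#'   parameters, see [process_condition()].
#' @param seed Seed for the EEMD ensembles.
#' @return An object of class `wristbcg_report`: `features` (per
#'   participant-condition), `condition_summary`, `posture_tests`,
#'   `correlations`, `sv_amplitude`, `errors`.
#' @export
run_pipeline <- function(cohort, fs_common = 500, n_ensembles = 200L,
                         noise_sigma_ratio = 0.2, rejection_k = 3.0,
                         seed = 1) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  rows <- list()
  errors <- list()
  for (p in names(cohort$recordings)) {
    for (ci in names(cohort$recordings[[p]])) {
      rec <- cohort$recordings[[p]][[ci]]
      res <- tryCatch(
        process_condition(rec$channels, fs_common = fs_common,
                          lvot_diameter_cm = rec$lvot_diameter_cm,
                          n_ensembles = n_ensembles,
                          noise_sigma_ratio = noise_sigma_ratio,
                          rejection_k = rejection_k,
                          seed = derive_seed(seed, as.integer(p), as.integer(ci))),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <-
          data.frame(participant = as.integer(p), condition = as.integer(ci),
                     message = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant = as.integer(p),
                   posture = rec$params$posture,
                   load_w = rec$params$load_w), res)
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    stop("pipeline failure: no condition produced features")
  structure(list(features = features,
                 condition_summary = condition_summary(features),
                 posture_tests = posture_tests(features),
                 correlations = ptt_correlations(features),
                 sv_amplitude = sv_amplitude_correlation(features),
                 errors = if (length(errors)) do.call(rbind, errors) else NULL),
            class = "wristbcg_report")
}

# Mean +/- SD of the six study measures per posture-by-load condition.
condition_summary <- function(features) {
  measures <- c("hr_bpm", "sbp_mmHg", "dbp_mmHg", "map_mmHg", "ptt_ms", "amp_mg")
  key <- interaction(features$posture, features$load_w, drop = TRUE)
  out <- lapply(split(features, key), function(g) {
    row <- data.frame(posture = g$posture[1], load_w = g$load_w[1], n = nrow(g))
    for (m in measures) {
      row[[paste0(m, "_mean")]] <- mean(g[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(g[[m]], na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$posture, out$load_w), ]
  rownames(out) <- NULL
  out
}

# Paired Wilcoxon posture comparison per load for each measure.
posture_tests <- function(features,
                          measures = c("ptt_ms", "sbp_mmHg", "dbp_mmHg",
                                       "map_mmHg", "hr_bpm", "amp_mg")) {
  out <- list()
  for (load in sort(unique(features$load_w))) {
    sup <- features[features$posture == "supine" & features$load_w == load, ]
    sr <- features[features$posture == "semirecumbent" & features$load_w == load, ]
    common <- intersect(sup$participant, sr$participant)
    if (length(common) < 5) next
    for (m in measures) {
      ps <- paired_sample(common,
                          sup[[m]][match(common, sup$participant)],
                          sr[[m]][match(common, sr$participant)])
      if (length(ps$x) < 5) next
      tst <- wilcoxon_signed_rank(ps)
      out[[length(out) + 1L]] <- data.frame(
        load_w = load, measure = m, n = length(ps$x),
        n_excluded = ps$n_excluded_missing,
        statistic = tst$statistic, p_value = tst$p_value,
        method = tst$method,
        significant = tst$p_value < 0.05)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# PTT against SBP and HR, per posture and pooled.
ptt_correlations <- function(features) {
  groups <- list(supine = features[features$posture == "supine", ],
                 semirecumbent = features[features$posture == "semirecumbent", ],
                 all = features)
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (yv in c("sbp_mmHg", "hr_bpm")) {
      ok <- is.finite(d$ptt_ms) & is.finite(d[[yv]])
      rho <- if (sum(ok) >= 3) pearson(d$ptt_ms[ok], d[[yv]][ok]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(group = g, pair = paste0("ptt~", yv),
                                            n = sum(ok), rho = rho)
    }
  }
  do.call(rbind, out)
}

# SV vs amplitude correlation on z-scored values, with and without robust
# Mahalanobis outlier exclusion.
sv_amplitude_correlation <- function(features, alpha = 0.05, seed = 1) {
  ok <- is.finite(features$sv_ml) & is.finite(features$amp_mg)
  if (sum(ok) < 10)
    return(list(rho_all = NA_real_, rho_excluded = NA_real_, n = sum(ok),
                n_outliers = NA_integer_))
  z <- cbind(zscore(features$sv_ml[ok]), zscore(features$amp_mg[ok]))
  mask <- tryCatch(robust_mahalanobis_outliers(z, alpha = alpha, seed = seed),
                   error = function(e) rep(FALSE, nrow(z)))
  list(rho_all = pearson(z[, 1], z[, 2]),
       rho_excluded = if (sum(!mask) >= 3)
         pearson(z[!mask, 1], z[!mask, 2]) else NA_real_,
       n = nrow(z), n_outliers = sum(mask))
}

#' Read a cohort written by [generate_cohort()] back from disk
#'
#' @param dir Directory containing `participant_XX/condition_YY/*.tsv` and
#'   `ground_truth.tsv`.
#' @return A cohort list usable by [run_pipeline()] (without realized
#'   generator parameters; posture/load are recovered from the ground truth).
#' @export
read_cohort <- function(dir) {
  gt <- utils::read.table(file.path(dir, "ground_truth.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  recordings <- list()
  for (pd in sort(list.dirs(dir, recursive = FALSE))) {
    if (!grepl("participant_\\d+$", pd)) next
    p <- as.integer(sub(".*participant_", "", pd))
    pc <- list()
    for (cd in sort(list.dirs(pd, recursive = FALSE))) {
      ci <- as.integer(sub(".*condition_", "", cd))
      files <- list.files(cd, pattern = "\\.tsv$", full.names = TRUE)
      chans <- lapply(files, read_channel)
      names(chans) <- vapply(chans, function(ch) ch$name, character(1))
      sub_gt <- gt[gt$participant == p & gt$condition == ci, ]
      pc[[as.character(ci)]] <- list(
        channels = chans,
        params = list(posture = sub_gt$posture[1], load_w = sub_gt$load_w[1]),
        participant = p, condition = ci,
        lvot_diameter_cm = sub_gt$lvot_diameter_cm[1])
    }
    recordings[[as.character(p)]] <- pc
  }
  list(ground_truth = gt, recordings = recordings)
}

#' @export
print.wristbcg_report <- function(x, ...) {
  cat("<wristbcg_report>\n")
  cat(sprintf("  %d participant-conditions (%d failed)\n",
              nrow(x$features), if (is.null(x$errors)) 0L else nrow(x$errors)))
  cat("  condition summary (mean):\n")
  cs <- x$condition_summary
  print(cs[, c("posture", "load_w", "n", "hr_bpm_mean", "sbp_mmHg_mean",
               "ptt_ms_mean", "amp_mg_mean")], digits = 4)
  if (!is.null(x$posture_tests)) {
    pt <- x$posture_tests[x$posture_tests$measure == "ptt_ms", ]
    if (nrow(pt)) {
      cat("  PTT posture comparisons (Wilcoxon):\n")
      print(pt[, c("load_w", "n", "statistic", "p_value")], digits = 4)
    }
  }
  cat("  PTT correlations:\n")
  print(x$correlations, digits = 3)
  invisible(x)
}
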