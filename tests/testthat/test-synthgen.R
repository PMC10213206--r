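# Synthetic cohort generator: calibration, determinism, waveform conventions.

test_that("participant draws respect invariants, degenerate SDs and determinism", {
  spec <- cohort_spec(n_participants = 3, seed = 11)
  a <- draw_participant_params(spec, 2)
  b <- draw_participant_params(spec, 2)
  expect_identical(a, b)
  for (p in a) {
    expect_true(p$ptt_mean > 0 && p$ptt_mean < 60000 / p$hr_mean)
    expect_true(p$dbp_mean > 0 && p$dbp_mean < p$sbp_mean)
    expect_true(p$amp_mean > 0)
  }
  # supine rest PTT drawn around the published 286.2 +/- 25.2 population
  expect_true(is.finite(a[[1]]$ptt_mean))
  # all SDs zero -> realized params equal population means
  cond0 <- lapply(reference_conditions(), function(p) {
    p$hr_sd <- p$sbp_sd <- p$dbp_sd <- p$ptt_sd <- p$amp_sd <- 0
    p
  })
  spec0 <- cohort_spec(n_participants = 2, conditions = cond0, seed = 5)
  r0 <- draw_participant_params(spec0, 1)
  expect_equal(r0[[1]]$ptt_mean, 286.2)
  expect_equal(r0[[5]]$ptt_mean, 263.1)
  expect_equal(r0[[4]]$hr_mean, 144.0)
})

test_that("cohort-mean drawn PTT stays within 3 SE of the population mean", {
  spec <- cohort_spec(n_participants = 25, seed = 42)
  ptts <- vapply(1:25, function(p) draw_participant_params(spec, p)[[1]]$ptt_mean,
                 numeric(1))
  expect_lt(abs(mean(ptts) - 286.2), 3 * 25.2 / sqrt(25))
})

test_that("beat trains: zero jitter is exact, jittered counts match the rate", {
  p60 <- condition_params("supine", 0, 60, 0, 120, 0, 70, 0, 280, 0, 30, 0)
  r <- synth_beat_train(p60, 10, jitter_cv = 0, seed = 1)
  expect_equal(r, 1:9)
  p144 <- condition_params("supine", 150, 144, 0, 207.7, 0, 75, 0, 219.6, 0,
                           82.2, 0, pep_ms = 60, ejection_ms = 210)
  r2 <- synth_beat_train(p144, 120, jitter_cv = 0.03, seed = 2)
  n_exp <- (120 - 2) / (60 / 144)
  expect_lt(abs(length(r2) - n_exp), 4 * 0.03 * sqrt(n_exp) * 10 + 3)
  expect_lt(abs(sd(diff(r2)) / mean(diff(r2)) - 0.03), 0.015)
  # determinism
  expect_identical(r2, synth_beat_train(p144, 120, jitter_cv = 0.03, seed = 2))
})

test_that("BCG channel matches the closed-form atom and its conventions", {
  spec <- cohort_spec(n_participants = 1, duration_s = 10, seed = 1)
  params <- rest_params()
  beats <- data.frame(r_time_s = 2, avo_time_s = 2.09,
                      pulse_foot_time_s = 2.09 + 0.2862, true_ptt_ms = 286.2,
                      true_amp_mg = 29.5, true_sv_ml = 70,
                      true_sbp_mmHg = 145.3, true_dbp_mmHg = 71.8,
                      true_hr_bpm = 69)
  ch <- synth_bcg(beats, spec, params, noise = FALSE, artifact = FALSE,
                  diastolic = FALSE)
  t <- (seq_along(ch$samples) - 1) / ch$fs
  ref <- oracle_gabor_burst(t, 2.09 + 0.010, 29.5)
  # the generator only evaluates the atom within +/-6 sigma of its center
  win <- abs(t - 2.16) < 0.125
  expect_lt(max(abs(ch$samples[win] - ref[win])), 1e-9)
  # first positive peak convention: local max at avo + 10 ms within one sample
  pk <- t[which(diff(sign(diff(ch$samples))) == -2) + 1]
  pk <- pk[which.min(abs(pk - 2.100))]
  expect_lt(abs(pk - 2.100), 1 / ch$fs + 1e-9)
  # measured prominence of the main peak equals the amplitude parameter
  i_main <- which.max(ch$samples)
  expect_equal(peak_prominence_oracle(ch$samples, i_main), 29.5,
               tolerance = 1e-3)
  # zero amplitude -> all-zero channel
  beats0 <- beats; beats0$true_amp_mg <- 0
  ch0 <- synth_bcg(beats0, spec, params, noise = FALSE, artifact = FALSE)
  expect_true(all(ch0$samples == 0))
  # configuration error when the rate cannot carry the burst
  spec_bad <- spec; spec_bad$rates["acc"] <- 70
  expect_error(synth_bcg(beats, spec_bad, params), "configuration")
})

test_that("noise-only accelerometer channel recovers the configured density", {
  spec <- cohort_spec(n_participants = 1, duration_s = 60, seed = 3)
  params <- rest_params()
  beats <- wristbcg:::build_beats(params, spec, 4)
  beats$true_amp_mg <- 0
  ch <- synth_bcg(beats, spec, params, seed = 9, artifact = FALSE)
  w <- welch_psd(ch$samples, ch$fs, nperseg = 4096)
  lvl <- sqrt(mean(w$psd[w$freq >= 50 & w$freq <= 200]))
  expect_lt(abs(lvl - 0.22) / 0.22, 0.10)
})

test_that("noise-free burst train concentrates its power in 10-30 Hz", {
  spec <- cohort_spec(n_participants = 1, duration_s = 30, seed = 5)
  params <- rest_params()
  beats <- wristbcg:::build_beats(params, spec, 6)
  ch <- synth_bcg(beats, spec, params, noise = FALSE, artifact = FALSE)
  expect_gt(band_energy_fraction(ch$samples, ch$fs, 10, 30), 0.8)
})

test_that("pressure channels hit per-beat extremes, share peak times, and their feet obey the tangents oracle", {
  spec <- cohort_spec(n_participants = 1, duration_s = 20, seed = 6)
  params <- rest_params()
  beats <- wristbcg:::build_beats(params, spec, 7)
  pr <- synth_pressure_channels(beats, spec, params, noise = FALSE)
  abp <- pr$abp; tono <- pr$tono
  feet <- beats$avo_time_s + spec$radial_delay_s
  t_abp <- wristbcg:::channel_times(abp)
  t_tono <- wristbcg:::channel_times(tono)
  for (b in 2:(nrow(beats) - 1)) {
    in_beat <- t_abp >= feet[b] & t_abp < feet[b + 1]
    expect_lt(abs(max(abp$samples[in_beat]) - 145.3), 0.3)
    expect_lt(abs(min(abp$samples[in_beat]) - 71.8), 0.3)
    # argmax of tono and abp for the same beat at identical times
    in_tono <- t_tono >= feet[b] & t_tono < feet[b + 1]
    t_pk_abp <- t_abp[in_beat][which.max(abp$samples[in_beat])]
    t_pk_tono <- t_tono[in_tono][which.max(tono$samples[in_tono])]
    expect_lt(abs(t_pk_abp - t_pk_tono), 1 / 125 + 1 / 200)
    # intersecting-tangents oracle on the noiseless ABP recovers the radial
    # foot within one sample at 125 Hz
    win <- t_abp >= feet[b] - 0.3 & t_abp <= feet[b] + 0.12
    foot_hat <- oracle_tangent_foot(t_abp[win], abp$samples[win])
    expect_lt(abs(foot_hat - feet[b]), 1 / 125)
  }
  expect_error(
    synth_pressure_channels(beats[c(2, 1), ], spec, params),
    "non-increasing")
})

test_that("Doppler half-sine ejection: analytic VTI, linear SV scaling, conservation", {
  spec <- cohort_spec(n_participants = 1, duration_s = 20, seed = 8)
  params <- rest_params()
  params$sv_ml <- 80; params$ejection_ms <- 250; params$lvot_diameter_cm <- 2.2
  beats <- wristbcg:::build_beats(params, spec, 9)
  ch <- synth_doppler(beats, spec = spec, params = params)
  area <- pi * 1.1^2
  v_peak_expected <- 80 * pi / (200 * 0.25 * area)
  expect_equal(max(ch$samples), v_peak_expected, tolerance = 1e-3)
  # VTI conservation per beat: trapezoid integral x area within 1%
  fs <- ch$fs
  for (b in seq_len(min(5, nrow(beats)))) {
    vti <- doppler_vti(ch$samples, fs, beats$avo_time_s[b],
                       beats$avo_time_s[b] + 0.25)
    expect_lt(abs(vti * area - 80) / 80, 0.01)
  }
  # doubling SV doubles the peak velocity
  params2 <- params; params2$sv_ml <- 160
  ch2 <- synth_doppler(beats, spec = spec, params = params2)
  expect_equal(max(ch2$samples) / max(ch$samples), 2, tolerance = 1e-6)
  # implausible configuration rejected
  params3 <- params; params3$sv_ml <- 600
  expect_error(synth_doppler(beats, spec = spec, params = params3),
               "implausible")
})

test_that("cohort assembly: structure, PAT identity, byte-identical regeneration", {
  spec <- cohort_spec(n_participants = 2, duration_s = 20, seed = 13)
  coh <- generate_cohort(spec)
  expect_length(coh$recordings, 2)
  expect_length(coh$recordings[["1"]], 8)
  expect_named(coh$recordings[["1"]][["3"]]$channels,
               c("acc_x", "acc_y", "acc_z", "tono", "abp", "ppg", "lvot", "ecg"))
  gt <- coh$ground_truth
  # PAT identity: pulse_foot - r_time = pep + ptt to machine precision
  pep_s <- vapply(seq_len(nrow(gt)), function(i) {
    ci <- which(vapply(spec$conditions, function(cc)
      cc$posture == gt$posture[i] && cc$load_w == gt$load_w[i], logical(1)))
    spec$conditions[[ci]]$pep_ms / 1000
  }, numeric(1))
  expect_lt(max(abs((gt$pulse_foot_time_s - gt$r_time_s) -
                    (pep_s + gt$true_ptt_ms / 1000))), 1e-9)
  expect_true(all(diff(gt$r_time_s[gt$participant == 1 & gt$load_w == 0 &
                                   gt$posture == "supine"]) > 0))
  # written bundle: 8 channel files per condition + annotation table,
  # byte-identical on regeneration
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  spec_s <- cohort_spec(n_participants = 1, duration_s = 12, seed = 21)
  generate_cohort(spec_s, conditions = 1, write_dir = d1)
  generate_cohort(spec_s, conditions = 1, write_dir = d2)
  f1 <- list.files(file.path(d1, "participant_01", "condition_01"))
  expect_length(f1, 8)
  expect_identical(readLines(file.path(d1, "ground_truth.tsv")),
                   readLines(file.path(d2, "ground_truth.tsv")))
  unlink(c(d1, d2), recursive = TRUE)
})
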