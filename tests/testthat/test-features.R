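# Feature extraction: AVO onset, intersecting-tangents foot, PTT, amplitude,
# blood-pressure metrics, heart rate, VTI and stroke volume.

test_that("AVO onset recovery on noiseless filtered bursts, failure on positive-only input", {
  fs <- 500
  x <- make_burst_segment(fs, onset_s = 0.21)
  onset <- detect_avo_onset(x, fs, search_window = c(0, 0.4))
  expect_lt(abs(onset - 0.21), 0.010)
  # a purely positive hump has no negative deflection: feature failure
  t <- (0:400) / fs
  hump <- exp(-(t - 0.2)^2 / (2 * 0.03^2))
  expect_true(is.na(detect_avo_onset(hump, fs, search_window = c(0, 0.4))))
  # onset precedes the tonometry systolic peak by 100-200 ms at rest
  rc <- rest_condition_result()
  lead_ms <- (0.4 - rc$res$avo_onset_s) * 1000
  expect_gt(lead_ms, 100)
  expect_lt(lead_ms, 200)
})

test_that("intersecting tangents: exact on piecewise-linear pulses, invariant to shifts", {
  fs <- 500
  t <- (0:400) / fs
  pulse <- pmax(0, t - 0.3)
  foot <- foot_intersecting_tangents(pulse, fs)
  expect_equal(foot, 0.300, tolerance = 1e-9)
  # constant offset leaves the foot unchanged
  expect_equal(foot_intersecting_tangents(pulse + 5, fs), foot,
               tolerance = 1e-9)
  # time shift moves the foot by exactly the shift
  pulse2 <- pmax(0, t - 0.4)
  expect_equal(foot_intersecting_tangents(pulse2, fs) - foot, 0.1,
               tolerance = 1e-9)
  # raised-cosine upstroke of duration T: tangent foot is the documented
  # T(1/2 - 1/pi) later than the true foot, within one sample
  T_up <- 0.055
  rcos <- ifelse(t < 0.25, 0,
                 ifelse(t < 0.25 + T_up,
                        0.5 * (1 - cos(pi * (t - 0.25) / T_up)), 1))
  delay <- foot_intersecting_tangents(rcos, fs) - 0.25
  expect_lt(abs(delay - T_up * (0.5 - 1 / pi)), 1 / fs)
  # non-positive upstroke: failure
  expect_true(is.na(foot_intersecting_tangents(rev(pulse), fs)))
})

test_that("PTT is the onset-to-foot delay with failure on non-positive gaps", {
  expect_equal(compute_ptt(0.210, 0.496), 286)
  expect_true(is.na(compute_ptt(0.5, 0.5)))
  expect_true(is.na(compute_ptt(NA_real_, 0.4)))
  # shifting a segment shifts onset and foot equally: PTT unchanged
  fs <- 500
  x <- make_burst_segment(fs, onset_s = 0.15, n = 501)
  t <- (0:500) / fs
  ppg <- ifelse(t < 0.35, 0, ifelse(t < 0.45, (t - 0.35) / 0.1, 1))
  shift <- 25L  # samples
  xs <- c(numeric(shift), x)[1:501]
  ppgs <- c(numeric(shift), ppg)[1:501]
  ptt1 <- compute_ptt(detect_avo_onset(x, fs, c(0, 0.3)),
                      foot_intersecting_tangents(ppg, fs, c(0.25, 0.6)))
  ptt2 <- compute_ptt(detect_avo_onset(xs, fs, c(0 + shift / fs, 0.3 + shift / fs)),
                      foot_intersecting_tangents(ppgs, fs, c(0.25 + shift / fs,
                                                             0.6 + shift / fs)))
  expect_equal(ptt1, ptt2, tolerance = 1e-9)
})

test_that("BCG amplitude is the prominence of the largest windowed peak", {
  fs <- 500
  t <- (0:400) / fs
  tri <- pmax(0, 1 - abs(t - 0.25) / 0.02) * 7
  expect_equal(bcg_amplitude(tri, fs, 0.2), 7, tolerance = 1e-9)
  # two peaks inside the window: the taller one's prominence is returned
  two <- pmax(0, 1 - abs(t - 0.23) / 0.015) * 5 +
    pmax(0, 1 - abs(t - 0.29) / 0.015) * 9
  expect_equal(bcg_amplitude(two, fs, 0.2), 9, tolerance = 1e-9)
  # no local maximum in the window
  expect_true(is.na(bcg_amplitude(t, fs, 0.2, window_ms = 50)))
})

test_that("blood-pressure metrics: per-beat extremes, waveform-average MAP, quality flags", {
  spec <- cohort_spec(n_participants = 1, duration_s = 20, seed = 23)
  params <- rest_params()
  beats <- wristbcg:::build_beats(params, spec, 3)
  pr <- synth_pressure_channels(beats, spec, params, noise = FALSE)
  peak_t <- beats$avo_time_s + spec$radial_delay_s + spec$tono_upstroke_s
  bp <- bp_metrics(pr$abp$samples, pr$abp$fs, peak_t)
  expect_lt(abs(bp$sbp - 145.3), 0.5)
  expect_lt(abs(bp$dbp - 71.8), 0.5)
  expect_false(bp$quality_flag)
  expect_true(bp$dbp < bp$map && bp$map < bp$sbp)
  # MAP equals the analytic time-average of a known waveform
  fs <- 125
  t <- seq(0, 20, by = 1 / fs)
  x <- 100 + 20 * sin(2 * pi * t)
  bp2 <- bp_metrics(x, fs, seq(0.25, 19.25, by = 1))
  expect_lt(abs(bp2$map - 100), 0.1)
  # constant signal: sbp = dbp = map = c with a quality flag
  bp3 <- bp_metrics(rep(80, 2000), 125, c(1, 4, 7, 10, 13))
  expect_equal(bp3$sbp, 80)
  expect_equal(bp3$map, 80)
  expect_true(bp3$quality_flag)
  expect_error(bp_metrics(x, fs, c(0.25, 1.25, 2.25, 3.25)[1:3]), "3")
})

test_that("heart rate from the median inter-peak interval is outlier-robust", {
  expect_equal(heart_rate(seq(0, 30, by = 1)), 60)
  expect_equal(heart_rate(seq(0, 30, by = 5 / 12)), 144)
  regular <- seq(0, 100, by = 1)
  wild <- regular; wild[51:101] <- wild[51:101] + 3  # one 4 s gap
  expect_equal(heart_rate(wild), 60)
})

test_that("VTI and stroke volume: analytic shapes, formula, generator round trip", {
  fs <- 200
  t <- seq(0, 1, by = 1 / fs)
  half_sine <- ifelse(t <= 0.25, sin(pi * t / 0.25), 0)
  vti <- doppler_vti(half_sine, fs, 0, 0.25)
  expect_equal(vti, 2 * 100 * 0.25 / pi, tolerance = 1e-3)
  rect <- ifelse(t <= 0.2, 0.5, 0)
  expect_equal(doppler_vti(rect, fs, 0, 0.2), 10, tolerance = 0.3)
  expect_equal(stroke_volume(20, 2.0), 20 * pi, tolerance = 1e-9)
  expect_equal(stroke_volume(0, 2.0), 0)
  expect_equal(stroke_volume(20, 2.0, use_area = FALSE), 40)
  expect_error(stroke_volume(20, 1.0), "diameter")
  # round trip through the generator: recovered SV within 1%
  spec <- cohort_spec(n_participants = 1, duration_s = 20, seed = 29)
  params <- rest_params()
  beats <- wristbcg:::build_beats(params, spec, 5)
  ch <- synth_doppler(beats, spec = spec, params = params)
  vti2 <- doppler_vti(ch$samples, ch$fs, beats$avo_time_s[2],
                      beats$avo_time_s[2] + params$ejection_ms / 1000)
  sv <- stroke_volume(vti2, params$lvot_diameter_cm)
  expect_lt(abs(sv - params$sv_ml) / params$sv_ml, 0.01)
})
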