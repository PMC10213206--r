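# Tonometry peak detection, segmentation, axis selection, ensemble averaging.

test_that("systolic peaks on noiseless tonometry match the per-beat argmax oracle", {
  spec <- cohort_spec(n_participants = 1, duration_s = 120, seed = 17)
  params <- rest_params()
  beats <- wristbcg:::build_beats(params, spec, 3)
  pr <- synth_pressure_channels(beats, spec, params, noise = FALSE)
  tono <- pr$tono
  pk <- detect_systolic_peaks(tono$samples, tono$fs)
  expect_lt(abs(length(pk) - nrow(beats)), 2)
  # oracle: argmax within each beat's foot-to-foot span
  feet <- beats$avo_time_s + spec$radial_delay_s
  t <- wristbcg:::channel_times(tono)
  for (b in seq_len(nrow(beats) - 1)) {
    in_beat <- which(t >= feet[b] & t < feet[b + 1])
    t_oracle <- t[in_beat][which.max(tono$samples[in_beat])]
    expect_true(min(abs(pk - t_oracle)) <= 1 / tono$fs + 1e-9)
  }
})

test_that("degenerate tonometry input is a segmentation failure", {
  expect_error(detect_systolic_peaks(numeric(5000), 500), "segmentation failure")
})

test_that("segmentation windows: inclusive length, boundary skipping", {
  x <- sin(2 * pi * seq(0, 10, by = 1 / 500))
  seg <- segment_beats(x, 500, c(2, 4, 6), pre_ms = 400, post_ms = 400)
  expect_equal(ncol(seg), 401)
  expect_equal(attr(seg, "center"), 201)
  seg2 <- segment_beats(x, 500, c(0.2, 5))
  expect_equal(nrow(seg2), 1)
  expect_equal(attr(seg2, "n_skipped"), 1)
  seg3 <- segment_beats(x, 500, 1:9)
  expect_equal(nrow(seg3), 9)
  expect_error(segment_beats(x, 500, c(0.1, 9.95)), "segmentation failure")
})

test_that("head-foot axis selection follows band energy, ties go to the default", {
  fs <- 500
  t <- seq(0, 30, by = 1 / fs)
  peaks <- seq(1, 29, by = 1)
  burst <- Reduce(`+`, lapply(peaks - 0.2, function(tc)
    exp(-(t - tc)^2 / (2 * 0.025^2)) * cos(2 * pi * 20 * (t - tc)) * 30))
  noise <- withr::with_seed(1, rnorm(length(t), 0, 0.5))
  axes <- list(noise, noise, burst + noise)
  expect_equal(select_headfoot_axis(axes, fs, peaks), 3)
  split70 <- list(0.7 * burst + noise, 0.3 * burst + noise, noise)
  expect_equal(select_headfoot_axis(split70, fs, peaks), 1)
  same <- list(noise, noise, noise)
  expect_equal(select_headfoot_axis(same, fs, peaks, default_axis = 1L), 1)
})

test_that("ensemble averaging: identity, linear cancellation, outlier rejection", {
  seg <- matrix(rep(sin(seq(0, 2 * pi, length.out = 101)), 5), nrow = 5,
                byrow = TRUE)
  attr(seg, "center") <- 51L; attr(seg, "fs") <- 100
  ens <- ensemble_average(seg)
  expect_equal(ens$average, seg[1, ])
  expect_equal(ens$n_rejected, 0)
  # equal-magnitude opposite-sign noise cancels in the mean
  noise <- sin(seq(0, 7, length.out = 101))
  seg2 <- rbind(seg[1, ] + noise, seg[1, ] - noise)
  attr(seg2, "center") <- 51L; attr(seg2, "fs") <- 100
  expect_equal(ensemble_average(seg2, rejection_k = Inf)$average, seg[1, ])
  # one huge-artifact segment among 50 clean ones is rejected at k = 3
  clean <- matrix(rep(seg[1, ], 50), nrow = 50, byrow = TRUE) +
    withr::with_seed(2, matrix(rnorm(50 * 101, 0, 0.05), nrow = 50))
  dirty <- rbind(clean, seg[1, ] + 50)
  attr(dirty, "center") <- 51L; attr(dirty, "fs") <- 100
  ens3 <- ensemble_average(dirty, rejection_k = 3)
  expect_equal(ens3$n_rejected, 1)
  expect_false(ens3$used[51])
})

test_that("ensemble residual noise shrinks as 1/sqrt(n)", {
  template <- sin(2 * pi * 5 * seq(0, 2, by = 1 / 500))
  rms_at <- function(n, seed) {
    seg <- withr::with_seed(seed,
      matrix(rep(template, n), nrow = n, byrow = TRUE) +
        matrix(rnorm(n * length(template)), nrow = n))
    attr(seg, "center") <- 1L; attr(seg, "fs") <- 500
    sqrt(mean((ensemble_average(seg, rejection_k = Inf)$average - template)^2))
  }
  r4 <- rms_at(4, 1); r16 <- rms_at(16, 2); r64 <- rms_at(64, 3)
  expect_lt(abs(r4 / r16 - 2), 0.5)
  expect_lt(abs(r16 / r64 - 2), 0.5)
  expect_lt(abs(r4 / r64 - 4), 1)
})

test_that("tonometry peak sits exactly at the window center of its ensemble", {
  spec <- cohort_spec(n_participants = 1, duration_s = 30, seed = 19)
  params <- rest_params()
  beats <- wristbcg:::build_beats(params, spec, 5)
  pr <- synth_pressure_channels(beats, spec, params, noise = FALSE)
  sync <- resample_common(list(pr$tono),
                          offsets = list(offset = c(tono = 0),
                                         clock = list(tono = c(slope = 1, intercept = 0))),
                          fs_common = 500)
  pk <- detect_systolic_peaks(sync$channels$tono, 500)
  ens <- ensemble_average(segment_beats(sync$channels$tono, 500, pk))
  expect_equal(which.max(ens$average), ens$center)
})
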