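# Synthetic cohort generator: co-registered multi-rate recordings (3-axis
# accelerometer BCG, radial tonometry, thumb PPG, radial-line ABP, ECG, LVOT
# Doppler) with beat-level ground truth, calibrated to the published exercise
# hemodynamics table.
#
# Unit convention: the accelerometer channel is generated in mG (1 mG =
# 1000 ug of acceleration). Systolic amplitude parameters are interpreted on
# the same mG scale while the sensor noise floor stays at its datasheet value
# of 220 ug/sqrt(Hz) = 0.22 mG/sqrt(Hz); see the methods vignette for why the
# two printed scales cannot both be micro-g.

#' Per-condition hemodynamic ground-truth parameters
#'
#' Holds the population (or realized per-participant) hemodynamics of one
#' posture/load condition: heart rate, systolic/diastolic radial pressure,
#' BCG-PPG pulse transit time, systolic BCG amplitude, plus the systolic
#' timing quantities the recordings are built from (pre-ejection period,
#' ejection duration, stroke volume, LVOT diameter). Mean arterial pressure is
#' derived from the waveform downstream, never stored.
#'
#' @param posture `"supine"` or `"semirecumbent"`.
#' @param load_w Ergometer load in watts, one of 0, 50, 100, 150.
#' @param hr_mean,hr_sd Heart rate, beats/min.
#' @param sbp_mean,sbp_sd Systolic radial pressure, mmHg.
#' @param dbp_mean,dbp_sd Diastolic radial pressure, mmHg.
#' @param ptt_mean,ptt_sd BCG-PPG pulse transit time, ms.
#' @param amp_mean,amp_sd Systolic BCG amplitude, mG.
#' @param pep_ms Pre-ejection period (R peak to aortic valve opening), ms.
#' @param sv_ml Stroke volume, mL.
#' @param lvot_diameter_cm LVOT diameter, cm.
#' @param ejection_ms Systolic ejection duration, ms.
#' @return An object of class `condition_params`.
#' @export
condition_params <- function(posture, load_w, hr_mean, hr_sd, sbp_mean, sbp_sd,
                             dbp_mean, dbp_sd, ptt_mean, ptt_sd, amp_mean,
                             amp_sd, pep_ms = 90, sv_ml = 70,
                             lvot_diameter_cm = 2.2, ejection_ms = 300) {
  posture <- match.arg(posture, c("supine", "semirecumbent"))
  stopifnot(load_w %in% c(0, 50, 100, 150),
            hr_sd >= 0, sbp_sd >= 0, dbp_sd >= 0, ptt_sd >= 0, amp_sd >= 0,
            dbp_mean > 0, dbp_mean < sbp_mean,
            ptt_mean > 0, ptt_mean < 60000 / hr_mean,
            pep_ms > 0, ejection_ms > 0,
            pep_ms + ejection_ms < 60000 / hr_mean)
  structure(list(posture = posture, load_w = load_w,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 sbp_mean = sbp_mean, sbp_sd = sbp_sd,
                 dbp_mean = dbp_mean, dbp_sd = dbp_sd,
                 ptt_mean = ptt_mean, ptt_sd = ptt_sd,
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 pep_ms = pep_ms, sv_ml = sv_ml,
                 lvot_diameter_cm = lvot_diameter_cm,
                 ejection_ms = ejection_ms),
            class = "condition_params")
}

#' Published study-condition calibration (8 conditions)
#'
#' The population means and standard deviations of HR, SBP, DBP, PTT and
#' systolic BCG amplitude for the eight posture-by-load exercise conditions
#' (supine and semirecumbent at 0/50/100/150 W), as summarized in the source
#' study's results table. Pre-ejection period (90 ms at rest falling linearly
#' to 60 ms at 150 W), stroke volume (70 mL at rest rising to a 110 mL plateau
#' from 100 W) and ejection duration (300 ms falling to 210 ms) are not
#' tabulated in the study and carry plausible resting-to-exercise defaults.
#'
#' @return A list of eight [condition_params()], supine loads first.
#' @export
reference_conditions <- function() {
  loads <- c(0, 50, 100, 150)
  tab <- list(
    supine = list(
      hr  = rbind(c(69.0, 12.0), c(101.2, 13.9), c(123.0, 18.0), c(144.0, 19.3)),
      sbp = rbind(c(145.3, 15.8), c(170.5, 22.0), c(194.1, 26.3), c(207.7, 27.0)),
      dbp = rbind(c(71.8, 7.4), c(70.3, 5.7), c(73.2, 6.0), c(75.0, 6.9)),
      ptt = rbind(c(286.2, 25.2), c(260.0, 21.5), c(237.8, 21.1), c(219.6, 26.1)),
      amp = rbind(c(29.5, 15.2), c(65.4, 37.8), c(78.8, 35.8), c(82.2, 38.0))),
    semirecumbent = list(
      hr  = rbind(c(79.1, 15.4), c(104.0, 16.4), c(130.1, 20.8), c(151.8, 20.6)),
      sbp = rbind(c(129.6, 19.1), c(154.3, 20.6), c(179.8, 23.4), c(200.9, 29.5)),
      dbp = rbind(c(65.2, 7.4), c(63.4, 6.1), c(66.8, 5.7), c(69.2, 5.6)),
      ptt = rbind(c(263.1, 23.6), c(246.0, 30.3), c(227.3, 23.2), c(209.1, 27.8)),
      amp = rbind(c(31.7, 20.4), c(52.3, 27.2), c(88.6, 39.5), c(98.2, 37.8))))
  pep <- c(90, 80, 70, 60)
  sv <- c(70, 90, 110, 110)
  ejc <- c(300, 270, 240, 210)
  out <- list()
  for (post in c("supine", "semirecumbent")) {
    for (i in seq_along(loads)) {
      p <- tab[[post]]
      out[[length(out) + 1L]] <- condition_params(
        posture = post, load_w = loads[i],
        hr_mean = p$hr[i, 1], hr_sd = p$hr[i, 2],
        sbp_mean = p$sbp[i, 1], sbp_sd = p$sbp[i, 2],
        dbp_mean = p$dbp[i, 1], dbp_sd = p$dbp[i, 2],
        ptt_mean = p$ptt[i, 1], ptt_sd = p$ptt[i, 2],
        amp_mean = p$amp[i, 1], amp_sd = p$amp[i, 2],
        pep_ms = pep[i], sv_ml = sv[i], ejection_ms = ejc[i])
    }
  }
  out
}

#' Cohort-level generator settings
#'
#' @param n_participants Number of participants (study default 25).
#' @param conditions List of [condition_params()]; default the eight published
#'   study conditions from [reference_conditions()].
#' @param duration_s Recording length per condition, seconds (study protocol:
#'   at least 2 min of steady-state measurements).
#' @param rates Named sampling rates in Hz for `abp`, `ppg`, `ecg`, `tono`,
#'   `acc` and `lvot` channels (study-native values by default).
#' @param seed Base RNG seed; every generated quantity is deterministic given
#'   the seed.
#' @param noise_density_mg_sqrthz One-sided accelerometer noise amplitude
#'   spectral density in mG/sqrt(Hz); the default 0.22 equals the sensor's
#'   220 ug/sqrt(Hz) datasheet noise floor.
#' @param cadence_rpm Pedalling cadence (motion-artifact fundamental), rev/min.
#' @param artifact_band_hz Two-element band (Hz) containing the cadence
#'   harmonics of the motion artifact.
#' @param burst_center_hz Carrier frequency of the systolic BCG burst, Hz.
#' @param burst_sigma_s Gaussian envelope width of the burst, seconds.
#' @param burst_lag_s Lag from aortic valve opening to the burst's first
#'   positive peak, seconds; this convention defines what "onset marks AVO"
#'   means for recovery tests.
#' @param jitter_cv Coefficient of variation of the multiplicative inter-beat
#'   interval jitter.
#' @param artifact_max_ratio Motion-artifact peak amplitude at 150 W as a
#'   multiple of the systolic burst amplitude (0 at 0 W, linear in load).
#' @param radial_delay_s Transit delay from aortic valve opening to the radial
#'   (tonometry/ABP) pulse foot, seconds.
#' @param tono_upstroke_s Radial pressure upstroke duration (foot to systolic
#'   peak), seconds.
#' @param ppg_upstroke_s Thumb-PPG upstroke duration, seconds. The default
#'   55 ms makes the intersecting-tangents foot delay on the raised-cosine PPG
#'   upstroke (0.1817 x duration, about 10 ms) offset the 10 ms burst-onset
#'   lag, so the end-to-end PTT estimator is unbiased by construction.
#' @param rho_ptt_sbp Between-participant correlation of the PTT and SBP
#'   random effects (0 = independent draws).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 25,
                        conditions = reference_conditions(),
                        duration_s = 120,
                        rates = c(abp = 125, ppg = 125, ecg = 500,
                                  tono = 200, acc = 900, lvot = 200),
                        seed = 42,
                        noise_density_mg_sqrthz = 0.22,
                        cadence_rpm = 60,
                        artifact_band_hz = c(1, 10),
                        burst_center_hz = 20,
                        burst_sigma_s = 0.025,
                        burst_lag_s = 0.010,
                        jitter_cv = 0.03,
                        artifact_max_ratio = 5,
                        radial_delay_s = 0.050,
                        tono_upstroke_s = 0.150,
                        ppg_upstroke_s = 0.055,
                        rho_ptt_sbp = 0) {
  stopifnot(n_participants >= 1, duration_s >= 10,
            all(c("abp", "ppg", "ecg", "tono", "acc", "lvot") %in% names(rates)),
            burst_center_hz >= 10, burst_center_hz <= 30,
            rates["acc"] > 2 * 30,
            abs(rho_ptt_sbp) < 1)
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions, duration_s = duration_s,
                 rates = rates, seed = seed,
                 noise_density_mg_sqrthz = noise_density_mg_sqrthz,
                 cadence_rpm = cadence_rpm,
                 artifact_band_hz = artifact_band_hz,
                 burst_center_hz = burst_center_hz,
                 burst_sigma_s = burst_sigma_s,
                 burst_lag_s = burst_lag_s,
                 jitter_cv = jitter_cv,
                 artifact_max_ratio = artifact_max_ratio,
                 radial_delay_s = radial_delay_s,
                 tono_upstroke_s = tono_upstroke_s,
                 ppg_upstroke_s = ppg_upstroke_s,
                 rho_ptt_sbp = rho_ptt_sbp),
            class = "cohort_spec")
}

#' Draw one participant's realized condition parameters
#'
#' Participant-level random effects: for each of the spec's conditions the
#' realized HR, SBP, DBP, PTT and amplitude means are drawn from
#' `Normal(condition mean, condition sd)`, truncated by rejection to the
#' physiological invariants (`0 < DBP < SBP`, `0 < PTT < beat interval`,
#' positive amplitude, valid systolic timing). Deterministic given the spec
#' seed and participant index.
#'
#' @param spec A [cohort_spec()].
#' @param participant_index 1-based participant number.
#' @return A list of realized [condition_params()] (sd fields set to 0).
#' @export
draw_participant_params <- function(spec, participant_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            participant_index >= 1, participant_index <= spec$n_participants)
  lapply(seq_along(spec$conditions), function(ci) {
    p <- spec$conditions[[ci]]
    with_seed(derive_seed(spec$seed, participant_index, ci), {
      for (try in 1:100) {
        z <- stats::rnorm(5)
        # optional coupling between the PTT and SBP random effects
        r <- spec$rho_ptt_sbp
        z_sbp <- r * z[4] + sqrt(1 - r^2) * z[2]
        hr <- p$hr_mean + p$hr_sd * z[1]
        sbp <- p$sbp_mean + p$sbp_sd * z_sbp
        dbp <- p$dbp_mean + p$dbp_sd * z[3]
        ptt <- p$ptt_mean + p$ptt_sd * z[4]
        amp <- p$amp_mean + p$amp_sd * z[5]
        ok <- hr > 30 && hr < 220 && dbp > 0 && dbp < sbp && ptt > 0 &&
          ptt < 60000 / hr && amp > 0 &&
          p$pep_ms + p$ejection_ms < 60000 / hr
        if (ok)
          return(condition_params(p$posture, p$load_w, hr, 0, sbp, 0, dbp, 0,
                                  ptt, 0, amp, 0, p$pep_ms, p$sv_ml,
                                  p$lvot_diameter_cm, p$ejection_ms))
      }
      stop("generation failure: no invariant-satisfying draw in 100 retries")
    })
  })
}

#' Generate a jittered beat train
#'
#' Inter-beat intervals are `60 / HR` seconds with multiplicative lognormal
#' jitter of coefficient of variation `jitter_cv`; the first beat is at 1 s
#' and beats continue while at least 1 s of record remains.
#'
#' @param params A (realized) [condition_params()].
#' @param duration_s Record duration, seconds.
#' @param jitter_cv Jitter coefficient of variation (0 disables jitter).
#' @param seed RNG seed.
#' @return Numeric vector of R-peak times `r_time_s`.
#' @export
synth_beat_train <- function(params, duration_s, jitter_cv = 0.03, seed = 1) {
  stopifnot(duration_s > 0)
  base <- 60 / params$hr_mean
  with_seed(seed, {
    n_max <- ceiling(duration_s / base) + 10L
    fac <- if (jitter_cv > 0) exp(stats::rnorm(n_max, 0, jitter_cv)) else rep(1, n_max)
    r <- 1 + c(0, cumsum(base * fac))[seq_len(n_max)]
    r[r <= duration_s - 1]
  })
}

# Beat-level ground truth for one realized condition.
build_beats <- function(params, spec, seed) {
  r <- synth_beat_train(params, spec$duration_s, spec$jitter_cv, seed)
  data.frame(r_time_s = r,
             avo_time_s = r + params$pep_ms / 1000,
             pulse_foot_time_s = r + params$pep_ms / 1000 + params$ptt_mean / 1000,
             true_ptt_ms = params$ptt_mean,
             true_amp_mg = params$amp_mean,
             true_sv_ml = params$sv_ml,
             true_sbp_mmHg = params$sbp_mean,
             true_dbp_mmHg = params$dbp_mean,
             true_hr_bpm = params$hr_mean)
}

# Gabor atom: Gaussian-windowed cosine, unit peak at `center`.
gabor_atom <- function(t, center, f, sigma) {
  exp(-(t - center)^2 / (2 * sigma^2)) * cos(2 * pi * f * (t - center))
}

# Exact atom geometry. Because the Gaussian envelope tilts the product, the
# local extrema of env(u) * cos(2 pi f u) do not sit exactly at the carrier
# extrema: each is shifted toward the envelope center. Solved numerically:
# `first_peak_u` is the (negative) offset of the first positive local maximum
# relative to the atom center, and `trough_depth` the |value| of the flanking
# troughs, so the main peak's topographic prominence is `1 + trough_depth`
# per unit height.
gabor_calibration <- function(f, sigma) {
  g <- function(u) exp(-u^2 / (2 * sigma^2)) * cos(2 * pi * f * u)
  tr <- stats::optimize(g, c(0.05 / f, 0.95 / f))
  pk <- stats::optimize(g, c(-1.45 / f, -0.55 / f), maximum = TRUE)
  list(first_peak_u = pk$maximum, trough_depth = -tr$objective)
}

# Scale factor turning the atom's unit height into unit topographic prominence
# (main peak relative to its flanking troughs).
gabor_prominence_factor <- function(f, sigma) {
  1 + gabor_calibration(f, sigma)$trough_depth
}

#' Synthesize the head-foot accelerometer BCG channel
#'
#' Each beat contributes a systolic Gabor burst (Gaussian-windowed cosine,
#' carrier `burst_center_hz`, envelope width `burst_sigma_s`) positioned so
#' that its first positive local maximum lies exactly at
#' `avo_time + burst_lag_s` (the atom center is offset by the numerically
#' solved extremum location, see `gabor_calibration`), and scaled so the main
#' peak's topographic prominence equals the condition amplitude (mG); a diastolic burst at +250 ms
#' with 30% amplitude; a motion artifact made of cadence harmonics inside the
#' artifact band, scaled linearly with load up to `artifact_max_ratio` times
#' the burst amplitude at 150 W; and white sensor noise at the configured
#' one-sided density.
#'
#' @param beats Beat ground-truth table from the generator (needs
#'   `avo_time_s`, `true_amp_mg`).
#' @param spec A [cohort_spec()].
#' @param params Realized [condition_params()] for this condition.
#' @param seed RNG seed for artifact phases and noise.
#' @param noise,artifact,diastolic Logical switches for the three additive
#'   components (all on by default).
#' @param name Channel name.
#' @return A [channel_recording()] in mG at the accelerometer rate.
#' @export
synth_bcg <- function(beats, spec, params, seed = 1, noise = TRUE,
                      artifact = TRUE, diastolic = TRUE, name = "acc_x") {
  stopifnot(nrow(beats) >= 1)
  fs <- unname(spec$rates["acc"])
  f <- spec$burst_center_hz
  if (fs < 4 * f) stop("configuration error: acc rate below 4x burst frequency")
  sigma <- spec$burst_sigma_s
  t <- seq(0, spec$duration_s, by = 1 / fs)
  x <- numeric(length(t))
  cal <- gabor_calibration(f, sigma)
  pf <- 1 + cal$trough_depth
  for (b in seq_len(nrow(beats))) {
    a_h <- beats$true_amp_mg[b] / pf
    tc <- beats$avo_time_s[b] + spec$burst_lag_s - cal$first_peak_u
    idx <- which(t >= tc - 6 * sigma & t <= tc + 6 * sigma)
    x[idx] <- x[idx] + a_h * gabor_atom(t[idx], tc, f, sigma)
    if (diastolic) {
      tc2 <- tc + 0.25
      idx2 <- which(t >= tc2 - 6 * sigma & t <= tc2 + 6 * sigma)
      x[idx2] <- x[idx2] + 0.3 * a_h * gabor_atom(t[idx2], tc2, f, sigma)
    }
  }
  with_seed(seed, {
    if (artifact && params$load_w > 0 && spec$artifact_max_ratio > 0) {
      x <- x + motion_artifact(t, spec, params)
    }
    if (noise && spec$noise_density_mg_sqrthz > 0) {
      x <- x + stats::rnorm(length(t), 0,
                            spec$noise_density_mg_sqrthz * sqrt(fs / 2))
    }
  })
  channel_recording(name, fs, x, units = "mG")
}

# Band-limited cadence-harmonic motion artifact (mG), amplitude linear in load.
motion_artifact <- function(t, spec, params) {
  f0 <- spec$cadence_rpm / 60
  harm <- seq(ceiling(spec$artifact_band_hz[1] / f0),
              floor(spec$artifact_band_hz[2] / f0))
  harm <- harm[harm >= 1]
  if (!length(harm)) return(numeric(length(t)))
  total <- spec$artifact_max_ratio * params$amp_mean * params$load_w / 150
  w <- (1 / harm) / sum(1 / harm)
  phases <- stats::runif(length(harm), 0, 2 * pi)
  out <- numeric(length(t))
  for (i in seq_along(harm))
    out <- out + total * w[i] * sin(2 * pi * harm[i] * f0 * t + phases[i])
  out
}

# Normalized pulse waveform in [0, 1]: upstroke from each foot to a peak after
# `upstroke_s`, then exponential relaxation reaching exactly 0 at the next
# foot. "qsine" (quarter sine) has maximum slope at the foot, as the sharp
# arterial upstroke, and a flat systolic top; "qsine_sharp" truncates the
# quarter sine at 80% of its span so the systolic peak is a corner with
# non-zero slope on both sides (precisely locatable under noise, as a
# tonometer gating reference must be); "rcos" (raised cosine) is the smoother
# PPG-like upstroke.
pulse_shape <- function(t, feet, upstroke_s, shape = c("qsine", "qsine_sharp", "rcos"),
                        lambda = 3) {
  shape <- match.arg(shape)
  if (length(feet) < 1) stop("generation failure: no pulse feet")
  if (length(feet) > 1 && any(diff(feet) <= 0))
    stop("generation failure: foot times non-increasing")
  med_rr <- if (length(feet) > 1) stats::median(diff(feet)) else 1
  bounds <- c(feet, feet[length(feet)] + med_rr)
  v <- numeric(length(t))
  i <- findInterval(t, feet)
  inb <- i >= 1L
  if (!any(inb)) return(v)
  fi <- feet[i[inb]]
  nxt <- bounds[i[inb] + 1L]
  u <- t[inb] - fi
  up <- u < upstroke_s
  val <- numeric(length(u))
  if (shape == "qsine") {
    val[up] <- sin(pi * u[up] / (2 * upstroke_s))
  } else if (shape == "qsine_sharp") {
    tq <- upstroke_s / 0.8
    val[up] <- sin(pi * u[up] / (2 * tq)) / sin(pi * upstroke_s / (2 * tq))
  } else {
    val[up] <- 0.5 * (1 - cos(pi * u[up] / upstroke_s))
  }
  pk <- fi + upstroke_s
  dur <- pmax(nxt - pk, 1e-6)
  u2 <- pmin((t[inb] - pk) / dur, 1)
  val[!up] <- pmax(0, (exp(-lambda * u2[!up]) - exp(-lambda)) /
                     (1 - exp(-lambda)))
  v[inb] <- val
  v
}

#' Synthesize tonometry, ABP and PPG channels
#'
#' The radial pressure pulse (shared by ABP and tonometry) rises from its foot
#' at `avo_time + radial_delay_s` with a quarter-sine upstroke to the systolic
#' peak `tono_upstroke_s` later, then relaxes exponentially to the next foot,
#' so each ABP beat spans exactly `[DBP, SBP]` mmHg. Tonometry is the same
#' shape with affine gain/offset and additive noise on its own 200 Hz clock.
#' The thumb PPG rises from the ground-truth pulse foot (`avo_time + PTT`)
#' with a smoother raised-cosine upstroke of `ppg_upstroke_s`.
#'
#' @inheritParams synth_bcg
#' @param noise Add measurement noise to tonometry and PPG.
#' @return Named list of [channel_recording()]s: `tono` (au, 200 Hz), `abp`
#'   (mmHg, 125 Hz), `ppg` (au, 125 Hz).
#' @export
synth_pressure_channels <- function(beats, spec, params, seed = 1,
                                    noise = TRUE) {
  stopifnot(nrow(beats) >= 1)
  radial_feet <- beats$avo_time_s + spec$radial_delay_s
  ppg_feet <- beats$pulse_foot_time_s
  sbp <- params$sbp_mean
  dbp <- params$dbp_mean
  mk_abp <- function(fs) {
    t <- seq(0, spec$duration_s, by = 1 / fs)
    dbp + (sbp - dbp) * pulse_shape(t, radial_feet, spec$tono_upstroke_s, "qsine")
  }
  abp <- channel_recording("abp", unname(spec$rates["abp"]),
                           mk_abp(spec$rates["abp"]), units = "mmHg")
  with_seed(derive_seed(seed, 2), {
    t_t <- seq(0, spec$duration_s, by = 1 / spec$rates["tono"])
    tono_shape <- pulse_shape(t_t, radial_feet, spec$tono_upstroke_s, "qsine_sharp")
    tono_x <- 1 + 0.01 * (dbp + (sbp - dbp) * tono_shape)
    if (noise) tono_x <- tono_x + stats::rnorm(length(tono_x), 0,
                                               0.005 * 0.01 * (sbp - dbp))
    tono <- channel_recording("tono", unname(spec$rates["tono"]), tono_x,
                              units = "au")
    t_p <- seq(0, spec$duration_s, by = 1 / spec$rates["ppg"])
    ppg_x <- pulse_shape(t_p, ppg_feet, spec$ppg_upstroke_s, "rcos")
    if (noise) ppg_x <- ppg_x + stats::rnorm(length(ppg_x), 0, 0.002)
    ppg <- channel_recording("ppg", unname(spec$rates["ppg"]), ppg_x,
                             units = "au")
    list(tono = tono, abp = abp, ppg = ppg)
  })
}

#' Synthesize the LVOT Doppler velocity channel
#'
#' Each beat's ejection is a half-sine velocity profile from `avo_time` to
#' `avo_time + ejection_ms`, with peak velocity chosen so that the
#' velocity-time integral times the LVOT cross-sectional area equals the
#' condition's true stroke volume; zero between ejections.
#'
#' @inheritParams synth_bcg
#' @return A [channel_recording()] (`lvot`, m/s) with the LVOT diameter (cm)
#'   attached as attribute `lvot_diameter_cm`.
#' @export
synth_doppler <- function(beats, spec, params) {
  stopifnot(nrow(beats) >= 1)
  t_ej <- params$ejection_ms / 1000
  if (t_ej >= 60 / params$hr_mean)
    stop("configuration error: ejection longer than beat interval")
  area <- pi * (params$lvot_diameter_cm / 2)^2
  # VTI_cm = 100 * 2 v T / pi must equal sv / area
  v_peak <- params$sv_ml * pi / (200 * t_ej * area)
  if (v_peak > 6)
    stop("physiologically implausible configuration: peak LVOT velocity > 6 m/s")
  fs <- unname(spec$rates["lvot"])
  t <- seq(0, spec$duration_s, by = 1 / fs)
  x <- numeric(length(t))
  for (b in seq_len(nrow(beats))) {
    t0 <- beats$avo_time_s[b]
    idx <- which(t >= t0 & t <= t0 + t_ej)
    x[idx] <- x[idx] + v_peak * sin(pi * (t[idx] - t0) / t_ej)
  }
  ch <- channel_recording("lvot", fs, x, units = "m/s")
  attr(ch, "lvot_diameter_cm") <- params$lvot_diameter_cm
  ch
}

# Stylized PQRST ECG with a dominant, locatable R peak at each r_time_s.
synth_ecg <- function(beats, spec) {
  fs <- unname(spec$rates["ecg"])
  t <- seq(0, spec$duration_s, by = 1 / fs)
  x <- numeric(length(t))
  waves <- list(c(0, 1, 0.008), c(-0.025, -0.12, 0.010), c(0.025, -0.18, 0.010),
                c(-0.17, 0.15, 0.022), c(0.25, 0.30, 0.040))
  for (r in beats$r_time_s) {
    for (w in waves) {
      idx <- which(t >= r + w[1] - 5 * w[3] & t <= r + w[1] + 5 * w[3])
      x[idx] <- x[idx] + w[2] * exp(-(t[idx] - r - w[1])^2 / (2 * w[3]^2))
    }
  }
  channel_recording("ecg", fs, x, units = "mV")
}

#' Generate the full synthetic cohort
#'
#' Draws each participant's realized condition parameters, builds the beat
#' trains and all six channels per condition, attaches shared timing events
#' (every 10 s of lab time) with per-channel clock offsets, and collects the
#' beat-level ground-truth table. Entirely deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param participants Integer vector of participant indices (default all).
#' @param conditions Integer vector of condition indices (default all).
#' @param write_dir Optional directory; when given, every channel is written
#'   with [write_channel()] under `participant_XX/condition_YY/` and the
#'   ground-truth table as `ground_truth.tsv`.
#' @param channel_offsets Add random per-channel clock offsets (accelerometer
#'   clock is the zero-offset reference). Disable for pre-aligned data.
#' @return A list with `spec`, `ground_truth` (one row per beat), and
#'   `recordings[[p]][[c]]`, each a list of `channels`, the realized `params`
#'   and the condition labels.
#' @export
generate_cohort <- function(spec = cohort_spec(), participants = NULL,
                            conditions = NULL, write_dir = NULL,
                            channel_offsets = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(participants)) participants <- seq_len(spec$n_participants)
  if (is.null(conditions)) conditions <- seq_along(spec$conditions)
  ev_lab <- seq(5, spec$duration_s - 1, by = 10)
  gt <- list()
  recordings <- list()
  for (p in participants) {
    rp <- draw_participant_params(spec, p)
    pc <- list()
    for (ci in conditions) {
      params <- rp[[ci]]
      bseed <- derive_seed(spec$seed, p, ci, 1)
      beats <- build_beats(params, spec, bseed)
      acc_x <- synth_bcg(beats, spec, params, seed = derive_seed(spec$seed, p, ci, 2))
      aux <- with_seed(derive_seed(spec$seed, p, ci, 3), {
        t <- channel_times(acc_x)
        lapply(c("acc_y", "acc_z"), function(nm) {
          x <- stats::rnorm(length(t), 0,
                            spec$noise_density_mg_sqrthz * sqrt(acc_x$fs / 2))
          if (params$load_w > 0 && spec$artifact_max_ratio > 0)
            x <- x + motion_artifact(t, spec, params)
          channel_recording(nm, acc_x$fs, x, units = "mG")
        })
      })
      press <- synth_pressure_channels(beats, spec, params,
                                       seed = derive_seed(spec$seed, p, ci, 4))
      lvot <- synth_doppler(beats, spec, params)
      ecg <- synth_ecg(beats, spec)
      chans <- c(list(acc_x = acc_x, acc_y = aux[[1]], acc_z = aux[[2]]),
                 press, list(lvot = lvot, ecg = ecg))
      offs <- if (channel_offsets)
        with_seed(derive_seed(spec$seed, p, ci, 5),
                  c(0, round(stats::runif(length(chans) - 1, -0.25, 0.25), 4)))
      else rep(0, length(chans))
      for (k in seq_along(chans)) {
        chans[[k]]$t0 <- chans[[k]]$t0 + offs[k]
        chans[[k]]$timing_events <- ev_lab + offs[k]
      }
      gt[[length(gt) + 1L]] <- cbind(
        data.frame(participant = p, condition = ci, posture = params$posture,
                   load_w = params$load_w,
                   lvot_diameter_cm = params$lvot_diameter_cm,
                   beat = seq_len(nrow(beats))),
        beats)
      pc[[as.character(ci)]] <- list(channels = chans, params = params,
                                     participant = p, condition = ci,
                                     lvot_diameter_cm = params$lvot_diameter_cm)
      if (!is.null(write_dir)) {
        d <- file.path(write_dir, sprintf("participant_%02d", p),
                       sprintf("condition_%02d", ci))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        for (ch in chans) write_channel(ch, file.path(d, paste0(ch$name, ".tsv")))
      }
    }
    recordings[[as.character(p)]] <- pc
  }
  ground_truth <- do.call(rbind, gt)
  rownames(ground_truth) <- NULL
  if (!is.null(write_dir)) {
    utils::write.table(format(ground_truth, digits = 10, trim = TRUE),
                       file.path(write_dir, "ground_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(spec = spec, ground_truth = ground_truth, recordings = recordings)
}
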