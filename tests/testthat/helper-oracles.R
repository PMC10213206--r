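# Independent oracles and small fixture builders used across the test files.
# Each oracle is a direct, separate implementation of the quantity it checks;
# none call the package code path they validate.

# Intersecting-tangents foot, direct geometric implementation on (t, y):
# steepest-ascent point by central differences, horizontal baseline through
# the minimum preceding it, intersection abscissa.
oracle_tangent_foot <- function(t, y) {
  dy <- c(NA, diff(y)) / c(NA, diff(t))
  imax <- which.max(dy)
  slope <- dy[imax]
  baseline <- min(y[1:imax])
  t[imax] - (y[imax] - baseline) / slope
}

# Exact two-sided signed-rank p-value by explicit bitmask enumeration.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n_le <- 0L; n_ge <- 0L
  for (mask in 0:(2^m - 1)) {
    w <- sum(r[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0])
    if (w <= w_obs + 1e-9) n_le <- n_le + 1L
    if (w >= w_obs - 1e-9) n_ge <- n_ge + 1L
  }
  min(1, 2 * min(n_le, n_ge) / 2^m)
}

# The generator's documented Gabor-burst expression, evaluated directly:
# atom center placed so the first positive local maximum of
# env * cos lies at `first_peak_time`; height scaled so the main peak's
# prominence (1 + flanking trough depth) equals `amp`.
oracle_gabor_burst <- function(t, first_peak_time, amp, f = 20, sigma = 0.025) {
  g <- function(u) exp(-u^2 / (2 * sigma^2)) * cos(2 * pi * f * u)
  u_pk <- stats::optimize(g, c(-1.45 / f, -0.55 / f), maximum = TRUE)$maximum
  depth <- -stats::optimize(g, c(0.05 / f, 0.95 / f))$objective
  center <- first_peak_time - u_pk
  amp / (1 + depth) * g(t - center)
}

# Topographic prominence of the peak at index i, direct scan implementation.
peak_prominence_oracle <- function(x, i) {
  n <- length(x)
  higher <- which(x > x[i])
  lb <- if (any(higher < i)) max(higher[higher < i]) else 1L
  rb <- if (any(higher > i)) min(higher[higher > i]) else n
  x[i] - max(min(x[lb:i]), min(x[i:rb]))
}

# A single-beat filtered-BCG-like segment: one calibrated burst on a zero
# baseline, sampled at `fs`, with the first positive peak at `onset_s`.
make_burst_segment <- function(fs = 500, n = 401, onset_s = 0.21, amp = 30,
                               f = 20, sigma = 0.025, diastolic = TRUE) {
  t <- (seq_len(n) - 1) / fs
  x <- oracle_gabor_burst(t, onset_s, amp, f, sigma)
  if (diastolic) x <- x + 0.3 * oracle_gabor_burst(t, onset_s + 0.25, amp, f, sigma)
  x
}

# Noise-free rest-condition parameter set (published supine 0 W means, all
# between-participant SDs zero).
rest_params <- function() {
  condition_params("supine", 0, 69.0, 0, 145.3, 0, 71.8, 0, 286.2, 0, 29.5, 0,
                   pep_ms = 90, sv_ml = 70, ejection_ms = 300)
}

# One fully processed noiseless-ish rest condition, computed once per test
# run and cached (single participant, 30 s).
rest_condition_cache <- new.env(parent = emptyenv())
rest_condition_result <- function() {
  if (is.null(rest_condition_cache$res)) {
    spec <- cohort_spec(n_participants = 1, duration_s = 30, seed = 42)
    coh <- generate_cohort(spec, participants = 1, conditions = 1)
    rec <- coh$recordings[["1"]][["1"]]
    rest_condition_cache$rec <- rec
    rest_condition_cache$res <-
      process_condition(rec$channels, lvot_diameter_cm = rec$lvot_diameter_cm,
                        seed = 7)
  }
  list(rec = rest_condition_cache$rec, res = rest_condition_cache$res)
}
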