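# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a reproducible sub-seed from a base seed and integer tags, kept < 2^31.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed)
  for (t in tags) s <- (s * 69069 + as.double(t) * 9973 + 1) %% 2147483647
  as.integer(s)
}

# Local extrema with plateau ties resolved to the earliest sample.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(x))
  nz <- s != 0
  if (!any(nz)) return(list(maxima = integer(0), minima = integer(0)))
  # backward-fill zero slopes with the next nonzero sign so that a plateau
  # extremum is attributed to its first sample
  f <- rev(s)
  ok <- f != 0
  pos <- cumsum(ok)
  pos[pos == 0L] <- 1L
  f <- rev(f[ok][pos])
  i <- seq_len(n - 2L)
  list(maxima = which(f[i] > 0 & f[i + 1L] < 0) + 1L,
       minima = which(f[i] < 0 & f[i + 1L] > 0) + 1L)
}

# Number of zero crossings (sign changes, zeros skipped).
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# Topographic prominence of peaks at indices `peaks` of `x`: height above the
# higher of the two bases, each base being the minimum between the peak and the
# nearest strictly higher terrain (or the record end).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    higher <- which(x > h)
    lo <- higher[higher < p]
    hi <- higher[higher > p]
    lb <- if (length(lo)) max(lo) else 1L
    rb <- if (length(hi)) min(hi) else n
    left_min <- min(x[lb:p])
    right_min <- min(x[p:rb])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Welch power spectral density estimate
#'
#' One-sided power spectral density by averaging modified (Hann-windowed)
#' periodograms over overlapping segments. The estimate is scaled as a density,
#' so for white noise with one-sided amplitude spectral density `d` the PSD
#' level is `d^2`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples (default: `min(length(x), 1024)`).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @param demean Subtract each segment's mean before windowing.
#' @return A list with `freq` (Hz) and `psd` (power per Hz).
#' @examples
#' x <- sin(2 * pi * 20 * seq(0, 2, by = 1 / 500))
#' w <- welch_psd(x, fs = 500, nperseg = 256)
#' w$freq[which.max(w$psd)]
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 1024L), overlap = 0.5,
                      demean = TRUE) {
  stopifnot(fs > 0, length(x) >= 8, overlap >= 0, overlap < 1)
  nperseg <- min(as.integer(nperseg), length(x))
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  k <- seq_len(nperseg) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * k / nperseg)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nf)]
    acc <- acc + Re(X * Conj(X))
  }
  psd <- acc / length(starts) * scale
  # one-sided doubling, except DC and (if present) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd * dbl)
}

# Trapezoid integral of y over uniform spacing dt.
trapz_int <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}
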