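# Internal spectral machinery: Hann-windowed Welch cross-spectra, dominant
# frequency with sub-bin refinement, and simultaneous rational approximation
# of frequency ratios.

hann <- function(L) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))

# Welch segment length: power of two giving ~30-60 half-overlapped segments,
# never below 64 samples. Keeps the independent-signal coherence bias
# (~ 1/n_segments) well below 0.05 at n = 1e4 while retaining frequency
# resolution.
welch_segment_length <- function(n) {
  max(64, min(1024, 2^floor(log2(n / 16))))
}

# Averaged cross- and auto-spectra over 50%-overlapping Hann segments.
welch_cross <- function(x, y, L) {
  n <- length(x)
  starts <- seq(1, n - L + 1, by = L %/% 2)
  w <- hann(L)
  sxx <- syy <- numeric(L)
  sxy <- complex(length.out = L)
  for (s in starts) {
    i <- s:(s + L - 1)
    xs <- (x[i] - mean(x[i])) * w
    ys <- (y[i] - mean(y[i])) * w
    fx <- fft(xs); fy <- fft(ys)
    sxx <- sxx + Mod(fx)^2
    syy <- syy + Mod(fy)^2
    sxy <- sxy + fx * Conj(fy)
  }
  half <- 2:(L %/% 2 + 1)  # positive frequencies, DC dropped
  list(freq = (half - 1) / L, sxx = sxx[half], syy = syy[half],
       sxy = sxy[half], n_segments = length(starts))
}

# Dominant frequency: full-length Hann periodogram peak with quadratic
# interpolation of log-power on the three bins around the maximum. Ties
# resolve toward the lower frequency (which.max takes the first maximum).
# Optional cubic-spline pre-smoothing of the series is available but off by
# default: GCV smoothing can attenuate and displace high-frequency peaks.
dominant_frequency <- function(x, fs, spline_smooth = FALSE) {
  n <- length(x)
  if (isTRUE(spline_smooth)) x <- stats::smooth.spline(seq_len(n), x)$y
  x <- x - mean(x)
  if (all(x == 0)) abort("Constant dimension: degenerate trajectory.")
  p <- Mod(fft(x * hann(n)))^2
  half <- 2:(n %/% 2)
  k <- half[which.max(p[half])]
  d <- 0
  if (k > 2 && k < n %/% 2 && all(p[(k - 1):(k + 1)] > 0)) {
    la <- log(p[k - 1]); lb <- log(p[k]); lc <- log(p[k + 1])
    den <- la - 2 * lb + lc
    if (is.finite(den) && den != 0) d <- 0.5 * (la - lc) / den
    if (!is.finite(d) || abs(d) > 0.5) d <- 0
  }
  (k - 1 + d) * fs / n
}

# Simultaneous rational approximation of a frequency triple: the reduced
# ratios r = f / min(f) are rational iff some integer triple (a, b, c) with
# max entry <= max_int reproduces every ratio within absolute tolerance tol.
rational_approximation <- function(freqs, max_int = 32, tol = 1e-3) {
  r <- freqs / min(freqs)
  for (a in seq_len(max_int)) {
    v <- round(a * r)
    if (all(v >= 1) && max(v) <= max_int && all(abs(v / a - r) <= tol)) {
      g <- Reduce(gcd2, v)
      return(list(rational = TRUE, triple = as.integer(v / g)))
    }
  }
  list(rational = FALSE, triple = NULL)
}

gcd2 <- function(p, q) if (q == 0) p else gcd2(q, p %% q)
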