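#' @include bands.R
NULL

# Internal filter and transform primitives shared by the signal module and
# the synthetic generator, so simulated carriers pass through the exact
# filter design the analysis uses.

# Zero-phase band-pass: 4th-order Butterworth run forward and backward
# (magnitude response squared, no phase distortion). `x` is a vector.
.zeroPhaseBandpass <- function(x, fs, low, high, order = 4L) {
  stopifnot(low > 0, high > low, high < fs / 2)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# Zero-phase low-pass, same construction.
.zeroPhaseLowpass <- function(x, fs, cutoff, order = 4L) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

# Discrete analytic signal of a real vector via the FFT construction:
# double the positive frequencies, zero the negative ones, keep DC and
# Nyquist. The real part of the result equals the input to rounding error.
.fftAnalytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1
    w[n / 2L + 1L] <- 1
    w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1
    w[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

# Anti-aliased decimation by block averaging: boxcar low-pass over
# non-overlapping windows of `m` samples, then one value per block.
.blockDecimate <- function(x, m) {
  nb <- floor(length(x) / m)
  if (nb < 1L) stop("decimation factor exceeds the signal length")
  colMeans(matrix(x[seq_len(nb * m)], nrow = m))
}

# Transient margin for phase statistics: one cycle of the band's low edge
# (or 100 ms for broadband), capped at a tenth of the epoch.
.edgeMargin <- function(fs, band, epochLen) {
  lim <- bandLimits(band)
  m <- if (is.null(lim)) ceiling(0.1 * fs) else ceiling(fs / lim[1L])
  as.integer(min(m, floor(epochLen / 10)))
}
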