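# Independent brute-force implementations of each metric's defining
# equation, written as direct per-sample transliterations (explicit loops,
# no shared code with the package internals). Used to freeze expected
# values and for the oracle-equivalence acceptance test.

oraclePLV <- function(h1, h2) {
  acc <- 0 + 0i
  for (t in seq_along(h1))
    acc <- acc + exp(1i * (Arg(h1[t]) - Arg(h2[t])))
  Mod(acc / length(h1))
}

oraclePLI <- function(h1, h2) {
  s <- 0
  for (t in seq_along(h1)) {
    d <- sin(Arg(h1[t]) - Arg(h2[t]))
    s <- s + sign(d)
  }
  abs(s / length(h1))
}

oracleWPLI <- function(h1, h2) {
  num <- 0; den <- 0
  for (t in seq_along(h1)) {
    term <- Mod(h1[t]) * Mod(h2[t]) * sin(Arg(h1[t]) - Arg(h2[t]))
    num <- num + term
    den <- den + abs(term)
  }
  if (den == 0) 0 else abs(num) / den
}

oraclePhaseMI <- function(h1, h2, nBins = 16L) {
  p1 <- Arg(h1); p2 <- Arg(h2)
  binOf <- function(p) {
    b <- ceiling((p + pi) / (2 * pi) * nBins)
    min(max(b, 1L), nBins)
  }
  counts <- matrix(0, nBins, nBins)
  for (t in seq_along(p1)) {
    counts[binOf(p1[t]), binOf(p2[t])] <-
      counts[binOf(p1[t]), binOf(p2[t])] + 1
  }
  p <- counts / sum(counts)
  I <- 0; E <- 0
  for (i in seq_len(nBins)) for (j in seq_len(nBins)) {
    if (p[i, j] > 0) {
      E <- E - p[i, j] * log(p[i, j])
      I <- I + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
    }
  }
  I / E
}

# Welch cross-spectral density between two channels: direct transliteration
# with explicit segment loop (Hamming taper, 50% overlap, mean removal).
oracleCrossSpectrum <- function(x1, x2, fs, windowS = 10, overlap = 0.5) {
  L <- floor(windowS * fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  step <- floor(L * (1 - overlap))
  starts <- seq(1, length(x1) - L + 1, by = step)
  nf <- floor(L / 2) + 1
  S11 <- S22 <- S12 <- complex(nf)
  for (s0 in starts) {
    a <- x1[s0:(s0 + L - 1)]; a <- (a - mean(a)) * w
    b <- x2[s0:(s0 + L - 1)]; b <- (b - mean(b)) * w
    A <- fft(a)[1:nf]; B <- fft(b)[1:nf]
    S11 <- S11 + A * Conj(A)
    S22 <- S22 + B * Conj(B)
    S12 <- S12 + A * Conj(B)
  }
  sc <- 1 / (fs * sum(w^2) * length(starts))
  list(S11 = S11 * sc, S22 = S22 * sc, S12 = S12 * sc,
       freqs = (0:(nf - 1)) * fs / L)
}

oracleCoherency <- function(x1, x2, fs, windowS = 10, overlap = 0.5) {
  cs <- oracleCrossSpectrum(x1, x2, fs, windowS, overlap)
  list(C = cs$S12 / sqrt(Re(cs$S11) * Re(cs$S22)), freqs = cs$freqs)
}

bandMean <- function(v, freqs, band) {
  lim <- bandRegistry()[[band]]
  mean(v[freqs >= lim[1] & freqs < lim[2]])
}

# PSI for one epoch by direct summation over FFT bins within the band.
oraclePSI <- function(x1, x2, fs, band) {
  cs <- oracleCrossSpectrum(x1, x2, fs, windowS = length(x1) / fs,
                            overlap = 0)
  C <- cs$S12 / sqrt(Re(cs$S11) * Re(cs$S22))
  lim <- bandRegistry()[[band]]
  bins <- which(cs$freqs >= lim[1] & cs$freqs < lim[2])
  acc <- 0 + 0i
  for (k in bins[-length(bins)])
    acc <- acc + Conj(C[k]) * C[k + 1]
  Im(acc)
}

# PDC from a coefficient array by the closed-form definition.
oraclePDC <- function(A, fs, freqs) {
  n <- dim(A)[1]; p <- dim(A)[3]
  out <- matrix(0, n, n)
  for (f in freqs) {
    Ab <- diag(n) + 0i
    for (q in seq_len(p))
      Ab <- Ab - A[, , q] * exp(-2i * pi * f * q / fs)
    for (j in seq_len(n)) {
      cn <- sqrt(sum(Mod(Ab[, j])^2))
      out[, j] <- out[, j] + Mod(Ab[, j]) / cn
    }
  }
  out / length(freqs)
}

oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
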