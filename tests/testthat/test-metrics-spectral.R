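test_that("Welch autospectra peak at the tone frequency and are real", {
  ts <- toneTS(10, fs = 100, dur = 60)
  cs <- welchCrossSpectrum(ts, 10)
  auto <- Re(cs@S[1, 1, ])
  expect_equal(cs@freqs[which.max(auto)], 10)
  expect_true(all(auto >= 0))
  expect_equal(cs@deltaF, 0.1)
  # Hermitian slices
  set.seed(1)
  ns <- noiseTS(3, fs = 100, dur = 60, seed = 16)
  cs2 <- welchCrossSpectrum(ns, 10)
  k <- 42
  expect_equal(cs2@S[, , k], Conj(t(cs2@S[, , k])), tolerance = 1e-12)
  expect_error(welchCrossSpectrum(noiseTS(1, dur = 5), 10), "longer")
})

test_that("cross-spectrum matches the brute-force Welch oracle", {
  ts <- bandpass(noiseTS(2, fs = 100, dur = 60, seed = 17), "alpha")
  cs <- welchCrossSpectrum(ts, 10)
  o <- oracleCrossSpectrum(values(ts)[1, ], values(ts)[2, ], 100, 10)
  expect_equal(cs@S[1, 2, ], o$S12, tolerance = 1e-10)
  expect_equal(Re(cs@S[1, 1, ]), Re(o$S11), tolerance = 1e-10)
})

test_that("coherence of a signal with a scaled copy is 1 with zero IMC", {
  set.seed(18)
  x <- values(bandpass(noiseTS(1, fs = 100, dur = 60, seed = 18),
                       "alpha"))[1, ]
  ts <- TimeSeriesSet(rbind(x, 3.7 * x), fs = 100, band = "alpha")
  cs <- welchCrossSpectrum(ts, 10)
  expect_equal(values(coherenceMatrix(cs))[1, 2], 1, tolerance = 1e-10)
  expect_equal(values(imaginaryCoherency(cs))[1, 2], 0, tolerance = 1e-10)
})

test_that("a delayed copy has IMC matching the closed-form phase profile", {
  set.seed(19)
  x <- values(bandpass(noiseTS(1, fs = 100, dur = 120, seed = 19),
                       "alpha"))[1, ]
  tau <- 5L  # 50 ms delay
  ts <- TimeSeriesSet(rbind(x[1:(length(x) - tau)], x[(tau + 1):length(x)]),
                      fs = 100, band = "alpha")
  cs <- welchCrossSpectrum(ts, 10)
  bins <- which(cs@freqs >= 8 & cs@freqs < 13)
  C12 <- cs@S[1, 2, bins] /
    sqrt(Re(cs@S[1, 1, bins]) * Re(cs@S[2, 2, bins]))
  # x leads: S12 = <x1 x2*> carries phase -2 pi f tau (x2 delayed by tau)
  pred <- mean(sin(-2 * pi * cs@freqs[bins] * tau / 100) * Mod(C12))
  expect_equal(values(imaginaryCoherency(cs))[1, 2], pred,
               tolerance = 0.02)
})

test_that("independent channels stay below the Welch coherence null", {
  obs <- values(coherenceMatrix(
    welchCrossSpectrum(noiseTS(2, fs = 100, dur = 120, seed = 20),
                       10), "alpha"))[1, 2]
  # Monte-Carlo null (fixed seeds): 99th percentile of band-mean coherence
  null <- vapply(1:25, function(s)
    values(coherenceMatrix(
      welchCrossSpectrum(noiseTS(2, fs = 100, dur = 120, seed = 300 + s),
                         10), "alpha"))[1, 2], numeric(1))
  expect_lt(obs, quantile(null, 0.99) * 1.5)
})

test_that("two-node partial coherence equals ordinary coherence", {
  ts <- bandpass(noiseTS(2, fs = 100, dur = 60, seed = 21), "alpha")
  cs <- welchCrossSpectrum(ts, 10)
  expect_equal(values(partialCoherence(cs))[1, 2],
               values(coherenceMatrix(cs))[1, 2], tolerance = 1e-10)
})

test_that("diagonal cross-spectra give zero partials", {
  S <- array(0i, c(3, 3, 5))
  for (k in 1:5) S[, , k] <- diag(c(1, 2, 3)) + 0i
  cs <- new("CrossSpectrum", S = S, freqs = seq(8, 12, 1), deltaF = 1,
            windowSec = 1, taper = "hamming", nSegments = 8L,
            band = "alpha", subjectId = "s", sessionId = "r")
  expect_equal(max(abs(values(partialCoherence(cs))), na.rm = TRUE), 0)
  expect_equal(max(abs(values(imaginaryPartialCoherency(cs))),
                   na.rm = TRUE), 0)
})

test_that("partial coherence suppresses the indirect edge of a chain", {
  # VAR chain 1 -> 2 -> 3: marginally coherent 1-3, but not partially.
  # The sharp alpha resonators need long Welch windows: the smoothing
  # bias of short windows leaks real coherence into the partials.
  lag <- matrix(0, 3, 3); lag[2, 1] <- lag[3, 2] <- 0.5
  net <- new("GroundTruthNetwork", nNodes = 3L, edges = lag, lagged = lag,
             couplingMode = "ar_process")
  d <- studyDesign(nSubjects = 2, durationS = 960, fs = 100, seed = 5,
                   noiseSd = 0)
  s <- simulateSession(net, d, seed = 23)
  f <- bandpass(s, "alpha")
  cs <- welchCrossSpectrum(f, 40)
  coh <- values(coherenceMatrix(cs))
  pc <- values(partialCoherence(cs))
  # null bound from matched uncoupled simulations, same estimator
  null <- vapply(1:12, function(k) {
    s0 <- simulateSession(makeNetwork(3, 0, seed = 1,
                                      couplingMode = "ar_process"),
                          d, seed = 400 + k)
    cs0 <- welchCrossSpectrum(bandpass(s0, "alpha"), 40)
    max(values(partialCoherence(cs0))[upper.tri(diag(3))])
  }, numeric(1))
  expect_gt(coh[1, 3], max(null))     # indirect edge visible marginally
  expect_lt(pc[1, 3], quantile(null, 0.99))  # suppressed partially
  expect_gt(pc[1, 2], 1.5 * pc[1, 3])   # direct edges dominate
})

test_that("PSI is antisymmetric, zero for identical signals, sign-correct", {
  set.seed(24)
  ts <- bandpass(noiseTS(3, fs = 100, dur = 60, seed = 24), "alpha")
  m <- values(phaseSlopeIndex(ts, "alpha", 10))
  m[is.na(m)] <- 0
  expect_equal(m, -t(m), tolerance = 1e-12)

  x <- values(ts)[1, ]
  same <- TimeSeriesSet(rbind(x, x), fs = 100, band = "alpha")
  expect_equal(values(phaseSlopeIndex(same, "alpha", 10))[1, 2], 0,
               tolerance = 1e-10)

  # node 1 leading a delayed copy: PSI(leader, laggard) > 0, equal to
  # the brute-force summation oracle
  tau <- 3L
  lead <- TimeSeriesSet(rbind(x[(tau + 1):length(x)],
                              x[1:(length(x) - tau)]),
                        fs = 100, band = "alpha")
  p <- phaseSlopeIndex(lead, "alpha", 10)
  expect_gt(values(p)[1, 2], 0)
  # brute-force per-epoch summation oracle
  o <- vapply(seq_len(5), function(e) {
    idx <- ((e - 1) * 1000 + 1):(e * 1000)
    oraclePSI(values(lead)[1, idx], values(lead)[2, idx], 100, "alpha")
  }, numeric(1))
  expect_equal(values(p)[1, 2], mean(o), tolerance = 1e-10)
})
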