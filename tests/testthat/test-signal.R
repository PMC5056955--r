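test_that("band-pass preserves in-band tones and rejects out-of-band", {
  inTone <- toneTS(10, fs = 100, dur = 20)
  f <- bandpass(inTone, "alpha")
  mid <- 500:1500  # avoid filter start-up
  expect_equal(sd(values(f)[1, mid]), sd(values(inTone)[1, mid]),
               tolerance = 0.01)

  outTone <- toneTS(40, fs = 200, dur = 20)
  g <- bandpass(outTone, "alpha")  # 40 Hz is > 1 octave above 13 Hz
  attenDb <- 20 * log10(sd(values(g)[1, mid]) / sd(values(outTone)[1, mid]))
  expect_lt(attenDb, -40)

  expect_error(bandpass(toneTS(10, fs = 20, dur = 5), "alpha"), "Nyquist")
})

test_that("band-passed white noise keeps < 5% spectral mass out of band", {
  ts <- noiseTS(1, fs = 100, dur = 60, seed = 4)
  f <- bandpass(ts, "alpha")
  x <- values(f)[1, ]
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) / length(x) * 100
  half <- freqs <= 50
  inBand <- half & freqs >= 8 & freqs < 13
  expect_lt(sum(spec[half & !inBand]) / sum(spec[half]), 0.05)
})

test_that("analytic signal of a cosine has unit modulus and advancing phase", {
  fs <- 100
  a <- analytic(toneTS(10, fs = fs, dur = 4, band = "alpha"))
  mid <- 50:350
  expect_equal(Mod(a@h[1, mid]), rep(1, length(mid)), tolerance = 1e-3)
  dphi <- diff(Arg(a@h[1, mid]))
  dphi <- (dphi + pi) %% (2 * pi) - pi   # unwrap single steps
  expect_equal(mean(dphi), 2 * pi * 10 / fs, tolerance = 1e-3)
})

test_that("sin and cos of one frequency are in quadrature", {
  fs <- 100
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ts <- TimeSeriesSet(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)),
                      fs = fs, band = "alpha")
  a <- analytic(ts)
  mid <- 50:350
  dphi <- Arg(a@h[1, mid]) - Arg(a@h[2, mid])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(dphi, rep(pi / 2, length(mid)), tolerance = 1e-2)
})

test_that("analytic real part is exact and power identity holds", {
  ts <- bandpass(noiseTS(1, fs = 100, dur = 30, seed = 7), "alpha")
  a <- analytic(ts)
  expect_equal(Re(a@h[1, ]), values(ts)[1, ], tolerance = 1e-12)
  x <- values(ts)[1, ] - mean(values(ts)[1, ])
  # mean |h|^2 = 2 var(s) for zero-mean band-limited signals
  expect_equal(mean(Mod(a@h[1, ])^2), 2 * mean(x^2), tolerance = 0.02)
})

test_that("Hilbert transform is linear", {
  ts <- bandpass(noiseTS(2, fs = 100, dur = 10, seed = 8), "alpha")
  x <- values(ts)[1, ]; y <- values(ts)[2, ]
  comb <- TimeSeriesSet(rbind(x, y, 2 * x - 3 * y), fs = 100,
                        band = "alpha")
  a <- analytic(comb)
  expect_equal(a@h[3, ], 2 * a@h[1, ] - 3 * a@h[2, ], tolerance = 1e-9)
})

test_that("analytic-of-bandpass commutes with channel permutation", {
  ts <- noiseTS(4, fs = 100, dur = 10, seed = 9)
  perm <- c(3, 1, 4, 2)
  a1 <- analytic(bandpass(ts, "alpha"))
  tsP <- TimeSeriesSet(values(ts)[perm, ], fs = 100)
  a2 <- analytic(bandpass(tsP, "alpha"))
  expect_equal(a2@h, a1@h[perm, ], tolerance = 1e-12)
})

test_that("constant channel is rejected for phase analysis", {
  ts <- TimeSeriesSet(rbind(rnorm(500), rep(1, 500)), fs = 100,
                      band = "alpha")
  expect_error(analytic(ts), "zero-variance")
})

test_that("epoching follows integer division and rejects short sessions", {
  ts <- bandpass(noiseTS(2, fs = 50, dur = 360, seed = 10), "alpha")
  expect_equal(nrow(epochSignal(ts, 10)@epochs), 36L)
  expect_equal(nrow(epochSignal(ts, 2)@epochs), 180L)
  short <- bandpass(noiseTS(2, fs = 50, dur = 9.5, seed = 10), "alpha")
  expect_error(epochSignal(short, 10), "shorter than one epoch")
})

test_that("envelope has the expected rate, recovers modulators and scales", {
  fs <- 100
  dur <- 360
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  modu <- 1 + 0.5 * sin(2 * pi * 0.1 * t)
  x <- modu * cos(2 * pi * 10 * t)
  ts <- TimeSeriesSet(rbind(x, cos(2 * pi * 10 * t)), fs = fs,
                      band = "alpha")
  e <- powerEnvelope(analytic(ts), log = FALSE)
  expect_equal(ncol(values(e)), 180L)
  # AM tone: envelope tracks the 0.1 Hz modulator
  m <- round(fs / 0.5)
  moduDec <- colMeans(matrix(modu[1:(180 * m)], nrow = m))
  expect_gt(cor(values(e)[1, ], moduDec), 0.95)
  # constant-amplitude tone: log envelope variance ~ 0
  eLog <- powerEnvelope(analytic(ts))
  expect_lt(var(values(eLog)[2, ]), 1e-4)
})

test_that("scaling a signal shifts its log envelope by log(alpha)", {
  ts <- bandpass(noiseTS(1, fs = 100, dur = 60, seed = 11), "alpha")
  x <- values(ts)[1, ]
  both <- TimeSeriesSet(rbind(x, 5 * x), fs = 100, band = "alpha")
  e <- powerEnvelope(analytic(both))
  expect_equal(values(e)[2, ] - values(e)[1, ],
               rep(log(5), ncol(values(e))), tolerance = 1e-9)
})
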