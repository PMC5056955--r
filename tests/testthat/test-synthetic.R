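test_that("network density and strengths behave as designed", {
  # density 1 on 2 nodes forces the single edge
  n2 <- makeNetwork(2, density = 1, strengthRange = c(0.7, 0.7), seed = 1)
  expect_equal(n2@edges, matrix(c(0, 0.7, 0.7, 0), 2))

  n0 <- makeNetwork(10, density = 0, seed = 1)
  expect_true(all(n0@edges == 0))

  # density 0.3 over 45 possible edges: count inside the binomial 99% CI
  counts <- vapply(1:20, function(s)
    sum(makeNetwork(10, 0.3, seed = s)@edges[upper.tri(diag(10))] > 0),
    numeric(1))
  expect_gte(min(counts), qbinom(0.005, 45, 0.3))
  expect_lte(max(counts), qbinom(0.995, 45, 0.3))

  expect_error(makeNetwork(1, 0.5), "at least 2 nodes")
})

test_that("simulation is bit-reproducible from its seed", {
  d <- studyDesign(nSubjects = 2, durationS = 20, fs = 100, seed = 5)
  net <- makeNetwork(4, 0.5, c(0.15, 0.35), seed = 2)
  s1 <- simulateSession(net, d, seed = 99)
  s2 <- simulateSession(net, d, seed = 99)
  expect_identical(values(s1), values(s2))
  st1 <- generateStudy(net, studyDesign(nSubjects = 2, durationS = 10,
                                        fs = 100, epochS = 5, seed = 7))
  st2 <- generateStudy(net, studyDesign(nSubjects = 2, durationS = 10,
                                        fs = 100, epochS = 5, seed = 7))
  expect_identical(values(st1$sessions[[3]]), values(st2$sessions[[3]]))
})

test_that("uncoupled pair stays below the AEC null bound", {
  d <- studyDesign(nSubjects = 2, durationS = 360, fs = 100, seed = 5,
                   noiseSd = 0.2)
  net <- makeNetwork(4, density = 0, seed = 3)
  s <- simulateSession(net, d, seed = 21)
  e <- powerEnvelope(analytic(bandpass(s, "alpha")))
  r <- values(aec(e))
  # 99% two-sided null bound for a Pearson correlation at 180 samples
  bound <- tanh(qnorm(0.995) / sqrt(180 - 3))
  expect_lt(max(abs(r[upper.tri(r)])), bound + 0.05)
})

test_that("designed envelope correlation is recovered by AEC", {
  d <- studyDesign(nSubjects = 2, durationS = 360, fs = 100, seed = 5,
                   noiseSd = 0.2)
  s <- simulateSession(pairNetwork(0.7, "envelope"), d, seed = 42)
  e <- powerEnvelope(analytic(bandpass(s, "alpha")))
  expect_equal(ncol(values(e)), 180L)
  expect_lt(abs(values(aec(e))[1, 2] - 0.7), 0.15)
})

test_that("a fixed phase-lag pair with minimal jitter gives PLI near 1", {
  d <- studyDesign(nSubjects = 2, durationS = 120, fs = 100, seed = 5,
                   noiseSd = 0)
  s <- simulateSession(pairNetwork(0.995, "phase_lag"), d, seed = 43,
                       phaseLag = pi / 2)
  a <- epochSignal(bandpass(s, "alpha"), 10)
  expect_gt(values(pli(a))[1, 2], 0.97)
  expect_gt(values(plv(a))[1, 2], 0.95)
})

test_that("phase-lag coupling strength calibrates the phase-locking value", {
  d <- studyDesign(nSubjects = 2, durationS = 360, fs = 100, seed = 5,
                   noiseSd = 0)
  for (target in c(0.5, 0.8)) {
    s <- simulateSession(pairNetwork(target, "phase_lag"), d, seed = 17)
    a <- epochSignal(bandpass(s, "alpha"), 10)
    expect_lt(abs(values(plv(a))[1, 2] - target), 0.12)
  }
})

test_that("leakage mixing is zero-lag only", {
  d <- studyDesign(nSubjects = 2, durationS = 60, fs = 100, seed = 5,
                   noiseSd = 0)
  net <- makeNetwork(4, density = 0, seed = 3)
  s <- simulateSession(net, d, leakage = ringLeakage(4, 0.4), seed = 31)
  f <- bandpass(s, "alpha")
  x <- values(f)[1, ]; y <- values(f)[2, ]
  cc <- ccf(x, y, lag.max = 100, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
  expect_gt(abs(cor(x, y)), 0.2)  # mixing induces zero-lag correlation
})

test_that("unstable AR coupling is rejected with a diagnostic", {
  d <- studyDesign(nSubjects = 2, durationS = 20, fs = 100, seed = 5)
  lag <- matrix(0, 3, 3); lag[1, 2] <- lag[2, 3] <- lag[3, 1] <- 0.9
  net <- new("GroundTruthNetwork", nNodes = 3L, edges = lag, lagged = lag,
             couplingMode = "ar_process")
  expect_error(simulateSession(net, d, seed = 1), "unstable")
})

test_that("stable AR mode passes the companion stability check", {
  d <- studyDesign(nSubjects = 2, durationS = 30, fs = 100, seed = 5,
                   noiseSd = 0)
  lag <- matrix(0, 3, 3); lag[2, 1] <- lag[3, 2] <- 0.15
  net <- new("GroundTruthNetwork", nNodes = 3L, edges = lag, lagged = lag,
             couplingMode = "ar_process")
  s <- simulateSession(net, d, seed = 12)
  expect_true(all(is.finite(values(s))))
  expect_equal(nSamples(s), 3000L)
})

test_that("study bookkeeping and subject perturbation follow the design", {
  net <- makeNetwork(6, 0.4, c(0.15, 0.35), seed = 4)
  d0 <- studyDesign(nSubjects = 6, nSessions = 3, durationS = 10,
                    fs = 100, subjectSd = 0, epochS = 5, seed = 8)
  st <- generateStudy(net, d0)
  expect_length(st$sessions, 18L)
  expect_equal(table(vapply(st$sessions, subjectId, character(1))),
               table(rep(sprintf("s%02d", 1:6), each = 3)))
  # subjectSd = 0: all subjects share the group network
  expect_true(all(vapply(st$networks, function(n)
    identical(n@edges, net@edges), logical(1))))

  # subjectSd > 0: per-subject spread of a true edge matches the setting
  dV <- studyDesign(nSubjects = 40, nSessions = 2, durationS = 10,
                    fs = 100, subjectSd = 0.08, epochS = 5, seed = 9)
  netV <- makeNetwork(4, 1, strengthRange = c(0.5, 0.5), seed = 4)
  stV <- generateStudy(netV, dV)
  edge <- vapply(stV$networks, function(n) n@edges[1, 2], numeric(1))
  expect_lt(abs(sd(edge) - 0.08), 0.03)
  expect_lt(abs(mean(edge) - 0.5), 0.03)
})

test_that("leakage models are validated", {
  expect_error(new("LeakageModel",
                   mixing = matrix(1, 3, 3)))  # singular
  M <- ringLeakage(5, 0.3)@mixing
  expect_equal(diag(M), rep(1, 5))
  expect_equal(M, t(M))
})
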