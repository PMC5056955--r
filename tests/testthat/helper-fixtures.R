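# Shared fixtures: small signals, sessions and hand-built containers.

toneTS <- function(freq, fs = 100, dur = 10, phase = 0, amp = 1,
                   band = "broadband") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  TimeSeriesSet(rbind(amp * cos(2 * pi * freq * t + phase)),
                fs = fs, band = band)
}

noiseTS <- function(n = 2, fs = 100, dur = 10, seed = 1,
                    band = "broadband") {
  set.seed(seed)
  TimeSeriesSet(matrix(rnorm(n * fs * dur), n), fs = fs, band = band)
}

# AnalyticSet with prescribed complex values (single whole epoch, no
# transient margin) — lets tests set phases/amplitudes exactly.
analyticFrom <- function(h, fs = 100, band = "alpha") {
  new("AnalyticSet", h = h, fs = fs, band = band,
      epochs = cbind(start = 1L, end = ncol(h)), edgeSamples = 0L,
      subjectId = "s1", sessionId = "r1")
}

envelopeFrom <- function(env, rate = 0.5) {
  new("EnvelopeSet", env = env, rate = rate, logTransformed = TRUE,
      band = "alpha", subjectId = "s1", sessionId = "r1")
}

# Undirected connectivity matrix with given edge values (upper triangle),
# for reliability-suite tests that need no signal pipeline.
cmFrom <- function(edges, n, metric = "pli", subject = "s1",
                   session = "r1") {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- edges
  M <- M + t(M)
  diag(M) <- NA_real_
  new("ConnectivityMatrix", values = M, metric = metric, directed = FALSE,
      leakageCorrected = FALSE, flags = matrix(FALSE, n, n),
      band = "alpha", subjectId = subject, sessionId = session)
}

# A StudyNetworks built from per-session edge vectors (list of numeric).
studyFromEdges <- function(edgeList, subjects, sessions, n,
                           metric = "pli") {
  mats <- mapply(function(e, su, se) cmFrom(e, n, metric, su, se),
                 edgeList, subjects, sessions, SIMPLIFY = FALSE)
  studyNetworks(mats)
}

pairNetwork <- function(strength, mode = "envelope", n = 2L) {
  e <- matrix(0, n, n)
  e[1, 2] <- e[2, 1] <- strength
  new("GroundTruthNetwork", nNodes = n, edges = e,
      lagged = matrix(0, n, n), couplingMode = mode)
}
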