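#' @include metrics-phase.R
NULL

#' Welch estimate of the cross-spectral density
#'
#' Segments the session into Hamming-tapered windows (default 10 s, 50%
#' overlap), removes each segment's mean, and averages the per-segment
#' cross-periodograms into one Hermitian cross-spectral density matrix per
#' frequency bin. The one-sided grid runs from 0 Hz to the Nyquist
#' frequency with resolution `1 / windowS`.
#'
#' @param ts a \linkS4class{TimeSeriesSet}.
#' @param windowS window length in seconds (default 10).
#' @param overlap fractional segment overlap (default 0.5).
#' @return a \linkS4class{CrossSpectrum}.
#' @export
welchCrossSpectrum <- function(ts, windowS = 10, overlap = 0.5) {
  stopifnot(is(ts, "TimeSeriesSet"))
  L <- floor(windowS * ts@fs)
  Tn <- ncol(ts@data)
  if (L > Tn)
    stop("Welch window (", L, " samples) longer than the session (", Tn,
         " samples)", call. = FALSE)
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, Tn - L + 1L, by = step)
  w <- signal::hamming(L)
  scale <- 1 / (ts@fs * sum(w^2))
  n <- nrow(ts@data)
  nf <- floor(L / 2) + 1L
  S <- array(complex(real = 0), c(n, n, nf))
  for (s0 in starts) {
    seg <- ts@data[, s0:(s0 + L - 1L), drop = FALSE]
    seg <- (seg - rowMeans(seg)) * rep(w, each = n)
    Fm <- stats::mvfft(t(seg))[seq_len(nf), , drop = FALSE]  # nf x n
    for (k in seq_len(nf))
      S[, , k] <- S[, , k] + outer(Fm[k, ], Conj(Fm[k, ])) * scale
  }
  S <- S / length(starts)
  new("CrossSpectrum", S = S, freqs = (seq_len(nf) - 1L) * ts@fs / L,
      deltaF = ts@fs / L, windowSec = windowS, taper = "hamming",
      nSegments = length(starts), band = ts@band,
      subjectId = ts@subjectId, sessionId = ts@sessionId)
}

# Frequency-bin indices whose centre lies in [low, high) — half-open band
# convention used everywhere.
.bandBins <- function(cs, band) {
  lim <- bandLimits(band)
  if (is.null(lim)) stop("a named band is required for band averaging")
  idx <- which(cs@freqs >= lim[1L] & cs@freqs < lim[2L])
  if (length(idx) == 0L)
    stop("no frequency bins inside band '", band, "'", call. = FALSE)
  idx
}

# Coherency slices C(f) = S(f) normalised by the autospectra.
.coherency <- function(cs, bins) {
  lapply(bins, function(k) {
    d <- Re(diag(cs@S[, , k]))
    if (any(d <= 0)) stop("zero autospectrum at ", cs@freqs[k], " Hz")
    cs@S[, , k] / sqrt(outer(d, d))
  })
}

.bandAverage <- function(slices, f) {
  Reduce(`+`, lapply(slices, f)) / length(slices)
}

# Im(C_ij) is antisymmetric under pair swap; as an undirected edge
# strength the upper-triangle (i < j) sign is kept and mirrored.
.mirrorUpper <- function(M) {
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

#' Band-averaged coherence
#'
#' Coherency is the cross-spectral density normalised by the autospectra;
#' coherence is its modulus, averaged over the bins of the requested band.
#' It measures a constant relative phase at each frequency and is inflated
#' by zero-lag leakage.
#'
#' @param cs a \linkS4class{CrossSpectrum}.
#' @param band a band name covered by the evaluated frequencies.
#' @return an undirected \linkS4class{ConnectivityMatrix}, values in
#'   \[0, 1\].
#' @export
coherenceMatrix <- function(cs, band = cs@band) {
  C <- .coherency(cs, .bandBins(cs, band))
  .connMatrix(.bandAverage(C, Mod), "coh", directed = FALSE, a = cs)
}

#' Band-averaged imaginary part of coherency
#'
#' The imaginary part of coherency vanishes for interactions with no phase
#' difference, making it insensitive to zero-lag leakage. `Im C_ij` is
#' antisymmetric under pair swap, so the undirected edge strength keeps
#' the upper-triangle (i < j) sign.
#'
#' @inheritParams coherenceMatrix
#' @return an undirected \linkS4class{ConnectivityMatrix}, values in
#'   \[-1, 1\].
#' @export
imaginaryCoherency <- function(cs, band = cs@band) {
  C <- .coherency(cs, .bandBins(cs, band))
  .connMatrix(.mirrorUpper(.bandAverage(C, Im)), "imc",
              directed = FALSE, a = cs)
}

# Inverse cross-spectral slices, ridge-regularised when ill-conditioned.
.inverseSlices <- function(cs, bins, ridge = 1e-8, condMax = 1e12) {
  lapply(bins, function(k) {
    Sk <- cs@S[, , k]
    kap <- kappa(Sk, exact = TRUE)
    if (!is.finite(kap) || kap > condMax) {
      warning("cross-spectrum near-singular at ", cs@freqs[k],
              " Hz; applying ridge regularisation")
      Sk <- Sk + ridge * mean(Re(diag(Sk))) * diag(nrow(Sk))
    }
    solve(Sk)
  })
}

# Normalised inverse cross-spectral density (partial coherency) per slice.
.partialCoherency <- function(cs, bins, ...) {
  lapply(.inverseSlices(cs, bins, ...), function(G) {
    d <- Re(diag(G))
    G / sqrt(outer(d, d))
  })
}

#' Band-averaged partial coherence
#'
#' Partial coherency is the normalised inverse of the cross-spectral
#' density: two signals are partially coherent if they remain coherent
#' conditional on the spectra of all other signals. Partial coherence is
#' its band-averaged magnitude.
#'
#' @inheritParams coherenceMatrix
#' @param ridge ridge factor applied (with a warning) when a slice's
#'   condition number exceeds `condMax`.
#' @param condMax condition-number threshold for regularisation.
#' @return an undirected \linkS4class{ConnectivityMatrix}, values in
#'   \[0, 1\].
#' @export
partialCoherence <- function(cs, band = cs@band, ridge = 1e-8,
                             condMax = 1e12) {
  P <- .partialCoherency(cs, .bandBins(cs, band), ridge = ridge,
                         condMax = condMax)
  .connMatrix(.bandAverage(P, Mod), "pcoh", directed = FALSE, a = cs)
}

#' Band-averaged imaginary part of partial coherency
#'
#' @inheritParams partialCoherence
#' @return an undirected \linkS4class{ConnectivityMatrix}, values in
#'   \[-1, 1\].
#' @export
imaginaryPartialCoherency <- function(cs, band = cs@band, ridge = 1e-8,
                                      condMax = 1e12) {
  P <- .partialCoherency(cs, .bandBins(cs, band), ridge = ridge,
                         condMax = condMax)
  .connMatrix(.mirrorUpper(.bandAverage(P, Im)), "impc",
              directed = FALSE, a = cs)
}

# PSI for one cross-spectrum: Im sum_f Conj(C(f)) C(f + df) over band bins.
.psiOne <- function(cs, band) {
  bins <- .bandBins(cs, band)
  if (length(bins) < 2L)
    stop("phase slope index needs at least two frequency bins in the band")
  C <- .coherency(cs, seq_len(dim(cs@S)[3L]))
  acc <- matrix(0, dim(cs@S)[1L], dim(cs@S)[2L])
  for (k in bins[-length(bins)])
    acc <- acc + Im(Conj(C[[k]]) * C[[k + 1L]])
  acc
}

#' Phase slope index
#'
#' A directed phase-synchronisation index formed from the slope of the
#' cross-spectral phase across frequencies: `Im sum_f C*(f) C(f + df)`
#' over the band, where C is coherency and `df` the frequency resolution.
#' A positive value for edge (i, j) indicates that i leads j. The index is
#' antisymmetric and insensitive to zero-lag leakage. It is computed in the
#' same epochs as the other phase metrics, averaging over epochs.
#'
#' @param x a \linkS4class{TimeSeriesSet} (epoched internally), a single
#'   \linkS4class{CrossSpectrum}, or a list of per-epoch cross-spectra.
#' @param band band name.
#' @param epochS epoch length in seconds when `x` is a time series; each
#'   epoch contributes a single Hamming-tapered cross-periodogram.
#' @return a directed, antisymmetric \linkS4class{ConnectivityMatrix}.
#' @export
phaseSlopeIndex <- function(x, band = NULL, epochS = 10) {
  if (is(x, "TimeSeriesSet")) {
    if (is.null(band)) band <- x@band
    bounds <- .epochBounds(ncol(x@data), x@fs, epochS)
    x <- lapply(seq_len(nrow(bounds)), function(e) {
      seg <- TimeSeriesSet(x@data[, bounds[e, 1L]:bounds[e, 2L],
                                  drop = FALSE],
                           fs = x@fs, band = x@band,
                           subjectId = x@subjectId, sessionId = x@sessionId)
      welchCrossSpectrum(seg, windowS = epochS, overlap = 0)
    })
  }
  if (is(x, "CrossSpectrum")) x <- list(x)
  if (is.null(band)) band <- x[[1L]]@band
  M <- Reduce(`+`, lapply(x, .psiOne, band = band)) / length(x)
  .connMatrix(M, "psi", directed = TRUE, a = x[[1L]])
}
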