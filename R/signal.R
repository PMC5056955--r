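#' @include TimeSeriesSet-methods.R filters.R
NULL

#' Band-pass filter a session into a named oscillatory band
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' to every node. The two-pass design squares the magnitude response, giving
#' at least 40 dB attenuation one octave outside the passband edges while
#' leaving phase untouched — phase metrics downstream rely on this.
#'
#' @param ts a \linkS4class{TimeSeriesSet}.
#' @param band a band name from [bandRegistry()].
#' @param order Butterworth order for a single pass (default 4).
#' @return a \linkS4class{TimeSeriesSet} labelled with `band`.
#' @examples
#' t <- seq(0, 10, by = 1 / 100)
#' ts <- TimeSeriesSet(rbind(sin(2 * pi * 10 * t)), fs = 100)
#' alpha <- bandpass(ts, "alpha")
#' @export
bandpass <- function(ts, band, order = 4L) {
  stopifnot(is(ts, "TimeSeriesSet"))
  lim <- bandLimits(band)
  if (is.null(lim)) stop("bandpass needs a named band, not 'broadband'")
  if (lim[2L] >= ts@fs / 2)
    stop("band '", band, "' reaches the Nyquist frequency at fs = ", ts@fs,
         " Hz", call. = FALSE)
  filt <- t(apply(ts@data, 1L, .zeroPhaseBandpass,
                  fs = ts@fs, low = lim[1L], high = lim[2L], order = order))
  TimeSeriesSet(filt, fs = ts@fs, band = band,
                subjectId = ts@subjectId, sessionId = ts@sessionId)
}

#' Analytic signal of each node via the Hilbert transform
#'
#' Computes the complex analytic extension h = s + i*H\[s\] by the FFT
#' construction, independently within each epoch (one whole-session epoch if
#' the input is not epoched). The instantaneous amplitude is `Mod(h)` and
#' the instantaneous phase `Arg(h)`. A transient margin at each epoch edge —
#' one cycle of the band's low-frequency edge — is flagged for exclusion
#' from phase statistics.
#'
#' @param ts a \linkS4class{TimeSeriesSet}. A warning is issued for
#'   broadband input, where instantaneous phase is poorly defined.
#' @param epochS optional epoch length in seconds; when given, the Hilbert
#'   transform is taken within each non-overlapping epoch.
#' @return an \linkS4class{AnalyticSet}.
#' @examples
#' t <- seq(0, 2, by = 1 / 100)
#' a <- analytic(TimeSeriesSet(rbind(cos(2 * pi * 10 * t)), fs = 100,
#'                             band = "alpha"))
#' range(Mod(a@h))
#' @export
analytic <- function(ts, epochS = NULL) {
  stopifnot(is(ts, "TimeSeriesSet"))
  if (identical(ts@band, "broadband"))
    warning("computing analytic signal of broadband data; ",
            "instantaneous phase assumes band-limited input")
  v <- apply(ts@data, 1L, stats::var)
  if (any(v == 0))
    stop("constant (zero-variance) channel(s): ",
         paste(which(v == 0), collapse = ", "),
         "; instantaneous phase is degenerate", call. = FALSE)
  n <- ncol(ts@data)
  epochs <- if (is.null(epochS)) {
    cbind(start = 1L, end = n)
  } else {
    .epochBounds(n, ts@fs, epochS)
  }
  h <- matrix(complex(real = 0), nrow = nrow(ts@data), ncol = n)
  for (e in seq_len(nrow(epochs))) {
    idx <- epochs[e, 1L]:epochs[e, 2L]
    for (i in seq_len(nrow(ts@data)))
      h[i, idx] <- .fftAnalytic(ts@data[i, idx])
  }
  epochLen <- epochs[1L, 2L] - epochs[1L, 1L] + 1L
  new("AnalyticSet", h = h, fs = ts@fs, band = ts@band, epochs = epochs,
      edgeSamples = .edgeMargin(ts@fs, ts@band, epochLen),
      subjectId = ts@subjectId, sessionId = ts@sessionId)
}

# Non-overlapping epoch boundaries; trailing partial epoch dropped.
.epochBounds <- function(n, fs, lengthS) {
  len <- floor(lengthS * fs)
  if (len < 2L) stop("epoch shorter than two samples")
  nEp <- floor(n / len)
  if (nEp < 1L)
    stop("session (", n, " samples) shorter than one epoch (", len,
         " samples)", call. = FALSE)
  cbind(start = (seq_len(nEp) - 1L) * len + 1L,
        end   = seq_len(nEp) * len)
}

#' Split a session (or analytic set) into non-overlapping epochs
#'
#' For a \linkS4class{TimeSeriesSet} this computes the analytic signal per
#' epoch (see [analytic()]); for an \linkS4class{AnalyticSet} it re-epochs
#' the stored epoch table (only from a whole-session transform, since the
#' Hilbert transform does not commute with re-windowing).
#'
#' @param x a \linkS4class{TimeSeriesSet} or \linkS4class{AnalyticSet}.
#' @param lengthS epoch length in seconds.
#' @return an epoched \linkS4class{AnalyticSet}.
#' @examples
#' ts <- TimeSeriesSet(matrix(rnorm(2 * 3600), 2), fs = 100, band = "alpha")
#' a <- epochSignal(bandpass(ts, "alpha"), lengthS = 10)
#' nrow(a@epochs)  # 3 full epochs of 10 s at 100 Hz in 36 s
#' @export
epochSignal <- function(x, lengthS) {
  if (is(x, "TimeSeriesSet")) return(analytic(x, epochS = lengthS))
  stopifnot(is(x, "AnalyticSet"))
  if (nrow(x@epochs) != 1L)
    stop("re-epoching an already-epoched AnalyticSet is not supported; ",
         "epoch the TimeSeriesSet instead")
  epochs <- .epochBounds(ncol(x@h), x@fs, lengthS)
  epochLen <- epochs[1L, 2L] - epochs[1L, 1L] + 1L
  new("AnalyticSet", h = x@h, fs = x@fs, band = x@band, epochs = epochs,
      edgeSamples = .edgeMargin(x@fs, x@band, epochLen),
      subjectId = x@subjectId, sessionId = x@sessionId)
}

#' Low-frequency (log) power envelopes
#'
#' Takes the instantaneous amplitude `Mod(h)` of each node, low-pass
#' filters it (default 1 Hz), decimates to a slow envelope rate (default
#' 0.5 Hz) with anti-aliased block averaging, and, by default, takes the
#' logarithm. Amplitude envelope correlation and its regularised partial
#' variant operate on these envelopes.
#'
#' Envelope values below `epsFactor` times the median envelope are floored
#' before the log, so silent segments cannot produce infinities; floored
#' samples are reported via a warning.
#'
#' @param a an \linkS4class{AnalyticSet} (epoch structure is ignored: the
#'   envelope is a slow, whole-session quantity).
#' @param lowpassHz envelope low-pass cutoff in Hz.
#' @param outRateHz output envelope sampling rate in Hz; must not exceed
#'   `2 * lowpassHz`.
#' @param log take the log of the envelope (default TRUE).
#' @param epsFactor envelope floor, as a fraction of the median envelope.
#' @return an \linkS4class{EnvelopeSet} with `floor(duration * outRateHz)`
#'   samples per node.
#' @export
powerEnvelope <- function(a, lowpassHz = 1, outRateHz = 0.5, log = TRUE,
                          epsFactor = 1e-12) {
  stopifnot(is(a, "AnalyticSet"))
  if (outRateHz > 2 * lowpassHz)
    stop("output rate ", outRateHz, " Hz exceeds twice the low-pass cutoff")
  env <- Mod(a@h)
  m <- round(a@fs / outRateHz)
  sm <- t(apply(env, 1L, function(x) {
    y <- .zeroPhaseLowpass(x, fs = a@fs, cutoff = lowpassHz, order = 2L)
    .blockDecimate(y, m)
  }))
  if (log) {
    flo <- epsFactor * stats::median(sm)
    nFloored <- sum(sm < flo)
    if (nFloored > 0L)
      warning(nFloored, " envelope sample(s) floored before log")
    sm <- base::log(pmax(sm, flo))
  }
  new("EnvelopeSet", env = sm, rate = a@fs / m, logTransformed = log,
      band = a@band, subjectId = a@subjectId, sessionId = a@sessionId)
}
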