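#' @include metrics-spectral.R
NULL

# Integer-factor decimation with a zero-phase anti-alias low-pass at 95%
# of the new Nyquist frequency.
.decimateTo <- function(X, fs, targetFs) {
  m <- max(1L, floor(fs / targetFs))
  if (m == 1L) return(list(X = X, fs = fs))
  fsNew <- fs / m
  Xf <- t(apply(X, 1L, .zeroPhaseLowpass, fs = fs,
                cutoff = 0.95 * fsNew / 2, order = 6L))
  list(X = Xf[, seq(1L, ncol(Xf), by = m), drop = FALSE], fs = fsNew)
}

#' Fit a vector-autoregressive model for spectral transfer analysis
#'
#' Fits an order-p multivariate AR model by ordinary least squares to the
#' (optionally resampled) session. For low-frequency bands the data are
#' first decimated to 2.5 times the band's highest frequency; for the beta
#' and gamma bands the fit is performed at the full sampling rate (the
#' narrow relative bandwidth makes decimated fits poor) with a
#' correspondingly longer lag structure. Defaults are 69 lags after
#' resampling and 201 lags at full rate, both configurable.
#'
#' @param ts a \linkS4class{TimeSeriesSet}.
#' @param band band name.
#' @param order model order; `NULL` selects the band-dependent default.
#' @param resample whether to decimate before fitting; `NULL` selects the
#'   band-dependent default (no resampling for beta/gamma bands).
#' @return an \linkS4class{ARTransferModel}; fitting fails with a
#'   diagnostic if the model is unstable or the regression ill-conditioned.
#' @export
fitVAR <- function(ts, band = ts@band, order = NULL, resample = NULL) {
  stopifnot(is(ts, "TimeSeriesSet"))
  lim <- bandLimits(band)
  if (is.null(lim)) stop("a named band is required")
  fullRateBand <- band %in% c("beta", "low_beta", "high_beta", "low_gamma")
  if (is.null(resample)) resample <- !fullRateBand
  if (is.null(order)) order <- if (resample) 69L else 201L
  order <- as.integer(order)
  if (order < 1L) stop("AR order must be at least 1")
  if (resample) {
    dec <- .decimateTo(ts@data, ts@fs, 2.5 * lim[2L])
    X <- dec$X; fsM <- dec$fs
  } else {
    X <- ts@data; fsM <- ts@fs
  }
  n <- nrow(X); Tn <- ncol(X)
  if (Tn - order < 2L * n * order)
    stop("too few samples (", Tn, ") for ", n, " nodes at order ", order,
         call. = FALSE)
  X <- X - rowMeans(X)
  Y <- t(X[, (order + 1L):Tn, drop = FALSE])            # T' x n
  D <- do.call(cbind, lapply(seq_len(order), function(p)
    t(X[, (order + 1L - p):(Tn - p), drop = FALSE])))   # T' x (n * order)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("AR design matrix is rank deficient (rank ", qrD$rank, " of ",
         ncol(D), "); reduce the order or lengthen the session",
         call. = FALSE)
  B <- qr.coef(qrD, Y)                                  # (n * order) x n
  A <- array(0, c(n, n, order))
  for (p in seq_len(order))
    A[, , p] <- t(B[((p - 1L) * n + 1L):(p * n), , drop = FALSE])
  res <- Y - D %*% B
  sigma <- crossprod(res) / (nrow(Y) - ncol(D))
  rad <- .companionRadius(A)
  if (rad >= 1)
    stop("fitted AR model is unstable (companion spectral radius ",
         format(rad, digits = 5), ")", call. = FALSE)
  new("ARTransferModel", A = A, order = order, sigma = sigma, fsModel = fsM,
      spectralRadius = rad, band = band,
      subjectId = ts@subjectId, sessionId = ts@sessionId)
}

# Spectral radius of the companion matrix of coefficient array A.
.companionRadius <- function(A) {
  n <- dim(A)[1L]; p <- dim(A)[3L]
  Cm <- matrix(0, n * p, n * p)
  for (q in seq_len(p)) Cm[seq_len(n), ((q - 1L) * n + 1L):(q * n)] <- A[, , q]
  if (p > 1L)
    Cm[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

# Frequency-domain coefficient transform Abar(f) = I - sum_p A_p e^{-i2pifp/fs}
.arTransform <- function(m, f) {
  n <- dim(m@A)[1L]
  Ab <- diag(n) + 0i
  for (p in seq_len(m@order))
    Ab <- Ab - m@A[, , p] * exp(-2i * pi * f * p / m@fsModel)
  Ab
}

#' Partial directed coherence
#'
#' A directed, frequency-domain measure of signal transfer derived from the
#' Fourier transform of the AR coefficients: with `Abar(f)` the inverse of
#' the model's transfer function, `PDC_ij(f) = |Abar_ij(f)| /
#' sqrt(sum_l |Abar_lj(f)|^2)`. Columns are normalised per frequency
#' (`sum_i PDC_ij(f)^2 = 1`) before averaging over the band grid.
#'
#' @param m an \linkS4class{ARTransferModel} from [fitVAR()].
#' @param band band name; must lie below the model's Nyquist frequency.
#' @param nFreq number of evaluation frequencies across the band.
#' @return a directed \linkS4class{ConnectivityMatrix}; diagonal NA.
#' @export
pdc <- function(m, band = m@band, nFreq = 64L) {
  stopifnot(is(m, "ARTransferModel"))
  lim <- bandLimits(band)
  if (is.null(lim)) stop("a named band is required")
  if (lim[2L] >= m@fsModel / 2)
    stop("band exceeds the model Nyquist frequency (",
         m@fsModel / 2, " Hz)", call. = FALSE)
  fg <- seq(lim[1L], lim[2L], length.out = nFreq)
  n <- dim(m@A)[1L]
  acc <- matrix(0, n, n)
  for (f in fg) {
    Ab <- .arTransform(m, f)
    cn <- sqrt(colSums(Mod(Ab)^2))
    if (any(cn == 0)) stop("degenerate AR transform at ", f, " Hz")
    acc <- acc + Mod(Ab) / rep(cn, each = n)
  }
  .connMatrix(acc / length(fg), "pdc", directed = TRUE, a = m)
}
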