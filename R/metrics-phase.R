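#' @include leakage.R
NULL

# Sample indices retained for phase statistics: each epoch minus the
# flagged transient margin at both edges.
.retainedIdx <- function(a) {
  m <- a@edgeSamples
  unlist(lapply(seq_len(nrow(a@epochs)), function(e) {
    s <- a@epochs[e, 1L] + m
    en <- a@epochs[e, 2L] - m
    if (s > en) stop("epoch shorter than twice the edge margin")
    s:en
  }))
}

.connMatrix <- function(values, metric, directed, a, flags = NULL,
                        leakageCorrected = FALSE) {
  diag(values) <- NA_real_
  if (is.null(flags))
    flags <- matrix(FALSE, nrow(values), ncol(values))
  new("ConnectivityMatrix", values = values, metric = metric,
      directed = directed, leakageCorrected = leakageCorrected,
      flags = flags, band = a@band,
      subjectId = a@subjectId, sessionId = a@sessionId)
}

#' Phase-locking value
#'
#' PLV between two signals is the modulus of the expected unit phasor of
#' their phase difference, `|<exp(i * dphi)>|`, the expectation running over
#' time and epochs. It is 1 for a constant phase relation (including zero
#' lag, which makes it sensitive to source leakage) and tends to 0 for
#' independent phases.
#'
#' @param a an (epoched) \linkS4class{AnalyticSet}.
#' @return an undirected \linkS4class{ConnectivityMatrix} with values in
#'   \[0, 1\]; diagonal NA.
#' @export
plv <- function(a) {
  stopifnot(is(a, "AnalyticSet"))
  idx <- .retainedIdx(a)
  E <- exp(1i * Arg(a@h[, idx, drop = FALSE]))
  M <- Mod(E %*% Conj(t(E))) / length(idx)
  .connMatrix(M, "plv", directed = FALSE, a = a)
}

#' Phase lag index
#'
#' PLI quantifies the asymmetry of the phase-difference distribution,
#' `|<sign sin(dphi)>|`, and is therefore insensitive to shared signal at
#' exactly zero (or pi) phase lag: `sign(sin 0) = 0`, so zero-lag leakage
#' contributes nothing.
#'
#' @inheritParams plv
#' @return an undirected \linkS4class{ConnectivityMatrix}, values in
#'   \[0, 1\].
#' @export
pli <- function(a) {
  stopifnot(is(a, "AnalyticSet"))
  idx <- .retainedIdx(a)
  H <- a@h[, idx, drop = FALSE]
  n <- nrow(H)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # Im(h_i conj(h_j)) = z_i z_j sin(phi_i - phi_j): same sign as
      # sin(dphi), with sign(0) = 0 so zero-lag samples contribute nothing
      M[i, j] <- M[j, i] <- abs(mean(sign(Im(H[i, ] * Conj(H[j, ])))))
    }
  }
  .connMatrix(M, "pli", directed = FALSE, a = a)
}

#' Weighted phase lag index
#'
#' wPLI weights each sample's contribution by the magnitude of the
#' imaginary cross-phasor, `|<Im(h1 conj(h2))>| / <|Im(h1 conj(h2))|>`,
#' down-weighting near-zero-lag samples relative to PLI. When no lagged
#' component exists anywhere (denominator zero) the edge is defined as 0
#' and flagged.
#'
#' @inheritParams plv
#' @return an undirected \linkS4class{ConnectivityMatrix}, values in
#'   \[0, 1\]; degenerate edges flagged.
#' @export
wpli <- function(a) {
  stopifnot(is(a, "AnalyticSet"))
  idx <- .retainedIdx(a)
  H <- a@h[, idx, drop = FALSE]
  n <- nrow(H)
  M <- matrix(0, n, n)
  flags <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      term <- Im(H[i, ] * Conj(H[j, ]))
      den <- mean(abs(term))
      if (den < .Machine$double.eps * max(Mod(H[i, ]) * Mod(H[j, ]))) {
        M[i, j] <- M[j, i] <- 0
        flags[i, j] <- flags[j, i] <- TRUE
      } else {
        M[i, j] <- M[j, i] <- abs(mean(term)) / den
      }
    }
  }
  .connMatrix(M, "wpli", directed = FALSE, a = a, flags = flags)
}

#' Normalised mutual information between instantaneous phases
#'
#' A non-linear coupling measure: the mutual information I of the two
#' nodes' discretised phase distributions, normalised by their joint
#' entropy E, giving `iota = I / E` in \[0, 1\]. Phases are binned
#' uniformly over (-pi, pi\].
#'
#' @inheritParams plv
#' @param nBins number of histogram bins per phase axis (default 16). A
#'   warning is issued when fewer than `10 * nBins^2` samples are
#'   available, where the plug-in estimator is badly biased.
#' @return an undirected \linkS4class{ConnectivityMatrix}, values in
#'   \[0, 1\].
#' @export
phaseMI <- function(a, nBins = 16L) {
  stopifnot(is(a, "AnalyticSet"), nBins >= 2L)
  idx <- .retainedIdx(a)
  P <- Arg(a@h[, idx, drop = FALSE])
  Tn <- length(idx)
  if (Tn < 10 * nBins^2)
    warning("only ", Tn, " samples for a ", nBins, "x", nBins,
            " phase histogram; mutual information will be biased upward")
  # bin (-pi, pi] into nBins half-open-from-the-left intervals
  B <- pmin(pmax(ceiling((P + pi) / (2 * pi) * nBins), 1L), nBins)
  n <- nrow(P)
  M <- matrix(0, n, n)
  flags <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      joint <- tabulate(B[i, ] + nBins * (B[j, ] - 1L), nbins = nBins^2)
      if (sum(joint) == 0L) stop("empty phase histogram")
      p <- joint / Tn
      pi1 <- rowSums(matrix(p, nBins))
      pi2 <- colSums(matrix(p, nBins))
      nz <- p > 0
      E <- -sum(p[nz] * base::log(p[nz]))
      if (E <= 0) {  # all mass in one cell: degenerate, flagged
        flags[i, j] <- flags[j, i] <- TRUE
        next
      }
      pij <- outer(pi1, pi2)
      I <- sum(p[nz] * base::log(p[nz] / as.vector(pij)[nz]))
      M[i, j] <- M[j, i] <- I / E
    }
  }
  .connMatrix(M, "mi", directed = FALSE, a = a, flags = flags)
}
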