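#' @include signal.R
NULL

# Polar (closest-orthonormal) factor of a tall matrix: M = U S V' -> U V'.
.polarOrth <- function(M) {
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

#' Symmetric orthogonalisation of a multi-node session
#'
#' Finds the set of signals least displaced, in Frobenius norm, from the
#' (mean-centred) inputs subject to exact mutual orthogonality — removing
#' all shared signal at zero lag between the nodes, with no bias related to
#' any reordering of them. This is the multivariate correction for spatial
#' leakage used before computing leakage-sensitive connectivity metrics.
#'
#' The solution alternates two closed-form steps: the closest orthonormal
#' matrix to the current scaled target (the polar factor of its SVD) and a
#' per-node least-squares refit of the signal magnitudes. Signals are
#' mean-centred first, so orthogonality coincides with zero sample
#' correlation; because the orthonormal basis lies in the span of the
#' centred inputs, the corrected signals are exactly uncorrelated.
#'
#' @param ts a \linkS4class{TimeSeriesSet} (or plain nodes x samples
#'   matrix) with more samples than nodes and full row rank.
#' @param tol convergence tolerance: iteration stops when the displacement
#'   changes by less than `tol` times the input norm.
#' @param maxIter maximum number of alternating iterations.
#' @return an \linkS4class{OrthogonalisationResult}. `values()` returns the
#'   corrected nodes x samples matrix (mean-centred).
#' @examples
#' x <- matrix(rnorm(3 * 500), 3)
#' mixed <- matrix(c(1, .4, 0, .4, 1, .4, 0, .4, 1), 3) %*% x
#' o <- symmetricOrthogonalise(mixed)
#' max(abs(cor(t(values(o)))[upper.tri(diag(3))]))  # ~0
#' @export
symmetricOrthogonalise <- function(ts, tol = 1e-9, maxIter = 50L) {
  X <- if (is(ts, "TimeSeriesSet")) ts@data else as.matrix(ts)
  if (nrow(X) >= ncol(X))
    stop("orthogonalisation needs more samples than nodes (got ",
         nrow(X), " nodes x ", ncol(X), " samples)", call. = FALSE)
  Y <- t(X) - rep(colMeans(t(X)), each = ncol(X))  # samples x nodes, centred
  k <- ncol(Y)
  sv <- svd(Y, nu = 0, nv = 0)
  if (sv$d[k] < 1e-10 * sv$d[1L]) {
    cc <- abs(stats::cor(Y))
    bad <- which(cc > 1 - 1e-8 & upper.tri(cc), arr.ind = TRUE)
    detail <- if (nrow(bad))
      paste0(" (near-duplicate node pairs: ",
             paste(apply(bad, 1L, paste, collapse = "~"), collapse = ", "),
             ")")
    else ""
    stop("input is rank deficient; cannot orthogonalise", detail,
         call. = FALSE)
  }
  nrmY <- sqrt(sum(Y^2))
  d <- sqrt(colSums(Y^2))
  dispPrev <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    O <- .polarOrth(Y %*% diag(d, k))
    d <- colSums(Y * O)                       # per-node magnitude refit
    L <- O %*% diag(d, k)
    disp <- sqrt(sum((Y - L)^2))
    if (is.finite(dispPrev) && abs(dispPrev - disp) <= tol * nrmY) {
      converged <- TRUE
      break
    }
    dispPrev <- disp
    if (iter >= maxIter) break
  }
  if (!converged)
    stop("symmetric orthogonalisation did not converge in ", maxIter,
         " iterations (last displacement change ",
         format(abs(dispPrev - disp), digits = 3), ")", call. = FALSE)
  new("OrthogonalisationResult", corrected = t(L),
      displacement = disp, iterations = iter, converged = converged)
}

#' Apply the leakage correction over the windows a metric uses
#'
#' The correction must be applied over the same time windows in which each
#' metric is computed: for correlation, spectral and autoregressive
#' measures that is the entire session (`"whole_series"`); for phase-based
#' metrics it is applied independently within each epoch (`"per_epoch"`).
#'
#' @param ts a \linkS4class{TimeSeriesSet}.
#' @param metricClass `"whole_series"` or `"per_epoch"`.
#' @param epochS epoch length in seconds (required for `"per_epoch"`).
#' @param ... passed to [symmetricOrthogonalise()].
#' @return a \linkS4class{TimeSeriesSet} whose rows are mutually
#'   uncorrelated over each correction window.
#' @export
applyCorrectionPolicy <- function(ts, metricClass = c("whole_series",
                                                      "per_epoch"),
                                  epochS = NULL, ...) {
  stopifnot(is(ts, "TimeSeriesSet"))
  metricClass <- match.arg(metricClass)
  if (metricClass == "whole_series") {
    corr <- symmetricOrthogonalise(ts, ...)@corrected
  } else {
    if (is.null(epochS))
      stop("per_epoch correction needs an epoch length")
    bounds <- .epochBounds(ncol(ts@data), ts@fs, epochS)
    epochLen <- bounds[1L, 2L] - bounds[1L, 1L] + 1L
    if (epochLen <= nrow(ts@data))
      stop("epoch (", epochLen, " samples) not longer than node count; ",
           "orthogonalisation is rank deficient", call. = FALSE)
    if (epochLen < 2L * nrow(ts@data))
      warning("epochs shorter than twice the node count; ",
              "per-epoch orthogonalisation may be numerically fragile")
    corr <- matrix(0, nrow(ts@data), ncol(ts@data))
    for (e in seq_len(nrow(bounds))) {
      idx <- bounds[e, 1L]:bounds[e, 2L]
      corr[, idx] <- symmetricOrthogonalise(ts@data[, idx], ...)@corrected
    }
    corr <- corr[, seq_len(bounds[nrow(bounds), 2L]), drop = FALSE]
  }
  TimeSeriesSet(corr, fs = ts@fs, band = ts@band,
                subjectId = ts@subjectId, sessionId = ts@sessionId)
}
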