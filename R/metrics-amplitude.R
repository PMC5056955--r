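#' @include glasso.R
NULL

#' Amplitude envelope correlation
#'
#' Pearson correlation between the (log) power envelopes of each node
#' pair — the simplest amplitude-coupling metric. Sensitive to zero-lag
#' leakage unless the signals were orthogonalised first.
#'
#' @param e an \linkS4class{EnvelopeSet} from [powerEnvelope()] with at
#'   least 3 envelope samples.
#' @return an undirected \linkS4class{ConnectivityMatrix} with values in
#'   \[-1, 1\]; zero-variance nodes produce flagged NA edges.
#' @export
aec <- function(e) {
  stopifnot(is(e, "EnvelopeSet"))
  if (ncol(e@env) < 3L) stop("need at least 3 envelope samples")
  v <- apply(e@env, 1L, stats::var)
  n <- nrow(e@env)
  flags <- matrix(FALSE, n, n)
  if (any(v == 0)) {
    bad <- which(v == 0)
    warning("zero-variance envelope for node(s) ",
            paste(bad, collapse = ", "), "; edges flagged undefined")
    flags[bad, ] <- TRUE
    flags[, bad] <- TRUE
  }
  M <- suppressWarnings(stats::cor(t(e@env)))
  M[flags] <- NA_real_
  .connMatrix(M, "aec", directed = FALSE, a = e, flags = flags)
}

#' Regularised partial amplitude envelope correlation
#'
#' Partial correlations of the (log) power envelopes, from the inverse of
#' their covariance matrix regularised with the graphical lasso. The
#' penalty is chosen per session over a logarithmic grid by minimising the
#' corrected Akaike information criterion of the held-out Gaussian
#' log-likelihood under k-fold cross-validation; the effective parameter
#' count is the number of nonzero upper-triangle precision entries.
#'
#' @param e an \linkS4class{EnvelopeSet}.
#' @param cvFolds number of cross-validation folds (default 5).
#' @param penaltyGrid optional vector of penalties; default is 20
#'   logarithmic points spanning `[1e-3, 1]` times the maximum absolute
#'   off-diagonal covariance.
#' @param seed optional seed controlling fold assignment.
#' @return an undirected \linkS4class{ConnectivityMatrix} of partial
#'   correlations; the chosen penalty is stored in
#'   `attr(values(x), "penalty")`.
#' @export
partialAEC <- function(e, cvFolds = 5L, penaltyGrid = NULL, seed = NULL) {
  stopifnot(is(e, "EnvelopeSet"))
  X <- t(e@env)                      # samples x nodes
  nObs <- nrow(X)
  if (nObs < 2L * cvFolds)
    stop("need at least ", 2L * cvFolds, " envelope samples for ",
         cvFolds, "-fold cross-validation", call. = FALSE)
  X <- scale(X, center = TRUE, scale = FALSE)
  Sfull <- stats::cov(X)
  if (is.null(penaltyGrid)) {
    mx <- max(abs(Sfull[row(Sfull) != col(Sfull)]))
    penaltyGrid <- exp(seq(log(1e-3), log(1), length.out = 20L)) * mx
  }
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(cvFolds), length.out = nObs))
  aicc <- vapply(penaltyGrid, function(rho) {
    tot <- 0
    for (f in seq_len(cvFolds)) {
      tr <- X[folds != f, , drop = FALSE]
      te <- X[folds == f, , drop = FALSE]
      fit <- tryCatch(graphicalLasso(stats::cov(tr), rho),
                      error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      k <- sum(fit$Theta[upper.tri(fit$Theta)] != 0) + nrow(Sfull)
      ll <- .gaussLogLik(fit$Theta, stats::cov(te), nrow(te))
      nTe <- nrow(te)
      corr <- if (nTe - k - 1 > 0) 2 * k * (k + 1) / (nTe - k - 1) else Inf
      tot <- tot + (-2 * ll + 2 * k + corr)
    }
    tot
  }, numeric(1))
  best <- penaltyGrid[which.min(aicc)]
  fit <- graphicalLasso(Sfull, best)
  Th <- fit$Theta
  d <- sqrt(diag(Th))
  P <- -Th / outer(d, d)
  diag(P) <- 1
  out <- .connMatrix(P, "paec", directed = FALSE, a = e)
  attr(out@values, "penalty") <- best
  attr(out@values, "aicc") <- stats::setNames(aicc, signif(penaltyGrid, 4))
  out
}
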