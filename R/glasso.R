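#' @include metrics-ar.R
NULL

#' Graphical lasso estimate of a sparse precision matrix
#'
#' L1-penalised Gaussian maximum likelihood for the inverse covariance:
#' maximises `log det(Theta) - tr(S Theta) - rho * ||Theta||_1` (off-diagonal
#' penalty) by blockwise coordinate descent, cycling over variables and
#' solving each row's lasso subproblem in closed coordinate updates. With
#' `rho = 0` and a well-conditioned `S` the solution is the plain inverse
#' covariance; as `rho` grows all off-diagonal partial dependencies are
#' shrunk to zero.
#'
#' @param S sample covariance matrix (symmetric, non-negative definite).
#' @param rho scalar penalty, >= 0.
#' @param tol convergence tolerance on the estimated covariance, relative
#'   to the mean absolute off-diagonal of `S`.
#' @param maxIter maximum full sweeps.
#' @return list with `Theta` (precision estimate), `W` (covariance
#'   estimate `= Theta^-1` at convergence), `iterations`, `converged`.
#' @export
graphicalLasso <- function(S, rho, tol = 1e-6, maxIter = 200L) {
  stopifnot(isSymmetric(unname(S), tol = 1e-8), rho >= 0)
  p <- nrow(S)
  if (p < 2L) stop("need at least two variables")
  W <- S + rho * diag(p)
  Beta <- matrix(0, p - 1L, p)
  offScale <- mean(abs(S[row(S) != col(S)]))
  if (offScale == 0) offScale <- mean(diag(S))
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Wold <- W
    for (j in seq_len(p)) {
      W11 <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      b <- Beta[, j]
      # lasso coordinate descent: min .5 b'W11 b - b's12 + rho |b|_1
      repeat {
        bOld <- b
        for (k in seq_len(p - 1L)) {
          r <- s12[k] - sum(W11[k, -k] * b[-k])
          b[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(b - bOld)) < 1e-10 * max(1, offScale)) break
      }
      Beta[, j] <- b
      w12 <- W11 %*% b
      W[-j, j] <- w12
      W[j, -j] <- w12
    }
    if (max(abs(W - Wold)) < tol * offScale) {
      converged <- TRUE
      break
    }
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    denom <- W[j, j] - sum(W[-j, j] * Beta[, j])
    Theta[j, j] <- 1 / denom
    Theta[-j, j] <- -Beta[, j] * Theta[j, j]
  }
  Theta <- (Theta + t(Theta)) / 2
  list(Theta = Theta, W = W, iterations = it, converged = converged)
}

# Log-likelihood (up to constants) of covariance Stest under precision Theta,
# per observation: .5 * (log det Theta - tr(Stest Theta)).
.gaussLogLik <- function(Theta, Stest, nObs) {
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  nObs / 2 * (as.numeric(ld$modulus) - sum(Stest * Theta))
}
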