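#' @include metric-registry.R
NULL

#' Create a ground-truth coupling network
#'
#' Draws a random network over `nNodes` nodes: each upper-triangle edge is
#' present independently with probability `density`, with coupling strength
#' uniform in `strengthRange`. For the directed `ar_process` mode each
#' ordered node pair is drawn independently and the strengths populate the
#' lagged (transfer) coefficient matrix instead.
#'
#' Edge strengths are interpreted by [simulateSession()] according to the
#' coupling mode: target log-envelope correlation (`envelope`), target
#' phase-locking value (`phase_lag`), or lag-1 AR coefficient
#' (`ar_process`).
#'
#' @param nNodes number of nodes (>= 2).
#' @param density expected fraction of possible edges present, in (0, 1\].
#' @param strengthRange interval of coupling strengths, within \[0, 1).
#' @param couplingMode "envelope", "phase_lag" or "ar_process".
#' @param seed optional RNG seed for reproducibility.
#' @return a \linkS4class{GroundTruthNetwork}.
#' @examples
#' net <- makeNetwork(10, density = 0.3, seed = 1)
#' sum(net@edges[upper.tri(net@edges)] > 0)
#' @export
makeNetwork <- function(nNodes, density, strengthRange = c(0.3, 0.8),
                        couplingMode = c("envelope", "phase_lag",
                                         "ar_process"),
                        seed = NULL) {
  couplingMode <- match.arg(couplingMode)
  if (nNodes < 2L) stop("a network needs at least 2 nodes")
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  stopifnot(all(strengthRange >= 0), all(strengthRange < 1))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nNodes)
  edges <- matrix(0, n, n)
  lagged <- matrix(0, n, n)
  if (couplingMode == "ar_process") {
    off <- which(row(lagged) != col(lagged))
    on <- off[stats::runif(length(off)) < density]
    lagged[on] <- stats::runif(length(on), strengthRange[1L],
                               strengthRange[2L])
    edges <- lagged
  } else {
    ut <- which(upper.tri(edges))
    on <- ut[stats::runif(length(ut)) < density]
    edges[on] <- stats::runif(length(on), strengthRange[1L],
                              strengthRange[2L])
    edges <- edges + t(edges)
  }
  new("GroundTruthNetwork", nNodes = n, edges = edges, lagged = lagged,
      couplingMode = couplingMode)
}

#' Ring-topology leakage mixing model
#'
#' Identity plus symmetric nearest-neighbour off-diagonal weights on a ring
#' of nodes: a minimal stand-in for the local point-spread of a source
#' reconstruction, applied instantaneously (zero lag only).
#'
#' @param nNodes number of nodes.
#' @param weight off-diagonal neighbour weight (default 0.3).
#' @return a \linkS4class{LeakageModel}.
#' @export
ringLeakage <- function(nNodes, weight = 0.3) {
  n <- as.integer(nNodes)
  M <- diag(n)
  for (i in seq_len(n)) {
    M[i, i %% n + 1L] <- M[i %% n + 1L, i] <- weight
  }
  new("LeakageModel", mixing = M)
}

#' Construct a study design
#'
#' Defaults mirror a large resting-state protocol: 61 subjects, three
#' consecutive sessions each, six minutes per session, with the alpha band
#' as the analysis target. Scale the subject count, duration and sampling
#' rate down for desk-scale simulation.
#'
#' @param nSubjects number of subjects.
#' @param nSessions sessions per subject (>= 2).
#' @param durationS session duration, seconds.
#' @param fs sampling rate, Hz.
#' @param band analysis band name.
#' @param subjectSd SD of per-subject perturbations of true edge strengths.
#' @param noiseSd additive white measurement-noise SD (carriers are
#'   unit-scale).
#' @param epochS epoch length for phase metrics, seconds.
#' @param seed master seed; every subject network and session realisation
#'   derives deterministically from it.
#' @return a \linkS4class{StudyDesign}.
#' @export
studyDesign <- function(nSubjects = 61L, nSessions = 3L, durationS = 360,
                       fs = 300, band = "alpha", subjectSd = 0.1,
                       noiseSd = 0.2, epochS = 10, seed = 1L) {
  bandLimits(band)  # validates the name
  new("StudyDesign", nSubjects = as.integer(nSubjects),
      nSessions = as.integer(nSessions), durationS = durationS, fs = fs,
      band = band, subjectSd = subjectSd, noiseSd = noiseSd,
      epochS = epochS, seed = as.integer(seed))
}

# Clip a correlation matrix to positive definiteness by eigenvalue
# flooring, restoring the unit diagonal.
.makePD <- function(R, floor = 1e-6) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= floor) return(R)
  warning("target correlation matrix not positive definite; ",
          "flooring eigenvalues")
  R2 <- ev$vectors %*% diag(pmax(ev$values, floor)) %*% t(ev$vectors)
  D <- 1 / sqrt(diag(R2))
  R2 * outer(D, D)
}

# A unit-amplitude oscillatory carrier: cos of the instantaneous phase of
# band-pass-filtered white noise. Band-limited phase dynamics, constant
# modulus — so an imposed envelope modulator is recovered exactly by the
# analysis pipeline.
.unitCarrier <- function(Tn, fs, low, high) {
  b <- .zeroPhaseBandpass(stats::rnorm(Tn + 200L), fs, low, high)
  cos(Arg(.fftAnalytic(b)))[101L:(Tn + 100L)]
}

# Band-limited filtered-noise carrier, unit variance.
.noiseCarrier <- function(Tn, fs, low, high) {
  b <- .zeroPhaseBandpass(stats::rnorm(Tn + 200L), fs, low, high)
  b <- b[101L:(Tn + 100L)]
  b / stats::sd(b)
}

# Connected components of the positive-edge graph (simple BFS).
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# BFS depth of each node from the lowest-index node of its component.
.bfsDepth <- function(adj, comp) {
  n <- nrow(adj)
  depth <- integer(n)
  for (cc in unique(comp)) {
    nodes <- which(comp == cc)
    root <- min(nodes)
    depth[root] <- 0L
    queue <- root
    seen <- rep(FALSE, n); seen[root] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & !seen)
      depth[nb] <- depth[v] + 1L
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  depth
}

# Per-node phase-jitter variances achieving target pairwise PLV values:
# with independent Gaussian jitter, PLV_ij = exp(-(v_i + v_j) / 2), so
# -2 log s_ij = v_i + v_j is solved by least squares, clipped at zero.
.jitterVariances <- function(edges) {
  n <- nrow(edges)
  v <- numeric(n)
  pairs <- which(edges > 0 & upper.tri(edges), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(v)
  A <- matrix(0, nrow(pairs), n)
  for (r in seq_len(nrow(pairs))) A[r, pairs[r, ]] <- 1
  b <- -2 * base::log(edges[pairs])
  sol <- qr.coef(qr(A), b)
  sol[is.na(sol)] <- 0
  pmax(sol, 0)
}

#' Simulate one session of coupled oscillatory ROI signals
#'
#' Generates band-limited signals for every node, couples them according to
#' the network's mode, then (optionally) applies the instantaneous leakage
#' mix and adds white measurement noise.
#'
#' \describe{
#'   \item{envelope}{Unit-modulus oscillatory carriers (cosine of the
#'     instantaneous phase of band-filtered noise) are multiplied by
#'     log-normal envelope modulators. The log-modulators are drawn from a
#'     multivariate Gaussian whose correlation equals the edge matrix, at
#'     the 0.5 Hz envelope rate, and interpolated up to the sampling rate —
#'     so the designed value is the target log-envelope (AEC) correlation
#'     directly.}
#'   \item{phase_lag}{Nodes in a connected component share one oscillator's
#'     phase, offset per node by `phaseLag` times its graph depth, plus
#'     independent slow Gaussian phase jitter whose variance is calibrated
#'     analytically so the pairwise phase-locking value matches the edge
#'     strength.}
#'   \item{ar_process}{A stable VAR process: each node an AR(2) resonator
#'     centred in the band, with the network's lagged matrix as the
#'     off-diagonal lag-1 coefficients. Unstable coefficient sets are
#'     rejected.}
#' }
#'
#' @param net a \linkS4class{GroundTruthNetwork}.
#' @param design a \linkS4class{StudyDesign} (band, fs, duration, noise).
#' @param leakage optional \linkS4class{LeakageModel} applied at zero lag
#'   after coupling.
#' @param seed RNG seed.
#' @param sdLog log-envelope modulator SD (envelope mode), log units.
#' @param phaseLag inter-node phase offset per graph step (phase-lag mode),
#'   radians.
#' @param subjectId,sessionId labels stored on the output.
#' @return a broadband \linkS4class{TimeSeriesSet}.
#' @export
simulateSession <- function(net, design, leakage = NULL, seed = NULL,
                            sdLog = 0.5, phaseLag = pi / 2,
                            subjectId = "s1", sessionId = "r1") {
  stopifnot(is(net, "GroundTruthNetwork"), is(design, "StudyDesign"))
  validObject(net)
  lim <- bandLimits(design@band)
  if (lim[2L] >= design@fs / 2)
    stop("band reaches Nyquist at fs = ", design@fs, " Hz")
  if (!is.null(seed)) set.seed(seed)
  n <- net@nNodes
  Tn <- round(design@durationS * design@fs)
  X <- switch(net@couplingMode,
    envelope = {
      R <- .makePD(net@edges + diag(n))
      modRate <- 0.5
      nEnv <- ceiling(design@durationS * modRate) + 2L
      Z <- MASS::mvrnorm(nEnv, mu = rep(0, n), Sigma = R)
      tEnv <- (seq_len(nEnv) - 0.5) / modRate
      tS <- (seq_len(Tn) - 0.5) / design@fs
      out <- matrix(0, n, Tn)
      for (i in seq_len(n)) {
        L <- stats::approx(tEnv, Z[, i], xout = tS, rule = 2)$y
        out[i, ] <- exp(sdLog * L) *
          .unitCarrier(Tn, design@fs, lim[1L], lim[2L])
      }
      out
    },
    phase_lag = {
      adj <- net@edges > 0
      comp <- .components(adj)
      depth <- .bfsDepth(adj, comp)
      v <- .jitterVariances(net@edges)
      phases <- matrix(0, n, Tn)
      for (cc in unique(comp)) {
        nodes <- which(comp == cc)
        if (length(nodes) == 1L || all(!adj[nodes, nodes])) {
          for (i in nodes)
            phases[i, ] <- Arg(.fftAnalytic(
              .zeroPhaseBandpass(stats::rnorm(Tn), design@fs,
                                 lim[1L], lim[2L])))
        } else {
          shared <- Arg(.fftAnalytic(
            .zeroPhaseBandpass(stats::rnorm(Tn), design@fs,
                               lim[1L], lim[2L])))
          for (i in nodes) {
            jit <- if (v[i] > 0) {
              j <- .zeroPhaseLowpass(stats::rnorm(Tn), design@fs,
                                     cutoff = 1, order = 2L)
              j / stats::sd(j) * sqrt(v[i])
            } else 0
            phases[i, ] <- shared + phaseLag * depth[i] + jit
          }
        }
      }
      cos(phases)
    },
    ar_process = {
      f0 <- mean(lim)
      rPole <- 0.95
      a1 <- 2 * rPole * cos(2 * pi * f0 / design@fs)
      a2 <- -rPole^2
      A <- array(0, c(n, n, 2L))
      A[, , 1L] <- diag(a1, n) + net@lagged
      A[, , 2L] <- diag(a2, n)
      rad <- .companionRadius(A)
      if (rad >= 1)
        stop("AR coupling coefficients give an unstable process ",
             "(companion spectral radius ", format(rad, digits = 5), ")",
             call. = FALSE)
      burn <- 500L
      out <- matrix(0, n, Tn + burn)
      innov <- matrix(stats::rnorm(n * (Tn + burn)), n)
      for (t in 3L:(Tn + burn))
        out[, t] <- A[, , 1L] %*% out[, t - 1L] +
          A[, , 2L] %*% out[, t - 2L] + innov[, t]
      out <- out[, (burn + 1L):(burn + Tn), drop = FALSE]
      out / apply(out, 1L, stats::sd)
    }
  )
  if (!is.null(leakage)) {
    stopifnot(is(leakage, "LeakageModel"))
    validObject(leakage)
    if (nrow(leakage@mixing) != n)
      stop("leakage mixing is ", nrow(leakage@mixing), "x",
           ncol(leakage@mixing), " but the network has ", n, " nodes")
    X <- leakage@mixing %*% X
  }
  if (design@noiseSd > 0)
    X <- X + design@noiseSd * matrix(stats::rnorm(length(X)), nrow(X))
  TimeSeriesSet(X, fs = design@fs, band = "broadband",
                subjectId = subjectId, sessionId = sessionId)
}

#' Generate a full multi-subject, multi-session study
#'
#' Each subject's true network is the group network with its nonzero edge
#' strengths perturbed once by Gaussian noise of SD `design@subjectSd`
#' (clipped to valid strengths) — constant across that subject's sessions,
#' so within-subject consistency exceeds between-subject by construction.
#' Session realisations are independent. Everything derives
#' deterministically from `design@seed`.
#'
#' @param net group-level \linkS4class{GroundTruthNetwork}.
#' @param design a \linkS4class{StudyDesign}.
#' @param leakage optional \linkS4class{LeakageModel} shared by all
#'   sessions.
#' @param ... further arguments to [simulateSession()] (`sdLog`,
#'   `phaseLag`).
#' @return a list of class `megconnStudy` with elements `sessions` (list
#'   of \linkS4class{TimeSeriesSet}), `networks` (per-subject true
#'   networks), `design` and `leakage`.
#' @export
generateStudy <- function(net, design, leakage = NULL, ...) {
  stopifnot(is(net, "GroundTruthNetwork"), is(design, "StudyDesign"))
  validObject(design)
  set.seed(design@seed)
  nS <- design@nSubjects
  nR <- design@nSessions
  sessSeeds <- matrix(sample.int(.Machine$integer.max - 1L, nS * nR),
                      nrow = nS)
  networks <- vector("list", nS)
  for (s in seq_len(nS)) {
    e <- net@edges
    lag <- net@lagged
    if (design@subjectSd > 0) {
      if (net@couplingMode == "ar_process") {
        nz <- which(lag != 0)
        lag[nz] <- pmin(pmax(lag[nz] +
          stats::rnorm(length(nz), 0, design@subjectSd), -0.95), 0.95)
        e <- lag
      } else {
        nz <- which(e != 0 & upper.tri(e))
        e[nz] <- pmin(pmax(e[nz] +
          stats::rnorm(length(nz), 0, design@subjectSd), 0), 0.95)
        e[lower.tri(e)] <- 0
        e <- e + t(e)
      }
    }
    networks[[s]] <- new("GroundTruthNetwork", nNodes = net@nNodes,
                         edges = e, lagged = lag,
                         couplingMode = net@couplingMode)
  }
  sessions <- vector("list", nS * nR)
  k <- 0L
  for (s in seq_len(nS)) {
    for (r in seq_len(nR)) {
      k <- k + 1L
      sessions[[k]] <- simulateSession(
        networks[[s]], design, leakage, seed = sessSeeds[s, r],
        subjectId = sprintf("s%02d", s), sessionId = sprintf("r%d", r),
        ...)
    }
  }
  structure(list(sessions = sessions, networks = networks,
                 design = design, leakage = leakage),
            class = "megconnStudy")
}

#' @export
print.megconnStudy <- function(x, ...) {
  cat("megconnStudy:", x$design@nSubjects, "subjects x",
      x$design@nSessions, "sessions;", x$networks[[1L]]@nNodes, "nodes,",
      x$design@durationS, "s @", x$design@fs, "Hz; mode",
      x$networks[[1L]]@couplingMode,
      if (!is.null(x$leakage)) "(with leakage)" else "(no leakage)", "\n")
  invisible(x)
}
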