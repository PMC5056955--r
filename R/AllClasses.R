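#' @import methods
NULL

#' One session of multi-node region-of-interest time courses
#'
#' Container for a nodes-by-samples real matrix together with its sampling
#' rate, frequency-band label and subject/session identifiers. This is the
#' common currency of the pipeline: the synthetic generator produces it, the
#' signal tools filter and decompose it, and the leakage correction rewrites
#' its rows.
#'
#' @slot data numeric matrix, nodes x samples; all values finite.
#' @slot fs sampling rate in Hz.
#' @slot band band label (a registry name, or "broadband").
#' @slot subjectId,sessionId character labels used by the reliability suite.
#'
#' @seealso [TimeSeriesSet()] for the user-facing constructor.
#' @export
setClass("TimeSeriesSet",
  representation(
    data      = "matrix",
    fs        = "numeric",
    band      = "character",
    subjectId = "character",
    sessionId = "character"
  ),
  prototype(band = "broadband", subjectId = "s1", sessionId = "r1")
)

setValidity("TimeSeriesSet", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix (nodes x samples)")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite values")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) > ncol(object@data))
    msg <- c(msg, "need at least as many samples as nodes")
  if (length(msg)) msg else TRUE
})

#' Complex analytic signals per node
#'
#' Holds the analytic extension h = s + i*H[s] of each node's band-limited
#' time course, the epoch boundaries over which the Hilbert transform was
#' taken, and the number of edge samples per epoch to exclude from phase
#' statistics (the transform's transient margin).
#'
#' @slot h complex matrix, nodes x samples.
#' @slot fs sampling rate in Hz.
#' @slot band band label.
#' @slot epochs integer matrix with columns `start`, `end` (inclusive sample
#'   indices); one row per epoch.
#' @slot edgeSamples number of samples at each epoch edge flagged for
#'   exclusion from phase statistics.
#' @slot subjectId,sessionId labels carried through from the input.
#' @export
setClass("AnalyticSet",
  representation(
    h           = "matrix",
    fs          = "numeric",
    band        = "character",
    epochs      = "matrix",
    edgeSamples = "integer",
    subjectId   = "character",
    sessionId   = "character"
  )
)

setValidity("AnalyticSet", function(object) {
  msg <- character()
  if (!is.complex(object@h))
    msg <- c(msg, "h must be a complex matrix")
  if (ncol(object@epochs) != 2L)
    msg <- c(msg, "epochs must have two columns (start, end)")
  if (nrow(object@epochs) >= 1L) {
    if (any(object@epochs[, 1L] > object@epochs[, 2L]))
      msg <- c(msg, "epoch starts must not exceed epoch ends")
    if (max(object@epochs[, 2L]) > ncol(object@h))
      msg <- c(msg, "epoch boundaries exceed the data length")
  }
  if (length(msg)) msg else TRUE
})

#' Log power envelopes sampled at a slow envelope rate
#'
#' @slot env numeric matrix, nodes x envelope samples. Log-transformed when
#'   `logTransformed` is TRUE (an envelope floor is applied before the log).
#' @slot rate envelope sampling rate in Hz (default pipeline value 0.5 Hz).
#' @slot logTransformed whether the log was taken.
#' @slot band,subjectId,sessionId labels.
#' @export
setClass("EnvelopeSet",
  representation(
    env            = "matrix",
    rate           = "numeric",
    logTransformed = "logical",
    band           = "character",
    subjectId      = "character",
    sessionId      = "character"
  )
)

setValidity("EnvelopeSet", function(object) {
  msg <- character()
  if (any(!is.finite(object@env)))
    msg <- c(msg, "envelope contains non-finite values")
  if (object@rate <= 0)
    msg <- c(msg, "envelope rate must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-frequency cross-spectral density matrices
#'
#' Welch (or single-window) estimates of the cross-spectral density
#' S(f), stored as an N x N x F complex array, with the frequency grid and
#' its resolution. Each slice is Hermitian with a real non-negative diagonal.
#'
#' @slot S complex array, nodes x nodes x frequencies.
#' @slot freqs frequency grid in Hz.
#' @slot deltaF frequency resolution (grid spacing) in Hz.
#' @slot windowSec estimation window length in seconds.
#' @slot taper taper identifier ("hamming").
#' @slot nSegments number of averaged segments.
#' @slot band,subjectId,sessionId labels.
#' @export
setClass("CrossSpectrum",
  representation(
    S         = "array",
    freqs     = "numeric",
    deltaF    = "numeric",
    windowSec = "numeric",
    taper     = "character",
    nSegments = "integer",
    band      = "character",
    subjectId = "character",
    sessionId = "character"
  )
)

setValidity("CrossSpectrum", function(object) {
  msg <- character()
  d <- dim(object@S)
  if (length(d) != 3L || d[1L] != d[2L])
    msg <- c(msg, "S must be an N x N x F array")
  if (length(object@freqs) != d[3L])
    msg <- c(msg, "freqs length must match the third dimension of S")
  if (object@deltaF <= 0)
    msg <- c(msg, "deltaF must be positive")
  if (length(msg)) msg else TRUE
})

#' A fitted vector-autoregressive transfer model
#'
#' Multivariate AR fit used by partial directed coherence: lagged coefficient
#' matrices, innovation covariance, the model's sampling rate (the data may
#' have been resampled before fitting) and stability diagnostics.
#'
#' @slot A coefficient array, nodes x nodes x order; `A[, , p]` multiplies
#'   the observation at lag p.
#' @slot order model order (number of lags).
#' @slot sigma innovation covariance matrix.
#' @slot fsModel sampling rate (Hz) of the data the model was fitted to.
#' @slot spectralRadius spectral radius of the companion matrix (< 1 for a
#'   stable model).
#' @slot band,subjectId,sessionId labels.
#' @export
setClass("ARTransferModel",
  representation(
    A              = "array",
    order          = "integer",
    sigma          = "matrix",
    fsModel        = "numeric",
    spectralRadius = "numeric",
    band           = "character",
    subjectId      = "character",
    sessionId      = "character"
  )
)

setValidity("ARTransferModel", function(object) {
  msg <- character()
  d <- dim(object@A)
  if (length(d) != 3L || d[1L] != d[2L])
    msg <- c(msg, "A must be an N x N x order array")
  if (d[3L] != object@order)
    msg <- c(msg, "third dimension of A must equal order")
  if (object@spectralRadius >= 1)
    msg <- c(msg, "model is unstable (companion spectral radius >= 1)")
  if (length(msg)) msg else TRUE
})

#' An N x N connectivity matrix for one metric and session
#'
#' @slot values numeric matrix of edge strengths; diagonal is NA by
#'   convention (self-connectivity is not defined for these metrics).
#' @slot metric metric identifier (see [metricInfo()]).
#' @slot directed whether edges carry direction (values\[i, j\] and
#'   values\[j, i\] are distinct).
#' @slot leakageCorrected whether symmetric orthogonalisation was applied
#'   before computing the metric.
#' @slot flags logical matrix marking degenerate edges (e.g. a weighted
#'   phase-lag denominator of zero); same shape as `values`.
#' @slot band,subjectId,sessionId labels.
#' @export
setClass("ConnectivityMatrix",
  representation(
    values           = "matrix",
    metric           = "character",
    directed         = "logical",
    leakageCorrected = "logical",
    flags            = "matrix",
    band             = "character",
    subjectId        = "character",
    sessionId        = "character"
  ),
  prototype(directed = FALSE, leakageCorrected = FALSE)
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v))
    msg <- c(msg, "values must be square")
  if (!all(dim(object@flags) == dim(v)))
    msg <- c(msg, "flags must have the same shape as values")
  off <- v[row(v) != col(v)]
  if (!object@directed) {
    if (any(abs(v - t(v)) > 1e-10, na.rm = TRUE))
      msg <- c(msg, "undirected metric must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a symmetric orthogonalisation
#'
#' @slot corrected nodes x samples matrix of mutually uncorrelated signals
#'   (mean-centred; all pairwise sample correlations are zero to within
#'   1e-8).
#' @slot displacement Frobenius distance between the corrected and input
#'   (mean-centred) matrices.
#' @slot iterations number of alternating iterations used.
#' @slot converged whether the relative displacement change fell below the
#'   tolerance within `maxIter`.
#' @export
setClass("OrthogonalisationResult",
  representation(
    corrected    = "matrix",
    displacement = "numeric",
    iterations   = "integer",
    converged    = "logical"
  )
)

#' Ground-truth coupling network for simulation
#'
#' @slot nNodes number of network nodes.
#' @slot edges symmetric matrix of target coupling strengths in \[0, 1);
#'   zero diagonal. Interpreted as target log-envelope correlation
#'   (envelope mode), target phase-locking value (phase-lag mode) or, via
#'   `lagged`, directed AR coefficients (AR mode).
#' @slot lagged directed coefficient matrix for `ar_process` simulations
#'   (zero when unused).
#' @slot couplingMode one of "envelope", "phase_lag", "ar_process".
#' @export
setClass("GroundTruthNetwork",
  representation(
    nNodes       = "integer",
    edges        = "matrix",
    lagged       = "matrix",
    couplingMode = "character"
  )
)

setValidity("GroundTruthNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (object@nNodes < 2L)
    msg <- c(msg, "a network needs at least two nodes")
  if (any(dim(e) != object@nNodes))
    msg <- c(msg, "edges must be nNodes x nNodes")
  if (any(diag(e) != 0))
    msg <- c(msg, "edge diagonal must be zero")
  if (any(abs(e) >= 1))
    msg <- c(msg, "edge strengths must have magnitude < 1")
  if (object@couplingMode %in% c("envelope", "phase_lag") &&
      any(abs(e - t(e)) > 1e-12))
    msg <- c(msg, "edges must be symmetric for undirected coupling modes")
  if (!object@couplingMode %in% c("envelope", "phase_lag", "ar_process"))
    msg <- c(msg, "unknown coupling mode")
  if (length(msg)) msg else TRUE
})

#' Instantaneous linear mixing model for source leakage
#'
#' Emulates the point-spread of a source-reconstruction inverse operator:
#' a full-rank, diagonal-dominant matrix applied to the source signals at
#' lag zero only.
#'
#' @slot mixing N x N real full-rank matrix.
#' @export
setClass("LeakageModel", representation(mixing = "matrix"))

setValidity("LeakageModel", function(object) {
  m <- object@mixing
  if (nrow(m) != ncol(m))
    return("mixing must be square")
  if (abs(det(m)) < 1e-12)
    return("mixing matrix is singular")
  TRUE
})

#' Study design for the synthetic generator
#'
#' Defaults mirror a resting-state MEG protocol: three consecutive sessions
#' per subject of six minutes each.
#'
#' @slot nSubjects number of subjects.
#' @slot nSessions sessions per subject (>= 2 for within-subject tests).
#' @slot durationS session duration in seconds.
#' @slot fs sampling rate in Hz.
#' @slot band analysis band name.
#' @slot subjectSd standard deviation of per-subject perturbations of the
#'   true edge strengths.
#' @slot noiseSd additive white measurement-noise standard deviation
#'   (signal carriers have unit scale).
#' @slot epochS epoch length in seconds for phase metrics.
#' @slot seed RNG seed from which all subject/session seeds derive.
#' @export
setClass("StudyDesign",
  representation(
    nSubjects = "integer",
    nSessions = "integer",
    durationS = "numeric",
    fs        = "numeric",
    band      = "character",
    subjectSd = "numeric",
    noiseSd   = "numeric",
    epochS    = "numeric",
    seed      = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "need at least one subject")
  if (object@nSessions < 2L)
    msg <- c(msg, "need >= 2 sessions per subject for within-subject tests")
  if (object@durationS < 2 * object@epochS)
    msg <- c(msg, "session must contain at least two epochs")
  if (object@subjectSd < 0 || object@noiseSd < 0)
    msg <- c(msg, "standard deviations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A study's worth of connectivity matrices for one metric
#'
#' @slot matrices list of [ConnectivityMatrix-class] objects sharing metric,
#'   band and shape.
#' @slot subjects,sessions character vectors parallel to `matrices`.
#' @slot metric,band shared labels.
#' @slot directed edge-vectorisation rule: directed metrics use all
#'   off-diagonal entries, undirected the upper triangle only.
#' @export
setClass("StudyNetworks",
  representation(
    matrices = "list",
    subjects = "character",
    sessions = "character",
    metric   = "character",
    band     = "character",
    directed = "logical"
  )
)

setValidity("StudyNetworks", function(object) {
  msg <- character()
  n <- length(object@matrices)
  if (length(object@subjects) != n || length(object@sessions) != n)
    msg <- c(msg, "subjects/sessions must parallel the matrix list")
  if (n > 0L) {
    dims <- vapply(object@matrices, function(m) nrow(m@values), integer(1))
    if (length(unique(dims)) != 1L)
      msg <- c(msg, "all matrices must share one shape")
    mets <- vapply(object@matrices, function(m) m@metric, character(1))
    if (length(unique(mets)) != 1L)
      msg <- c(msg, "all matrices must share one metric")
  }
  if (length(msg)) msg else TRUE
})

#' Reliability report for one metric, band and correction state
#'
#' Gathers the three consistency tests — split-half group consistency,
#' within-subject session-pair consistency and between-subject consistency —
#' together with the group-mean network and the edge-contribution map for
#' the group-level correlation.
#'
#' @slot splitHalf per-partition edge-vector Pearson correlations between
#'   the two halves' group means.
#' @slot splitHalfZ the same values after Fisher transformation.
#' @slot withinSubject data.frame with columns subject, sessionA, sessionB,
#'   rho.
#' @slot betweenSubject numeric vector of cross-subject correlations.
#' @slot groupMean group-mean [ConnectivityMatrix-class].
#' @slot edgeContributions matrix of mean per-edge shares of the split-half
#'   correlation (shares over a partition sum to 1).
#' @slot metric,band,corrected identifiers.
#' @slot nPartitions,seed provenance of the split-half randomisation.
#' @slot params list of every parameter needed to regenerate the report.
#' @export
setClass("ReliabilityReport",
  representation(
    splitHalf         = "numeric",
    splitHalfZ        = "numeric",
    withinSubject     = "data.frame",
    betweenSubject    = "numeric",
    groupMean         = "ConnectivityMatrix",
    edgeContributions = "matrix",
    metric            = "character",
    band              = "character",
    corrected         = "logical",
    nPartitions       = "integer",
    seed              = "integer",
    params            = "list"
  )
)
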