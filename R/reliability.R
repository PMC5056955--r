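#' @include synthetic.R
NULL

#' Fisher transformation of a correlation coefficient
#'
#' `Z = atanh(rho)`, a monotonic, variance-stabilising transform that
#' separates correlations near unity. Values with `|rho| = 1` (to within
#' floating-point) are clamped to `1 - 1e-15` and flagged via the
#' `"clamped"` attribute.
#'
#' @param rho correlations, `|rho| <= 1`.
#' @return Fisher-Z values; `attr(, "clamped")` marks clamped entries.
#' @examples
#' fisherZ(0.5)  # 0.5493061
#' @export
fisherZ <- function(rho) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("|rho| > 1 is not a correlation")
  clamped <- abs(rho) >= 1 - 1e-15
  rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  z <- atanh(rho)
  if (any(clamped, na.rm = TRUE)) attr(z, "clamped") <- clamped
  z
}

#' @rdname fisherZ
#' @param z Fisher-Z values.
#' @export
fisherZInv <- function(z) tanh(z)

#' Bundle per-session connectivity matrices into a study collection
#'
#' @param matrices list of \linkS4class{ConnectivityMatrix} objects for one
#'   metric and band (subject/session labels are read from each matrix).
#' @return a \linkS4class{StudyNetworks}.
#' @export
studyNetworks <- function(matrices) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, is, logical(1), "ConnectivityMatrix")))
  m1 <- matrices[[1L]]
  new("StudyNetworks", matrices = matrices,
      subjects = vapply(matrices, function(m) m@subjectId, character(1)),
      sessions = vapply(matrices, function(m) m@sessionId, character(1)),
      metric = m1@metric, band = m1@band, directed = m1@directed)
}

#' Vectorise a connectivity matrix's edges
#'
#' Undirected metrics use the upper triangle only (no diagonal, no
#' double-counted edges); directed metrics use all off-diagonal entries.
#'
#' @param m a \linkS4class{ConnectivityMatrix} or square matrix.
#' @param directed vectorisation rule when `m` is a plain matrix.
#' @return numeric vector of edge strengths.
#' @export
vectoriseEdges <- function(m, directed = FALSE) {
  if (is(m, "ConnectivityMatrix")) {
    directed <- m@directed
    m <- m@values
  }
  if (directed) m[row(m) != col(m)] else m[upper.tri(m)]
}

# Edge-by-session matrix for a study; edges undefined (NA) in any session
# are dropped consistently.
.edgeMatrix <- function(nets) {
  E <- vapply(nets@matrices, vectoriseEdges,
              numeric(length(vectoriseEdges(nets@matrices[[1L]]))))
  keep <- stats::complete.cases(E)
  structure(E[keep, , drop = FALSE], keep = keep)
}

# Back-fill a group-mean edge vector into a square matrix.
.unvectorise <- function(edges, n, directed) {
  M <- matrix(NA_real_, n, n)
  if (directed) M[row(M) != col(M)] <- edges else {
    M[upper.tri(M)] <- edges
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
  }
  M
}

#' Group-mean connectivity matrix
#'
#' The mean value at each network connection over all sessions and
#' subjects. Correlation-valued metrics (AEC, partial AEC) are averaged in
#' Fisher-Z space and back-transformed; all other metrics are averaged
#' arithmetically. The rule applied is recorded in the returned matrix's
#' `averaging` attribute.
#'
#' @param nets a \linkS4class{StudyNetworks}.
#' @return a \linkS4class{ConnectivityMatrix} of group means.
#' @export
groupMean <- function(nets) {
  stopifnot(is(nets, "StudyNetworks"))
  info <- metricInfo(nets@metric)
  vals <- vapply(nets@matrices, vectoriseEdges,
                 numeric(length(vectoriseEdges(nets@matrices[[1L]]))))
  if (!is.matrix(vals)) vals <- rbind(vals)
  mean_ <- if (info$correlationType) {
    fisherZInv(rowMeans(fisherZ(vals)))
  } else {
    rowMeans(vals)
  }
  m1 <- nets@matrices[[1L]]
  out <- new("ConnectivityMatrix",
             values = .unvectorise(mean_, nrow(m1@values), nets@directed),
             metric = nets@metric, directed = nets@directed,
             leakageCorrected = m1@leakageCorrected,
             flags = matrix(FALSE, nrow(m1@values), nrow(m1@values)),
             band = nets@band, subjectId = "group", sessionId = "mean")
  attr(out@values, "averaging") <-
    if (info$correlationType) "fisher-z" else "arithmetic"
  out
}

#' Split-half consistency of group-level network estimation
#'
#' Randomly divides the subjects in half `nPartitions` times (all sessions
#' of a subject stay in one half; odd counts split floor/ceil), computes
#' the group-mean network of each half, and correlates the two halves'
#' edge vectors. The distribution of these correlations measures the
#' stability of group-level inference.
#'
#' @param nets a \linkS4class{StudyNetworks} with >= 4 subjects.
#' @param nPartitions number of random partitions (default 100).
#' @param seed RNG seed for the partitioning.
#' @param contributions also return the per-edge contribution shares,
#'   averaged over partitions.
#' @return list with `rho` (per-partition Pearson correlations), `z`
#'   (Fisher-transformed, clamped at unity with a flag), and, when
#'   requested, `meanContributions` (per-edge shares aligned with
#'   [vectoriseEdges()], averaged over partitions).
#' @export
splitHalfConsistency <- function(nets, nPartitions = 100L, seed = 1L,
                                 contributions = FALSE) {
  stopifnot(is(nets, "StudyNetworks"))
  subjects <- unique(nets@subjects)
  if (length(subjects) < 4L)
    stop("split-half consistency needs at least 4 subjects")
  info <- metricInfo(nets@metric)
  E <- .edgeMatrix(nets)
  half <- floor(length(subjects) / 2)
  set.seed(seed)
  rho <- numeric(nPartitions)
  shareAcc <- 0
  for (b in seq_len(nPartitions)) {
    g1 <- sample(subjects, half)
    in1 <- nets@subjects %in% g1
    m1 <- .halfMean(E[, in1, drop = FALSE], info$correlationType)
    m2 <- .halfMean(E[, !in1, drop = FALSE], info$correlationType)
    rho[b] <- stats::cor(m1, m2)
    if (contributions)
      shareAcc <- shareAcc + edgeContributions(m1, m2)
  }
  out <- list(rho = rho, z = fisherZ(rho))
  if (contributions) {
    full <- rep(NA_real_, length(attr(E, "keep")))
    full[attr(E, "keep")] <- shareAcc / nPartitions
    out$meanContributions <- full
  }
  out
}

.halfMean <- function(E, correlationType) {
  if (correlationType) fisherZInv(rowMeans(fisherZ(E))) else rowMeans(E)
}

#' Within-subject consistency of network estimation
#'
#' Correlates edge strengths between the network matrices of every
#' unordered pair of sessions within each subject (three sessions give
#' three pairs per subject). Subjects with a single session are skipped
#' with a warning.
#'
#' @param nets a \linkS4class{StudyNetworks}.
#' @return data.frame with columns `subject`, `sessionA`, `sessionB`,
#'   `rho`, `z`.
#' @export
withinSubjectConsistency <- function(nets) {
  stopifnot(is(nets, "StudyNetworks"))
  E <- .edgeMatrix(nets)
  out <- list()
  for (s in unique(nets@subjects)) {
    idx <- which(nets@subjects == s)
    if (length(idx) < 2L) {
      warning("subject ", s, " has a single session; skipped")
      next
    }
    prs <- utils::combn(idx, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1L, k]; j <- prs[2L, k]
      out[[length(out) + 1L]] <- data.frame(
        subject = s, sessionA = nets@sessions[i],
        sessionB = nets@sessions[j],
        rho = stats::cor(E[, i], E[, j]))
    }
  }
  if (length(out) == 0L) stop("no subject has two or more sessions")
  res <- do.call(rbind, out)
  res$z <- as.numeric(fisherZ(res$rho))
  res
}

#' Between-subject consistency of network estimation
#'
#' Correlates edge strengths between network matrices of distinct
#' subjects. By default every cross-subject session pair is used; the
#' `"subject_mean"` scheme first averages each subject's sessions (with
#' the metric's group-mean rule) and correlates the subject means.
#'
#' @param nets a \linkS4class{StudyNetworks} with >= 2 subjects.
#' @param scheme `"sessions"` (all cross-subject session pairs) or
#'   `"subject_mean"`.
#' @return numeric vector of correlations, with Fisher-Z values in
#'   `attr(, "z")`.
#' @export
betweenSubjectConsistency <- function(nets,
                                      scheme = c("sessions",
                                                 "subject_mean")) {
  stopifnot(is(nets, "StudyNetworks"))
  scheme <- match.arg(scheme)
  subjects <- unique(nets@subjects)
  if (length(subjects) < 2L)
    stop("between-subject consistency needs at least 2 subjects")
  info <- metricInfo(nets@metric)
  E <- .edgeMatrix(nets)
  cols <- if (scheme == "subject_mean") {
    M <- vapply(subjects, function(s)
      .halfMean(E[, nets@subjects == s, drop = FALSE],
                info$correlationType), numeric(nrow(E)))
    list(M = M, subj = subjects)
  } else {
    list(M = E, subj = nets@subjects)
  }
  prs <- utils::combn(ncol(cols$M), 2L)
  cross <- cols$subj[prs[1L, ]] != cols$subj[prs[2L, ]]
  rho <- vapply(which(cross), function(k)
    stats::cor(cols$M[, prs[1L, k]], cols$M[, prs[2L, k]]), numeric(1))
  attr(rho, "z") <- as.numeric(fisherZ(rho))
  rho
}

#' Edge-level decomposition of a network correlation
#'
#' Writing each edge vector in standardised form `z_i = (x_i - mean(x)) /
#' sqrt(sum((x - mean(x))^2))`, the Pearson correlation between two edge
#' vectors is `rho = sum_i z_i^x z_i^y`, so the element-wise products
#' attribute the correlation to individual edges. The returned shares
#' `z_i^x z_i^y / rho` sum to exactly 1.
#'
#' @param x,y equal-length edge vectors with at least 2 entries and
#'   nonzero variance.
#' @return vector of per-edge shares; `attr(, "rho")` holds the
#'   reconstructed Pearson correlation.
#' @export
edgeContributions <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("edge contributions are undefined for a constant edge vector")
  zx <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(sum((y - mean(y))^2))
  rho <- sum(zx * zy)
  shares <- zx * zy / rho
  attr(shares, "rho") <- rho
  shares
}
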