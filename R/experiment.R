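#' @include reliability.R
NULL

#' Compute one connectivity matrix from one session
#'
#' The full per-session pipeline for a single metric: band-pass filter,
#' optional symmetric orthogonalisation over the metric's correction
#' window (whole series for correlation/spectral/AR measures, per epoch
#' for phase measures), signal decomposition, and the metric itself.
#'
#' @param ts a broadband (or pre-filtered) \linkS4class{TimeSeriesSet}.
#' @param metric a metric id from [metricInfo()].
#' @param band band name (default: the session's band if named, else
#'   "alpha").
#' @param orthogonalise apply the leakage correction first.
#' @param epochS epoch length (s) for phase metrics.
#' @param welchS Welch window length (s) for spectral metrics.
#' @param arOrder AR order override for `pdc` (NULL: band default).
#' @param nBins phase histogram bins for `mi`.
#' @param cvFolds folds for the `paec` penalty search.
#' @param seed seed for the `paec` cross-validation folds.
#' @return a \linkS4class{ConnectivityMatrix}.
#' @examples
#' d <- studyDesign(nSubjects = 1, durationS = 30, fs = 100, seed = 7)
#' s <- simulateSession(makeNetwork(3, 0.5, seed = 7), d, seed = 7)
#' computeMetric(s, "plv")
#' @export
computeMetric <- function(ts, metric, band = NULL, orthogonalise = FALSE,
                          epochS = 10, welchS = 10, arOrder = NULL,
                          nBins = 16L, cvFolds = 5L, seed = 1L) {
  stopifnot(is(ts, "TimeSeriesSet"))
  info <- metricInfo(metric)
  if (is.null(band))
    band <- if (identical(ts@band, "broadband")) "alpha" else ts@band
  filtered <- if (identical(ts@band, band)) ts else bandpass(ts, band)
  if (orthogonalise)
    filtered <- applyCorrectionPolicy(filtered, info$correctionClass,
                                      epochS = epochS)
  out <- switch(metric,
    plv  = plv(epochSignal(filtered, epochS)),
    pli  = pli(epochSignal(filtered, epochS)),
    wpli = wpli(epochSignal(filtered, epochS)),
    mi   = phaseMI(epochSignal(filtered, epochS), nBins = nBins),
    psi  = phaseSlopeIndex(filtered, band = band, epochS = epochS),
    coh  = coherenceMatrix(welchCrossSpectrum(filtered, welchS), band),
    imc  = imaginaryCoherency(welchCrossSpectrum(filtered, welchS), band),
    pcoh = partialCoherence(welchCrossSpectrum(filtered, welchS), band),
    impc = imaginaryPartialCoherency(welchCrossSpectrum(filtered, welchS),
                                     band),
    pdc  = pdc(fitVAR(filtered, band, order = arOrder), band),
    aec  = aec(powerEnvelope(analytic(filtered))),
    paec = partialAEC(powerEnvelope(analytic(filtered)),
                      cvFolds = cvFolds, seed = seed)
  )
  out@leakageCorrected <- orthogonalise
  out
}

#' Run the full reliability experiment on a study
#'
#' For each requested metric and correction state, computes a connectivity
#' matrix per session, then the three consistency tests (split-half
#' group consistency, within-subject and between-subject consistency), the
#' group-mean network and the mean edge-contribution map. By default,
#' leakage-sensitive metrics are evaluated both raw and orthogonalised
#' while leakage-robust metrics are evaluated raw only; set
#' `correctAll = TRUE` to add the corrected state for every metric.
#'
#' @param study a `megconnStudy` from [generateStudy()] (or a list of
#'   \linkS4class{TimeSeriesSet} sessions plus a design).
#' @param metrics character vector of metric ids (default: all twelve).
#' @param band band name (default: the study design's band).
#' @param correctAll evaluate the orthogonalised state for every metric.
#' @param nPartitions split-half partitions (default 100).
#' @param seed seed for the split-half partitioning and penalty CV.
#' @param betweenScheme pairing scheme for [betweenSubjectConsistency()].
#' @param ... further arguments to [computeMetric()] (`arOrder`, `nBins`,
#'   `cvFolds`).
#' @return named list of \linkS4class{ReliabilityReport} objects, one per
#'   metric x correction state, named `"<metric>"` or
#'   `"<metric>_corrected"`.
#' @export
runExperiment <- function(study, metrics = metricInfo()$id, band = NULL,
                          correctAll = FALSE, nPartitions = 100L,
                          seed = 1L, betweenScheme = "sessions", ...) {
  stopifnot(inherits(study, "megconnStudy"))
  design <- study$design
  if (is.null(band)) band <- design@band
  reports <- list()
  for (metric in metrics) {
    info <- metricInfo(metric)
    states <- if (correctAll) c(FALSE, TRUE)
      else if (info$leakageRobust) FALSE else c(FALSE, TRUE)
    for (corrected in states) {
      mats <- lapply(study$sessions, computeMetric, metric = metric,
                     band = band, orthogonalise = corrected,
                     epochS = design@epochS, seed = seed, ...)
      nets <- studyNetworks(mats)
      sh <- splitHalfConsistency(nets, nPartitions = nPartitions,
                                 seed = seed, contributions = TRUE)
      ws <- withinSubjectConsistency(nets)
      bs <- betweenSubjectConsistency(nets, scheme = betweenScheme)
      gm <- groupMean(nets)
      nNode <- nrow(gm@values)
      rep_ <- new("ReliabilityReport",
        splitHalf = sh$rho, splitHalfZ = as.numeric(sh$z),
        withinSubject = ws, betweenSubject = as.numeric(bs),
        groupMean = gm,
        edgeContributions = .unvectorise(sh$meanContributions, nNode,
                                         info$directed),
        metric = metric, band = band, corrected = corrected,
        nPartitions = as.integer(nPartitions), seed = as.integer(seed),
        params = list(design = design, nPartitions = nPartitions,
                      seed = seed, betweenScheme = betweenScheme,
                      band = band, epochS = design@epochS))
      nm <- if (corrected) paste0(metric, "_corrected") else metric
      reports[[nm]] <- rep_
    }
  }
  reports
}

#' Long-format summary of reliability reports
#'
#' @param reports list of \linkS4class{ReliabilityReport} (from
#'   [runExperiment()]).
#' @return data.frame with columns `metric`, `band`, `corrected`, `test`,
#'   `value` (one row per individual correlation).
#' @export
reliabilityTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    rbind(
      data.frame(metric = r@metric, band = r@band, corrected = r@corrected,
                 test = "split_half", value = r@splitHalf),
      data.frame(metric = r@metric, band = r@band, corrected = r@corrected,
                 test = "within_subject", value = r@withinSubject$rho),
      data.frame(metric = r@metric, band = r@band, corrected = r@corrected,
                 test = "between_subject", value = r@betweenSubject))
  }))
}
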