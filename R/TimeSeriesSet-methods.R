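#' @include AllGenerics.R
NULL

#' Construct a TimeSeriesSet
#'
#' @param data numeric matrix, nodes x samples.
#' @param fs sampling rate in Hz.
#' @param band band label ("broadband" or a [bandRegistry()] name).
#' @param subjectId,sessionId character labels.
#' @return a \linkS4class{TimeSeriesSet}.
#' @examples
#' ts <- TimeSeriesSet(matrix(rnorm(400), nrow = 2), fs = 100)
#' nNodes(ts)
#' @export
TimeSeriesSet <- function(data, fs, band = "broadband",
                          subjectId = "s1", sessionId = "r1") {
  if (!is.matrix(data)) data <- rbind(data)
  storage.mode(data) <- "double"
  new("TimeSeriesSet", data = data, fs = fs, band = band,
      subjectId = as.character(subjectId), sessionId = as.character(sessionId))
}

#' @describeIn TimeSeriesSet node count.
#' @param x a TimeSeriesSet.
#' @export
setMethod("nNodes", "TimeSeriesSet", function(x) nrow(x@data))

#' @describeIn TimeSeriesSet sample count.
#' @export
setMethod("nSamples", "TimeSeriesSet", function(x) ncol(x@data))

#' @export
setMethod("samplingRate", "TimeSeriesSet", function(x) x@fs)

#' @export
setMethod("bandName", "TimeSeriesSet", function(x) x@band)

#' @export
setMethod("subjectId", "TimeSeriesSet", function(x) x@subjectId)

#' @export
setMethod("sessionId", "TimeSeriesSet", function(x) x@sessionId)

#' @export
setMethod("values", "TimeSeriesSet", function(x) x@data)

setMethod("show", "TimeSeriesSet", function(object) {
  cat("TimeSeriesSet:", nrow(object@data), "nodes x",
      ncol(object@data), "samples @", object@fs, "Hz\n")
  cat("  band:", object@band,
      " subject:", object@subjectId,
      " session:", object@sessionId, "\n")
})

#' @export
setMethod("nNodes", "AnalyticSet", function(x) nrow(x@h))

#' @export
setMethod("nSamples", "AnalyticSet", function(x) ncol(x@h))

#' @export
setMethod("samplingRate", "AnalyticSet", function(x) x@fs)

#' @export
setMethod("bandName", "AnalyticSet", function(x) x@band)

#' @export
setMethod("subjectId", "AnalyticSet", function(x) x@subjectId)

#' @export
setMethod("sessionId", "AnalyticSet", function(x) x@sessionId)

setMethod("show", "AnalyticSet", function(object) {
  cat("AnalyticSet:", nrow(object@h), "nodes x", ncol(object@h),
      "samples @", object@fs, "Hz;", nrow(object@epochs), "epoch(s),",
      object@edgeSamples, "edge samples flagged per epoch\n")
})

#' @export
setMethod("nNodes", "EnvelopeSet", function(x) nrow(x@env))

#' @export
setMethod("nSamples", "EnvelopeSet", function(x) ncol(x@env))

#' @export
setMethod("samplingRate", "EnvelopeSet", function(x) x@rate)

#' @export
setMethod("values", "EnvelopeSet", function(x) x@env)

setMethod("show", "EnvelopeSet", function(object) {
  cat("EnvelopeSet:", nrow(object@env), "nodes x", ncol(object@env),
      "samples @", object@rate, "Hz",
      if (object@logTransformed) "(log)" else "", "\n")
})

#' @export
setMethod("nNodes", "ConnectivityMatrix", function(x) nrow(x@values))

#' @export
setMethod("values", "ConnectivityMatrix", function(x) x@values)

#' @export
setMethod("bandName", "ConnectivityMatrix", function(x) x@band)

#' @export
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)

#' @export
setMethod("sessionId", "ConnectivityMatrix", function(x) x@sessionId)

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix [", object@metric, "]: ",
      nrow(object@values), " nodes, ",
      if (object@directed) "directed" else "undirected",
      if (object@leakageCorrected) ", leakage-corrected" else "",
      "; band ", object@band, "\n", sep = "")
})

#' @export
setMethod("values", "OrthogonalisationResult", function(x) x@corrected)

setMethod("show", "OrthogonalisationResult", function(object) {
  cat("OrthogonalisationResult:", nrow(object@corrected), "nodes x",
      ncol(object@corrected), "samples; displacement",
      format(object@displacement, digits = 4), "in",
      object@iterations, "iterations",
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
})

setMethod("show", "ReliabilityReport", function(object) {
  cat("ReliabilityReport [", object@metric,
      if (object@corrected) ", corrected" else "",
      "] band ", object@band, "\n", sep = "")
  cat("  split-half rho: median",
      format(stats::median(object@splitHalf), digits = 3),
      "over", object@nPartitions, "partitions\n")
  cat("  within-subject rho: median",
      format(stats::median(object@withinSubject$rho), digits = 3),
      "over", nrow(object@withinSubject), "session pairs\n")
  cat("  between-subject rho: median",
      format(stats::median(object@betweenSubject), digits = 3),
      "over", length(object@betweenSubject), "pairs\n")
})
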