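#' @include AllClasses.R
NULL

#' Number of network nodes in an object
#' @param x an object carrying node-wise data.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of time samples in an object
#' @param x an object carrying sampled data.
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate accessor
#' @param x an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Band label accessor
#' @param x an object with a band label.
#' @return band name.
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' Subject label accessor
#' @param x an object with a subject label.
#' @return subject id.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Session label accessor
#' @param x an object with a session label.
#' @return session id.
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' Extract the numeric payload of a container
#' @param x a \linkS4class{TimeSeriesSet}, \linkS4class{EnvelopeSet},
#'   \linkS4class{ConnectivityMatrix} or \linkS4class{OrthogonalisationResult}.
#' @return the underlying numeric (or complex) matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))
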