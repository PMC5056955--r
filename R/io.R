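#' @include experiment.R
NULL

.manifestPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                       ".manifest.yaml")

#' Write / read a session as delimited text plus a manifest
#'
#' The payload is a plain tab-separated nodes x samples matrix (diffable,
#' lossless for doubles via full precision formatting); the sidecar
#' manifest (`<stem>.manifest.yaml`) carries subject id, session id,
#' sampling rate, band and the package version.
#'
#' @param ts a \linkS4class{TimeSeriesSet}.
#' @param path output path for the matrix file (e.g. `session.tsv`).
#' @return `writeSession` returns `path` invisibly; `readSession` returns
#'   the reconstructed \linkS4class{TimeSeriesSet}, bitwise-equal payload.
#' @export
writeSession <- function(ts, path) {
  stopifnot(is(ts, "TimeSeriesSet"))
  utils::write.table(format(ts@data, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(kind = "session", nodes = nrow(ts@data),
                        samples = ncol(ts@data), fs = ts@fs,
                        band = ts@band, subject_id = ts@subjectId,
                        session_id = ts@sessionId,
                        version = as.character(
                          utils::packageVersion("megconn"))),
                   .manifestPath(path))
  invisible(path)
}

#' @rdname writeSession
#' @param path path of a matrix file written by `writeSession`.
#' @export
readSession <- function(path) {
  mf <- .manifestPath(path)
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  man <- yaml::read_yaml(mf)
  if (!identical(man$kind, "session"))
    stop("manifest does not describe a session")
  M <- as.matrix(utils::read.table(path, sep = "\t",
                                   colClasses = "numeric"))
  dimnames(M) <- NULL
  if (nrow(M) != man$nodes || ncol(M) != man$samples)
    stop("payload is ", nrow(M), "x", ncol(M),
         " but the manifest declares ", man$nodes, "x", man$samples)
  TimeSeriesSet(M, fs = man$fs, band = man$band,
                subjectId = man$subject_id, sessionId = man$session_id)
}

#' Write / read a connectivity matrix as delimited text plus a manifest
#'
#' Flagged (undefined) edges are stored as NA in the payload and their
#' positions recorded in the manifest, so flags survive a round trip.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param path output path (e.g. `aec_alpha.tsv`).
#' @return `writeMatrix` returns `path` invisibly; `readMatrix` the
#'   reconstructed \linkS4class{ConnectivityMatrix}.
#' @export
writeMatrix <- function(m, path) {
  stopifnot(is(m, "ConnectivityMatrix"))
  utils::write.table(format(m@values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(kind = "connectivity", metric = m@metric,
                        nodes = nrow(m@values), directed = m@directed,
                        leakage_corrected = m@leakageCorrected,
                        band = m@band, subject_id = m@subjectId,
                        session_id = m@sessionId,
                        flagged = which(m@flags),
                        version = as.character(
                          utils::packageVersion("megconn"))),
                   .manifestPath(path))
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  mf <- .manifestPath(path)
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  man <- yaml::read_yaml(mf)
  if (!identical(man$kind, "connectivity"))
    stop("manifest does not describe a connectivity matrix")
  M <- as.matrix(utils::read.table(path, sep = "\t", na.strings = "NA",
                                   colClasses = "numeric"))
  dimnames(M) <- NULL
  if (nrow(M) != man$nodes || ncol(M) != man$nodes)
    stop("payload is ", nrow(M), "x", ncol(M),
         " but the manifest declares ", man$nodes, "x", man$nodes)
  flags <- matrix(FALSE, man$nodes, man$nodes)
  flags[unlist(man$flagged)] <- TRUE
  new("ConnectivityMatrix", values = M, metric = man$metric,
      directed = man$directed, leakageCorrected = man$leakage_corrected,
      flags = flags, band = man$band, subjectId = man$subject_id,
      sessionId = man$session_id)
}

.CONFIG_DEFAULTS <- list(
  n_subjects     = 61L,
  n_sessions     = 3L,
  duration_s     = 360,
  fs             = 300,
  band           = "alpha",
  subject_sd     = 0.1,
  noise_sd       = 0.2,
  epoch_s        = 10,
  welch_s        = 10,
  n_partitions   = 100L,
  metrics        = c("aec", "paec", "coh", "imc", "pcoh", "impc",
                     "plv", "pli", "wpli", "psi", "mi", "pdc"),
  network_density  = 0.3,
  coupling_mode    = "envelope",
  leakage_weight   = 0.3,
  ar_order         = NULL,
  mi_bins          = 16L,
  cv_folds         = 5L,
  seed             = 1L,
  output_dir       = "."
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults (10 s epochs and Welch
#' windows, 100 split-half partitions, 3 sessions per subject, the alpha
#' band), and rejects unknown keys or unknown metric/band names. An empty
#' or absent-keys file yields all defaults.
#'
#' @param path YAML file path.
#' @return validated configuration list of class `megconnConfig`.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, raw)
  badMetric <- setdiff(cfg$metrics, .METRICS$id)
  if (length(badMetric))
    stop("unknown metric name(s): ", paste(badMetric, collapse = ", "),
         call. = FALSE)
  bandLimits(cfg$band)
  if (!cfg$coupling_mode %in% c("envelope", "phase_lag", "ar_process"))
    stop("unknown coupling mode: ", cfg$coupling_mode, call. = FALSE)
  structure(cfg, class = "megconnConfig")
}

#' @export
print.megconnConfig <- function(x, ...) {
  cat("megconn configuration:\n")
  for (k in names(x))
    cat("  ", k, ": ", paste(format(x[[k]]), collapse = " "), "\n",
        sep = "")
  invisible(x)
}
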