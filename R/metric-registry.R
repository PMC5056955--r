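#' @include metrics-amplitude.R
NULL

.METRICS <- data.frame(
  id          = c("aec", "paec", "coh", "imc", "pcoh", "impc",
                  "plv", "pli", "wpli", "psi", "mi", "pdc"),
  name        = c("amplitude envelope correlation",
                  "partial amplitude envelope correlation",
                  "coherence", "imaginary coherency",
                  "partial coherence", "imaginary partial coherency",
                  "phase-locking value", "phase lag index",
                  "weighted phase lag index", "phase slope index",
                  "phase mutual information", "partial directed coherence"),
  directed    = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
  # Pearson-correlation-valued metrics: group means are taken in Fisher-Z
  # space and back-transformed.
  correlationType = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  # robust to zero-lag leakage without any correction
  leakageRobust   = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                      FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
  # window over which the orthogonalisation is applied when requested
  correctionClass = c("whole_series", "whole_series", "whole_series",
                      "whole_series", "whole_series", "whole_series",
                      "per_epoch", "per_epoch", "per_epoch", "per_epoch",
                      "per_epoch", "whole_series"),
  stringsAsFactors = FALSE
)

#' Properties of the twelve connectivity metrics
#'
#' @param metric optional metric id; with no argument the full table is
#'   returned.
#' @return data.frame with columns `id`, `name`, `directed`,
#'   `correlationType` (averaged in Fisher-Z space), `leakageRobust`
#'   (insensitive to zero-lag mixing without correction) and
#'   `correctionClass` (window over which orthogonalisation is applied:
#'   whole series for correlation/spectral/AR measures, per epoch for
#'   phase measures).
#' @examples
#' metricInfo("pli")
#' @export
metricInfo <- function(metric = NULL) {
  if (is.null(metric)) return(.METRICS)
  row <- .METRICS[.METRICS$id == metric, ]
  if (nrow(row) == 0L)
    stop("unknown metric '", metric, "'; known metrics: ",
         paste(.METRICS$id, collapse = ", "), call. = FALSE)
  row
}
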