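#' @include AllClasses.R
NULL

# Canonical oscillatory band edges (Hz) used throughout the pipeline.
.BANDS <- list(
  delta      = c(1, 4),
  theta      = c(4, 8),
  alpha      = c(8, 13),
  beta       = c(13, 30),
  low_beta   = c(13, 20),
  high_beta  = c(20, 30),
  low_gamma  = c(30, 48)
)

#' The registry of named frequency bands
#'
#' Standard electrophysiological bands: delta (1-4 Hz), theta (4-8 Hz),
#' alpha (8-13 Hz), beta (13-30 Hz), low beta (13-20 Hz), high beta
#' (20-30 Hz) and low gamma (30-48 Hz).
#'
#' @return named list of `c(low, high)` band edges in Hz.
#' @examples
#' bandRegistry()$alpha  # 8 13
#' @export
bandRegistry <- function() .BANDS

#' Band edges for a named band
#'
#' @param band a band name from [bandRegistry()], or "broadband".
#' @return numeric `c(low, high)` in Hz (`NULL` for "broadband").
#' @export
bandLimits <- function(band) {
  if (identical(band, "broadband")) return(NULL)
  if (!band %in% names(.BANDS))
    stop("unknown band '", band, "'; known bands: ",
         paste(names(.BANDS), collapse = ", "), call. = FALSE)
  .BANDS[[band]]
}
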