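#' Standard EEG frequency band table
#'
#' Canonical clinical band edges in Hz: delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-50, plus `raw` covering the full analysed range
#' 1-50 Hz. Bands are half-open `[f_lo, f_hi)`; the 50 Hz ceiling is
#' inclusive for `gamma` and `raw` so that the five narrow bands partition
#' `raw` with no bin counted twice.
#'
#' @return Data frame with columns `name`, `f_lo`, `f_hi`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("raw", "delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(1, 1, 4, 8, 13, 30),
    f_hi = c(50, 4, 8, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Look up or construct a band definition
#'
#' @param band Either a band name from [eeg_bands()] or a list/one-row data
#'   frame with `name`, `f_lo`, `f_hi`.
#' @return A one-row data frame band definition.
#' @export
band_definition <- function(band) {
  if (is.character(band) && length(band) == 1L) {
    tab <- eeg_bands()
    hit <- tab[tab$name == band, ]
    if (!nrow(hit)) stop("unknown band name: ", band)
    return(hit)
  }
  band <- as.data.frame(as.list(band), stringsAsFactors = FALSE)
  if (!all(c("name", "f_lo", "f_hi") %in% names(band)))
    stop("a band needs fields name, f_lo, f_hi")
  if (!(band$f_lo > 0 && band$f_lo < band$f_hi && band$f_hi <= 50))
    stop("band edges must satisfy 0 < f_lo < f_hi <= 50")
  band[c("name", "f_lo", "f_hi")]
}

# Frequency selector implementing the half-open [lo, hi) convention with the
# 50 Hz ceiling inclusive.
.band_mask <- function(freqs, band) {
  lo <- band$f_lo; hi <- band$f_hi
  sel <- freqs >= lo - 1e-9 & freqs < hi - 1e-9
  if (hi >= 50 - 1e-9) sel <- sel | abs(freqs - hi) < 1e-9
  sel
}
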