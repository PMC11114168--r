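#' Segment an annotated event into non-overlapping windows
#'
#' Cuts the samples of one annotated event into consecutive non-overlapping
#' windows of `window_seconds` (default 2 s); a trailing remainder shorter
#' than one window is dropped, so an event of duration `d` yields
#' `floor(d / window_seconds)` segments.
#'
#' @param recording An [eeg_recording()] whose annotations contain `event`.
#' @param event Event name to extract (e.g. `"MA1"`).
#' @param window_seconds Window length in seconds; `window_seconds * rate`
#'   must be an integer.
#' @return A `segment_set`: list with `event`, `segments` (array channels x
#'   samples x segments), `window_seconds`, `rate`, `channel_labels`.
#' @export
segment_event <- function(recording, event, window_seconds = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  ann <- recording$annotations
  hit <- ann[ann$label == event, ]
  if (!nrow(hit)) .stop_missing(paste0("event '", event, "'"),
                                "recording annotations")
  hit <- hit[1, ]
  Q <- window_seconds * recording$rate
  if (abs(Q - round(Q)) > 1e-9)
    stop("window_seconds * rate must be an integer number of samples")
  Q <- as.integer(round(Q))
  N <- floor(hit$duration / window_seconds)
  if (N < 1)
    stop("event '", event, "' (", hit$duration,
         " s) is shorter than the window (", window_seconds, " s)")
  idx <- .sample_window(recording$rate, hit$onset, N * window_seconds)
  block <- recording$data[, idx[1]:idx[2], drop = FALSE]
  segs <- array(block, dim = c(nrow(block), Q, N))
  structure(list(event = event, segments = segs,
                 window_seconds = window_seconds, rate = recording$rate,
                 channel_labels = recording$channel_labels),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<segment_set> event %s: %d segments x %d channels x %d samples (%g s windows)\n",
              x$event, d[3], d[1], d[2], x$window_seconds))
  invisible(x)
}

# Taper vector by name.
.taper <- function(window_fn, Q) {
  switch(window_fn,
    hamming = as.numeric(signal::hamming(Q)),
    rectangular = rep(1, Q),
    stop("unknown window function: ", window_fn))
}

#' Windowed periodogram of every segment and channel
#'
#' For each segment `n` and channel `m` computes the tapered power
#' `p[n, m, f] = |(1/Q) * sum_k w(k) x(k) exp(-i 2 pi f k T)|^2` on the DFT
#' frequency grid of the window (`f = k / (Q T)`), restricted to
#' `f_lo <= f <= f_hi`. The 1/Q normalization is used as-is (no taper-power
#' compensation); all downstream statistics live inside this convention.
#'
#' @param segset A [segment_event()] result.
#' @param window_fn Taper name, `"hamming"` (default) or `"rectangular"`.
#' @param f_lo,f_hi Frequency range in Hz (defaults 1 and 50).
#' @return A `spectra_grid`: list with `p` (array segments x channels x
#'   frequencies), `freqs`, `window_fn`, `rate`, `channel_labels`.
#' @export
periodogram <- function(segset, window_fn = "hamming", f_lo = 1, f_hi = 50) {
  stopifnot(inherits(segset, "segment_set"))
  d <- dim(segset$segments)
  M <- d[1]; Q <- d[2]; N <- d[3]
  if (N < 1) stop("empty segment set")
  if (f_hi > segset$rate / 2 + 1e-9)
    stop("f_hi exceeds the Nyquist frequency ", segset$rate / 2, " Hz")
  w <- .taper(window_fn, Q)
  freqs_all <- seq(0, Q - 1) * segset$rate / Q
  sel <- which(freqs_all >= f_lo - 1e-9 & freqs_all <= f_hi + 1e-9)
  if (!length(sel)) stop("no DFT bins inside [", f_lo, ", ", f_hi, "] Hz")
  # columns ordered channel-fastest, then segment
  X <- matrix(aperm(segset$segments, c(2, 1, 3)), nrow = Q)
  P <- Mod(stats::mvfft(X * w) / Q)^2
  p <- aperm(array(P[sel, , drop = FALSE], dim = c(length(sel), M, N)),
             c(3, 2, 1))
  structure(list(p = p, freqs = freqs_all[sel], window_fn = window_fn,
                 rate = segset$rate, channel_labels = segset$channel_labels,
                 event = segset$event),
            class = "spectra_grid")
}

#' Per-segment channel-weighted frequency power summation
#'
#' The segment statistic `S_n = (1/M) * sum_m sum_f f * p[n, m, f]`: each
#' spectral power value is weighted by its frequency in Hz, summed over the
#' band's frequencies and averaged over channels. Units Hz * uV^2.
#'
#' @param grid A [periodogram()] result.
#' @param band A band name or definition (see [band_definition()]); the sum
#'   runs over `[f_lo, f_hi)`, with the 50 Hz ceiling inclusive for `gamma`
#'   and `raw`.
#' @return A `segment_scores` object: numeric vector `S` of length N with
#'   attributes `band` and `event`.
#' @export
segment_scores <- function(grid, band = "raw") {
  stopifnot(inherits(grid, "spectra_grid"))
  band <- band_definition(band)
  sel <- .band_mask(grid$freqs, band)
  if (!any(sel)) stop("band '", band$name, "' is disjoint from the grid")
  d <- dim(grid$p)
  N <- d[1]; M <- d[2]
  arr <- grid$p[, , sel, drop = FALSE]
  wts <- rep(grid$freqs[sel], each = M)
  S <- as.numeric(matrix(arr, nrow = N) %*% wts) / M
  structure(S, band = band$name, event = grid$event, class = "segment_scores")
}

#' Per-channel channel-weighted frequency power summation
#'
#' The channel statistic `S_m = (1/N) * sum_n sum_f f * p[n, m, f]`: the
#' frequency-weighted power sum of channel `m`, averaged over an event's
#' segments. A decibel view `10 * log10(S_m)` is included for topography
#' export.
#'
#' @inheritParams segment_scores
#' @return A data frame with columns `channel`, `S_m`, `S_m_dB` and
#'   attributes `band` and `event`.
#' @export
channel_scores <- function(grid, band = "raw") {
  stopifnot(inherits(grid, "spectra_grid"))
  band <- band_definition(band)
  sel <- .band_mask(grid$freqs, band)
  if (!any(sel)) stop("band '", band$name, "' is disjoint from the grid")
  d <- dim(grid$p)
  N <- d[1]; M <- d[2]
  if (N < 1) stop("no segments")
  arr <- grid$p[, , sel, drop = FALSE]
  # contract the frequency axis first, then average over segments
  fw <- matrix(arr, nrow = N * M) %*% grid$freqs[sel]  # (n, m) pairs
  Sm <- colMeans(matrix(fw, nrow = N, ncol = M))
  out <- data.frame(channel = grid$channel_labels, S_m = Sm,
                    S_m_dB = 10 * log10(Sm), stringsAsFactors = FALSE)
  attr(out, "band") <- band$name
  attr(out, "event") <- grid$event
  out
}
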