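#' Configuration for the synthetic EEG session generator
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: within each scheduled event every channel is a sum of one
#' band-limited sinusoid per active frequency band (frequency drawn uniformly
#' inside the band, fresh random phase per 2-s block) plus 1/f-shaped
#' Gaussian background noise. The band oscillations are a common field shared
#' across channels — the volume-conduction-like spatial correlation of real
#' scalp EEG — while the background noise is independent per channel. Rest
#' and fixation blocks use the `"rest"` profile. Eye blinks are stereotyped
#' 300-ms raised-cosine transients at Poisson onsets, scaled per channel by
#' frontally-peaked weights.
#'
#' Noise is synthesized independently per phase block, so the 2-s analysis
#' segments of an event are i.i.d. draws: two events generated from identical
#' profiles are exchangeable, which is what the type-I-error calibration of
#' the statistical stage requires.
#'
#' @param rate Sampling rate in Hz (default 125, the 16-channel OpenBCI
#'   daisy-chain rate).
#' @param n_channels Number of channels (default 16, labelled per
#'   [default_montage()]).
#' @param band_powers Named list: event name (or `"rest"`) -> named numeric
#'   vector of per-band oscillation amplitudes in microvolts. Events absent
#'   from the list fall back to `"rest"` only if they are rest/fixation
#'   blocks; a treatment event without a profile is an error.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (power), default 1.
#' @param noise_scale RMS amplitude of the background noise in microvolts.
#' @param blink_rate Blink events per minute (Poisson).
#' @param blink_amplitude Peak blink amplitude in microvolts at weight-1
#'   channels.
#' @param blink_channel_weights Named per-channel scaling in [0, 1]. Default:
#'   Fp1/Fp2 = 1, F3/F4/F7/F8 = 0.5, all others 0.05.
#' @param phase_block_seconds Length of the block after which sinusoid
#'   frequency/phase are redrawn and noise restarts (default 2, matching the
#'   segmentation window).
#' @param seed Integer seed; identical (config, schedule) pairs reproduce
#'   sessions exactly.
#' @return A `synth_config` list.
#' @export
synth_config <- function(rate = 125, n_channels = 16,
                         band_powers = default_band_powers(),
                         noise_exponent = 1, noise_scale = 2,
                         blink_rate = 12, blink_amplitude = 80,
                         blink_channel_weights = NULL,
                         phase_block_seconds = 2, seed = 1L) {
  if (rate <= 0 || n_channels < 1) stop("rate and n_channels must be positive")
  if (noise_scale < 0 || blink_amplitude < 0)
    stop("amplitudes and scales must be non-negative")
  if (blink_rate < 0) stop("blink_rate must be non-negative")
  labels <- if (n_channels <= 16) default_montage()[seq_len(n_channels)]
            else as.character(seq_len(n_channels))
  if (is.null(blink_channel_weights)) {
    w <- rep(0.05, n_channels); names(w) <- labels
    w[names(w) %in% c("Fp1", "Fp2")] <- 1
    w[names(w) %in% c("F3", "F4", "F7", "F8")] <- 0.5
    blink_channel_weights <- w
  }
  structure(list(rate = rate, n_channels = n_channels, labels = labels,
                 band_powers = band_powers, noise_exponent = noise_exponent,
                 noise_scale = noise_scale, blink_rate = blink_rate,
                 blink_amplitude = blink_amplitude,
                 blink_channel_weights = blink_channel_weights,
                 phase_block_seconds = phase_block_seconds,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default per-event band amplitude profiles
#'
#' All six treatment events share one alpha-dominant profile and rest blocks
#' a slightly weaker one, i.e. the default session is generated under the
#' null of no MA/VA difference. `ma_scale`/`va_scale` multiply the alpha-band
#' amplitude of the MA or VA events to build contrast scenarios.
#'
#' @param ma_scale,va_scale Multipliers on the alpha amplitude of MA / VA
#'   events (default 1 = null profile).
#' @return Named list of per-band amplitude vectors (microvolts).
#' @export
default_band_powers <- function(ma_scale = 1, va_scale = 1) {
  base <- c(delta = 4, theta = 3, alpha = 6, beta = 2, gamma = 1)
  rest <- c(delta = 4, theta = 3, alpha = 5, beta = 2, gamma = 1)
  prof <- list(rest = rest)
  for (ev in c("MA1", "MA2")) {
    p <- base; p["alpha"] <- p["alpha"] * ma_scale; prof[[ev]] <- p
  }
  for (ev in c("VA1", "VA2", "VA3", "VA4")) {
    p <- base; p["alpha"] <- p["alpha"] * va_scale; prof[[ev]] <- p
  }
  prof
}

# Band edges for profile names come from the standard band table.
.band_edges <- function(name) {
  tab <- eeg_bands()
  hit <- tab[tab$name == name, ]
  if (!nrow(hit)) stop("unknown band in band_powers: ", name)
  c(hit$f_lo, hit$f_hi)
}

# One event's worth of signal: channels x samples, built blockwise. Each
# band's oscillation is a common field shared by all channels (the
# volume-conduction-like spatial correlation of scalp EEG); the 1/f noise is
# independent per channel. Blocks are i.i.d. by construction.
.synth_event_signal <- function(config, n_samples, profile) {
  rate <- config$rate
  M <- config$n_channels
  Q <- round(config$phase_block_seconds * rate)
  n_blocks <- ceiling(n_samples / Q)
  total <- n_blocks * Q
  common <- numeric(total)
  tq <- (seq_len(Q) - 1) / rate
  active <- profile[profile > 0]
  for (b in names(active)) {
    edges <- .band_edges(b)
    fr <- stats::runif(n_blocks, edges[1], edges[2])
    ph <- stats::runif(n_blocks, 0, 2 * pi)
    arg <- outer(tq, 2 * pi * fr) + rep(ph, each = Q)
    common <- common + active[[b]] * as.vector(sin(arg))
  }
  out <- matrix(common, nrow = M, ncol = total, byrow = TRUE)
  if (config$noise_scale > 0)
    out <- out + .pink_noise_blocks(config, n_blocks, Q, M)
  out[, seq_len(n_samples), drop = FALSE]
}

# 1/f^beta Gaussian noise, independent per block, RMS = noise_scale exactly
# in expectation (deterministic spectral normalization, so blocks stay
# i.i.d.).
.pink_noise_blocks <- function(config, n_blocks, Q, M) {
  beta <- config$noise_exponent
  freqs <- seq(0, Q - 1) * config$rate / Q
  # two-sided amplitude shaping |H(f)| ~ f^(-beta/2); DC removed
  f_fold <- pmin(freqs, config$rate - freqs)
  h <- c(0, f_fold[-1]^(-beta / 2))
  h <- h * config$noise_scale / sqrt(sum(h^2) / Q)
  w <- matrix(stats::rnorm(Q * n_blocks * M), nrow = Q)
  z <- stats::mvfft(w) * h
  x <- Re(stats::mvfft(z, inverse = TRUE)) / Q
  t(matrix(as.vector(x), nrow = Q * n_blocks, ncol = M))
}

#' Generate a synthetic EEG session
#'
#' Produces a recording spanning the given schedule, with the per-event band
#' profiles, blockwise random sinusoid phases/frequencies and 1/f background
#' described in [synth_config()]. All randomness flows from `config$seed`:
#' equal (config, schedule) pairs give bit-identical recordings.
#'
#' @param config A [synth_config()].
#' @param schedule An [event_schedule()].
#' @return An [eeg_recording()] annotated with the schedule's events.
#' @export
generate_session <- function(config, schedule) {
  stopifnot(inherits(config, "synth_config"), inherits(schedule, "event_schedule"))
  # a recording is one continuous acquisition: the schedule's events must not
  # overlap in recording time even across day labels (generate per day instead)
  ord <- order(schedule$onset)
  ends <- (schedule$onset + schedule$duration)[ord]
  if (nrow(schedule) > 1 &&
      any(schedule$onset[ord][-1] < ends[-length(ends)] - 1e-9))
    stop("schedule events overlap in recording time; generate one session per day")
  total_s <- schedule_duration(schedule)
  n_total <- round(total_s * config$rate)
  if (n_total > 5e8) stop("schedule longer than representable duration")
  data <- matrix(0, nrow = config$n_channels, ncol = n_total)
  with_seed(derive_seed(config$seed, "session"), {
    for (i in seq_len(nrow(schedule))) {
      ev <- schedule[i, ]
      profile <- config$band_powers[[ev$name]]
      if (is.null(profile)) {
        if (ev$name %in% c("rest", "fixation"))
          profile <- config$band_powers[["rest"]]
        if (is.null(profile))
          stop("no band-power profile for event '", ev$name, "'")
      }
      idx <- .sample_window(config$rate, ev$onset, ev$duration)
      n_samples <- idx[2] - idx[1] + 1L
      data[, idx[1]:idx[2]] <- .synth_event_signal(config, n_samples, profile)
    }
  })
  ann <- schedule[c("name", "onset", "duration")]
  names(ann)[1] <- "label"
  eeg_recording(data, config$rate, config$labels, ann)
}

#' Inject stereotyped eye-blink artifacts
#'
#' Adds 300-ms raised-cosine pulses at Poisson-process onsets, scaled per
#' channel by `config$blink_channel_weights`, and returns the ground-truth
#' onset times for testing artifact removal.
#'
#' @param recording An [eeg_recording()].
#' @param config A [synth_config()]; uses `blink_rate` (per minute),
#'   `blink_amplitude`, `blink_channel_weights` and `seed`.
#' @return List with elements `recording` (artifacted copy), `onsets`
#'   (numeric vector, seconds) and `truth` (the summed blink waveform, one
#'   value per sample, unit peak amplitude).
#' @export
inject_blinks <- function(recording, config) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(config, "synth_config"))
  if (config$blink_rate < 0) stop("blink_rate must be non-negative")
  dur <- recording_duration(recording)
  blink_len <- 0.3
  if (config$blink_rate == 0 || config$blink_amplitude == 0 || dur <= blink_len)
    return(list(recording = recording, onsets = numeric(0),
                truth = rep(0, ncol(recording$data))))
  rate <- recording$rate
  n <- ncol(recording$data)
  onsets <- with_seed(derive_seed(config$seed, "blinks"), {
    k <- stats::rpois(1, config$blink_rate * dur / 60)
    sort(stats::runif(k, 0, dur - blink_len))
  })
  tmpl <- 0.5 * (1 - cos(2 * pi * seq(0, blink_len, by = 1 / rate) / blink_len))
  truth <- rep(0, n)
  for (on in onsets) {
    i0 <- round(on * rate) + 1L
    idx <- i0:min(n, i0 + length(tmpl) - 1L)
    truth[idx] <- truth[idx] + tmpl[seq_along(idx)]
  }
  w <- config$blink_channel_weights[recording$channel_labels]
  w[is.na(w)] <- 0
  add <- config$blink_amplitude * outer(as.numeric(w), truth)
  out <- recording
  out$data <- recording$data + add
  list(recording = out, onsets = onsets, truth = truth)
}
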