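# Shared builders for synthetic study material.

# All six treatment events back to back in one recording (no rest blocks),
# the compact layout used by the simulation studies.
six_event_schedule <- function(duration = 300) {
  event_schedule(data.frame(
    name = c("MA1", "MA2", "VA1", "VA2", "VA3", "VA4"),
    day = 1,
    onset = seq(0, by = duration, length.out = 6),
    duration = duration))
}

# Segment scores per event for one synthetic subject under an optional
# MA-alpha amplitude contrast.
simulate_event_scores <- function(seed, ma_scale = 1, n_channels = 4,
                                  duration = 300, noise_scale = 2,
                                  band = "raw") {
  cfg <- synth_config(n_channels = n_channels, noise_scale = noise_scale,
                      seed = seed,
                      band_powers = default_band_powers(ma_scale = ma_scale))
  rec <- generate_session(cfg, six_event_schedule(duration))
  sapply(c("MA1", "MA2", "VA1", "VA2", "VA3", "VA4"), function(ev)
    as.numeric(segment_scores(periodogram(segment_event(rec, ev)), band)),
    simplify = FALSE)
}

# One annotated single-event recording, the smallest useful fixture.
single_event_recording <- function(seed = 1, duration = 60, n_channels = 16,
                                   noise_scale = 2, ...) {
  cfg <- synth_config(n_channels = n_channels, noise_scale = noise_scale,
                      seed = seed, ...)
  generate_session(cfg, event_schedule(
    data.frame(name = "MA1", day = 1, onset = 0, duration = duration)))
}
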