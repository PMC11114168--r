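test_that("silent configuration produces an all-zero recording", {
  cfg <- synth_config(n_channels = 2, noise_scale = 0, seed = 1,
                      band_powers = list(rest = c(alpha = 0),
                                         MA1 = c(alpha = 0)))
  rec <- generate_session(cfg, event_schedule(
    data.frame(name = "MA1", day = 1, onset = 0, duration = 10)))
  expect_true(all(rec$data == 0))
})

test_that("equal seeds reproduce sessions bit for bit", {
  cfg <- synth_config(n_channels = 3, seed = 99)
  sched <- event_schedule(data.frame(
    name = c("MA1", "rest"), day = 1, onset = c(0, 10), duration = c(10, 6)))
  r1 <- generate_session(cfg, sched)
  r2 <- generate_session(cfg, sched)
  expect_identical(r1$data, r2$data)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(generate_session(cfg2, sched)$data, r1$data))
})

test_that("configured band contrasts appear in the generated spectra", {
  # alpha amplitude 10 in MA1, 0 in VA1: MA1 alpha power must dominate
  cfg <- synth_config(n_channels = 2, noise_scale = 1, seed = 5,
                      band_powers = list(rest = c(alpha = 2),
                                         MA1 = c(alpha = 10),
                                         VA1 = c(alpha = 0)))
  sched <- event_schedule(data.frame(
    name = c("MA1", "VA1"), day = 1, onset = c(0, 12), duration = 12))
  rec <- generate_session(cfg, sched)
  alpha_power <- function(ev) {
    g <- periodogram(segment_event(rec, ev), window_fn = "rectangular")
    mean(segment_scores(g, "alpha"))
  }
  expect_gt(alpha_power("MA1"), 10 * alpha_power("VA1"))
})

test_that("pure-band signals concentrate >= 95% of power in their band", {
  for (b in c("delta", "alpha", "gamma")) {
    prof <- stats::setNames(list(c(stats::setNames(5, b))), "MA1")
    prof$rest <- c(alpha = 0)
    cfg <- synth_config(n_channels = 2, noise_scale = 0, seed = 8,
                        band_powers = prof)
    rec <- generate_session(cfg, event_schedule(
      data.frame(name = "MA1", day = 1, onset = 0, duration = 20)))
    g <- periodogram(segment_event(rec, "MA1"), f_lo = 0.5, f_hi = 62.5)
    band <- band_definition(b)
    res <- g$freqs[2] - g$freqs[1]  # estimator resolution: one DFT bin
    sel <- g$freqs >= band$f_lo - res - 1e-9 &
      g$freqs <= band$f_hi + res + 1e-9
    strict <- g$freqs >= band$f_lo - 1e-9 & g$freqs <= band$f_hi + 1e-9
    tot <- apply(g$p[, 1, , drop = FALSE], 1, sum)
    inband <- apply(g$p[, 1, sel, drop = FALSE], 1, sum)
    expect_true(all(inband / tot > 0.95))
    expect_gt(mean(apply(g$p[, 1, strict, drop = FALSE], 1, sum) / tot), 0.95)
  }
})

test_that("blink injection is Poisson with the configured rate", {
  rec <- eeg_recording(matrix(0, 1, 50 * 300), 50,
                       channel_labels = "Fp1")
  cfg0 <- synth_config(rate = 50, n_channels = 1, blink_rate = 0, seed = 1)
  out0 <- inject_blinks(rec, cfg0)
  expect_identical(out0$recording$data, rec$data)
  expect_length(out0$onsets, 0)

  counts <- vapply(1:100, function(s) {
    cfg <- synth_config(rate = 50, n_channels = 1, blink_rate = 12, seed = s)
    length(inject_blinks(rec, cfg)$onsets)
  }, numeric(1))
  # mean of 100 Poisson(60) draws lies within 3 standard errors
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60 / 100))
  # determinism of a single draw
  cfg <- synth_config(rate = 50, n_channels = 1, blink_rate = 12, seed = 3)
  expect_identical(inject_blinks(rec, cfg)$onsets,
                   inject_blinks(rec, cfg)$onsets)
})

test_that("blink amplitude scales the injected waveform linearly", {
  rec <- eeg_recording(matrix(0, 2, 125 * 30), 125)
  cfg1 <- synth_config(n_channels = 2, blink_rate = 10, blink_amplitude = 40,
                       seed = 4)
  cfg2 <- cfg1; cfg2$blink_amplitude <- 80
  a1 <- inject_blinks(rec, cfg1)$recording$data
  a2 <- inject_blinks(rec, cfg2)$recording$data
  expect_equal(a2, 2 * a1)
})

test_that("blink weights peak frontally by default", {
  w <- synth_config()$blink_channel_weights
  expect_equal(unname(w[c("Fp1", "Fp2")]), c(1, 1))
  expect_true(all(w[c("F3", "F4", "F7", "F8")] == 0.5))
  expect_true(all(w[setdiff(names(w), frontal_channels())] <= 0.1))
})

test_that("treatment events without a profile are rejected", {
  cfg <- synth_config(band_powers = list(rest = c(alpha = 1)))
  expect_error(generate_session(cfg, six_event_schedule(10)),
               "no band-power profile")
})
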