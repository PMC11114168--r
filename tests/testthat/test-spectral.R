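make_annotated <- function(data, rate = 125, event = "MA1",
                           duration = ncol(data) / rate) {
  eeg_recording(data, rate,
                annotations = data.frame(label = event, onset = 0,
                                         duration = duration))
}

test_that("events are cut into floor(duration / window) ordered segments", {
  rate <- 125
  rec <- make_annotated(matrix(seq_len(2 * 300 * rate), nrow = 2), rate,
                        duration = 300)
  ss <- segment_event(rec, "MA1", 2)
  expect_equal(dim(ss$segments), c(2, 250, 150))
  # trailing remainder dropped
  rec7 <- make_annotated(matrix(rnorm(2 * 7 * rate), nrow = 2), rate,
                         duration = 7)
  expect_equal(dim(segment_event(rec7, "MA1", 2)$segments)[3], 3)
  # segments are consecutive, in onset order
  expect_equal(ss$segments[1, , 2], rec$data[1, 251:500])
  rec1 <- make_annotated(matrix(rnorm(125), nrow = 1), rate, duration = 1)
  expect_error(segment_event(rec1, "MA1", 2), "shorter than the window")
  expect_error(segment_event(rec, "VA1"), "not found")
})

test_that("periodogram matches the direct-summation oracle", {
  rate <- 20; Q <- 40
  set.seed(3)
  for (win in c("hamming", "rectangular")) {
    x <- matrix(rnorm(2 * Q * 3), nrow = 2)
    rec <- make_annotated(x, rate, duration = 6)
    g <- periodogram(segment_event(rec, "MA1", 2), window_fn = win,
                     f_lo = 1, f_hi = 10)
    w <- if (win == "hamming") as.numeric(signal::hamming(Q)) else rep(1, Q)
    for (n in 1:3) for (m in 1:2) {
      seg <- x[m, ((n - 1) * Q + 1):(n * Q)]
      expect_equal(g$p[n, m, ], periodogram_oracle(seg, w, rate, g$freqs),
                   tolerance = 1e-10)
    }
  }
})

test_that("a bin-centered unit sinusoid yields p = 1/4 at its frequency", {
  rate <- 125; Q <- 250
  t <- (0:(Q - 1)) / rate
  rec <- make_annotated(matrix(sin(2 * pi * 10 * t), nrow = 1), rate,
                        duration = 2)
  g <- periodogram(segment_event(rec, "MA1", 2), window_fn = "rectangular")
  expect_equal(g$p[1, 1, which(abs(g$freqs - 10) < 1e-9)], 0.25,
               tolerance = 1e-12)
  expect_lt(max(g$p[1, 1, abs(g$freqs - 10) > 1.1]), 1e-20)
})

test_that("periodogram is homogeneous of degree 2 and zero on silence", {
  rate <- 50
  x <- matrix(rnorm(100), nrow = 1)
  g1 <- periodogram(segment_event(make_annotated(x, rate, duration = 2),
                                  "MA1", 2), f_lo = 1, f_hi = 20)
  g2 <- periodogram(segment_event(make_annotated(3 * x, rate, duration = 2),
                                  "MA1", 2), f_lo = 1, f_hi = 20)
  expect_equal(g2$p, 9 * g1$p, tolerance = 1e-12)
  g0 <- periodogram(segment_event(make_annotated(0 * x, rate, duration = 2),
                                  "MA1", 2), f_lo = 1, f_hi = 20)
  expect_true(all(g0$p == 0))
})

test_that("segment scores implement the frequency-weighted channel mean", {
  # hand-built grid: one nonzero power entry p = 2 at f = 10 Hz
  grid <- structure(list(
    p = array(0, dim = c(1, 2, 3)), freqs = c(5, 10, 15),
    window_fn = "hamming", rate = 50, channel_labels = c("Fp1", "Fp2"),
    event = "MA1"), class = "spectra_grid")
  g1 <- grid; g1$p[1, 1, 2] <- 2
  expect_equal(as.numeric(segment_scores(g1, list(name = "x", f_lo = 1,
                                                  f_hi = 20))), 20 / 2)
  g2 <- grid; g2$p[1, , 2] <- 2  # duplicated on both channels
  expect_equal(as.numeric(segment_scores(g2, list(name = "x", f_lo = 1,
                                                  f_hi = 20))), 20)
  expect_equal(as.numeric(segment_scores(grid, list(name = "x", f_lo = 1,
                                                    f_hi = 20))), 0)
})

test_that("channel scores average the per-segment sums over segments", {
  grid <- structure(list(
    p = array(0, dim = c(2, 2, 2)), freqs = c(10, 20),
    window_fn = "hamming", rate = 50, channel_labels = c("Fp1", "Fp2"),
    event = "MA1"), class = "spectra_grid")
  v <- 1.5
  grid$p[1, 1, 1] <- v      # segment 1, channel 1, f = 10
  grid$p[2, 1, 1] <- 3 * v  # segment 2
  cs <- channel_scores(grid, list(name = "x", f_lo = 1, f_hi = 25))
  expect_equal(cs$S_m[1], 10 * 2 * v)  # mean of v and 3v, weighted by 10 Hz
  expect_equal(cs$S_m[2], 0)
  expect_equal(cs$S_m_dB[1], 10 * log10(10 * 2 * v))
})

test_that("channel and segment reductions agree and bands are additive", {
  rec <- single_event_recording(seed = 21, duration = 30, n_channels = 3)
  g <- periodogram(segment_event(rec, "MA1"))
  for (b in c("raw", "alpha")) {
    expect_equal(mean(segment_scores(g, b)),
                 mean(channel_scores(g, b)$S_m), tolerance = 1e-12)
  }
  parts <- Reduce(`+`, lapply(c("delta", "theta", "alpha", "beta", "gamma"),
                              function(b) as.numeric(segment_scores(g, b))))
  expect_equal(parts, as.numeric(segment_scores(g, "raw")), tolerance = 1e-12)
})

test_that("disjoint bands are rejected", {
  rec <- single_event_recording(seed = 1, duration = 10, n_channels = 2)
  g <- periodogram(segment_event(rec, "MA1"), f_lo = 1, f_hi = 20)
  expect_error(segment_scores(g, list(name = "hi", f_lo = 30, f_hi = 40)),
               "disjoint")
})
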