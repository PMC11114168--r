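rate <- 125

test_that("bandpass rejects DC and passes in-band sinusoids at unit gain", {
  n <- 80 * rate
  t <- (0:(n - 1)) / rate
  mid <- 3000:(n - 3000)
  dc <- eeg_recording(matrix(1, 1, n), rate, "Fp1")
  out <- bandpass_filter(dc, filter_spec())
  expect_equal(attr(out, "filter_order"), 4142L)
  expect_lt(max(abs(out$data[1, mid])), 0.01)

  s10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1, n), rate, "Fp1")
  f10 <- bandpass_filter(s10, filter_spec())
  expect_lt(abs(max(abs(f10$data[1, mid])) - 1), 0.01)
  # designed response confirms the measured gain
  expect_lt(abs(filter_response(filter_spec(), rate, 10) - 1), 0.01)
  expect_lt(filter_response(filter_spec(), rate, 60), 0.01)
})

test_that("filtering is linear and idempotent in the passband", {
  set.seed(1)
  n <- 60 * rate
  x <- matrix(rnorm(2 * n), 2, n)
  rec <- eeg_recording(x, rate)
  spec <- filter_spec()
  f1 <- bandpass_filter(rec, spec)
  rec3 <- rec; rec3$data <- 3 * rec$data
  f3 <- bandpass_filter(rec3, spec)
  expect_equal(f3$data, 3 * f1$data, tolerance = 1e-10)

  n2 <- 100 * rate
  t <- (0:(n2 - 1)) / rate
  s <- eeg_recording(matrix(sin(2 * pi * 12 * t), 1, n2), rate, "Fp1")
  once <- bandpass_filter(s, spec)
  twice <- bandpass_filter(once, spec)
  mid <- 5000:(n2 - 5000)
  a1 <- max(abs(once$data[1, mid])); a2 <- max(abs(twice$data[1, mid]))
  expect_lt(abs(a2 / a1 - 1), 0.02)
})

test_that("short recordings fall back to the derived order or error", {
  short <- eeg_recording(matrix(rnorm(2000), 1, 2000), rate, "Fp1")
  out <- bandpass_filter(short, filter_spec())
  expect_equal(attr(out, "filter_order"), 1650L)  # ceil(3.3 * 125 / 0.25)
  tiny <- eeg_recording(matrix(rnorm(100), 1, 100), rate, "Fp1")
  expect_error(bandpass_filter(tiny, filter_spec()), "shorter than the filter")
})

test_that("ICA recovers a known two-source mixture", {
  set.seed(5)
  ns <- 5000
  s1 <- sin(2 * pi * 7 * (0:(ns - 1)) / rate)
  s2 <- runif(ns, -1, 1)
  X <- matrix(c(1, 0.6, 0.4, 1), 2) %*% rbind(s1, s2)
  rec <- eeg_recording(X, rate, c("Fp1", "Fp2"))
  d <- decompose_ica(rec, 2, seed = 3)
  cc <- abs(stats::cor(t(d$sources), cbind(s1, s2)))
  expect_true(all(apply(cc, 2, max) > 0.95))
  # removed = empty reconstructs the input
  back <- remove_components(d, integer(0))
  expect_lt(norm(back$data - X, "F") / norm(X, "F"), 1e-6)
  # determinism after canonicalization
  d2 <- decompose_ica(rec, 2, seed = 3)
  expect_equal(d$mixing, d2$mixing, tolerance = 1e-6)
  expect_equal(d$sources, d2$sources, tolerance = 1e-6)
})

test_that("ICA rejects rank-deficient input and over-removal", {
  x <- rnorm(1000)
  rec <- eeg_recording(rbind(x, x), 125, c("Fp1", "Fp2"))
  expect_error(decompose_ica(rec, 2, seed = 1), "rank-deficient")
  rec2 <- single_event_recording(seed = 2, duration = 20, n_channels = 4)
  d <- decompose_ica(rec2, 4, seed = 1)
  expect_error(remove_components(d, 1:3), "at most 2")
  expect_silent(remove_components(d, 1:2))
})

test_that("blink components are flagged on artifacted data and not on clean", {
  clean <- single_event_recording(seed = 11, duration = 120)
  cfg <- synth_config(seed = 11, blink_rate = 12, noise_scale = 2)
  b <- inject_blinks(clean, cfg)
  dec <- decompose_ica(b$recording, 16, seed = 3)
  idx <- identify_artifact_components(dec, b$recording)
  expect_gte(length(idx), 1)
  expect_lte(length(idx), 2)
  expect_gt(max(abs(stats::cor(dec$sources[idx[1], ], b$truth))), 0.8)

  # clean sessions: empty set at the default threshold over several seeds
  for (s in 1:5) {
    cl <- single_event_recording(seed = s, duration = 60)
    d0 <- decompose_ica(cl, 16, seed = 3)
    expect_length(identify_artifact_components(d0, cl), 0)
  }
  # max_remove = 0 always yields the empty set
  expect_length(identify_artifact_components(dec, b$recording,
                                             max_remove = 0), 0)
})

test_that("component removal never increases total power", {
  rec <- single_event_recording(seed = 13, duration = 60)
  cfg <- synth_config(seed = 13, blink_rate = 12, noise_scale = 2)
  b <- inject_blinks(rec, cfg)
  dec <- decompose_ica(b$recording, 16, seed = 3)
  idx <- identify_artifact_components(dec, b$recording)
  cln <- remove_components(dec, idx)
  pw <- function(r) sum((r$data - rowMeans(r$data))^2)
  expect_lte(pw(cln), pw(b$recording) * (1 + 1e-8))
})

test_that("preprocessing does not manufacture significance on null data", {
  # identical generating profiles everywhere: decisions with and without the
  # filtering/ICA stage must almost always agree
  changed <- 0L; total <- 0L
  for (s in 1:4) {
    cfg <- synth_config(seed = s, noise_scale = 2)
    rec <- generate_session(cfg, six_event_schedule(60))
    analyse <- function(r) {
      scores <- sapply(c("MA1", "MA2", "VA1", "VA2", "VA3", "VA4"),
                       function(ev) as.numeric(
                         segment_scores(periodogram(segment_event(r, ev)),
                                        "raw")), simplify = FALSE)
      run_comparison_plan(scores, mode = "approx")$decision
    }
    plain <- analyse(rec)
    pp <- bandpass_filter(rec)
    dec <- decompose_ica(pp, 16, seed = 1000 + s)
    idx <- identify_artifact_components(dec, pp)
    pp <- remove_components(dec, idx)
    cleaned <- analyse(pp)
    changed <- changed + sum(plain != cleaned)
    total <- total + length(plain)
  }
  expect_lte(changed / total, 0.06)
})
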