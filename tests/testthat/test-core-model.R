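test_that("default schedule lays out both study days contiguously", {
  s1 <- default_schedule(1)
  s2 <- default_schedule(2)
  expect_setequal(s1$name[s1$name %in% c("MA1", "MA2", "VA1", "VA2")],
                  c("MA1", "MA2", "VA1", "VA2"))
  expect_false(any(c("MA1", "MA2") %in% s2$name))
  expect_setequal(s2$name[grepl("^VA", s2$name)], c("VA3", "VA4"))
  trt1 <- s1[s1$name %in% c("MA1", "MA2", "VA1", "VA2"), ]
  expect_true(all(trt1$duration == 300))
  expect_equal(sum(trt1$duration), 4 * 300)
  trt2 <- s2[s2$name %in% c("VA3", "VA4"), ]
  expect_equal(sum(trt2$duration), 2 * 300)
  # contiguous onsets reproduce the 72-minute total recording time
  expect_equal(schedule_duration(s1) + schedule_duration(s2), 4320)
  expect_error(default_schedule(3), "day")
})

test_that("event schedules reject overlap, duplicates and unknown names", {
  expect_error(event_schedule(data.frame(
    name = c("MA1", "MA1"), day = 1, onset = c(0, 400), duration = 300)),
    "at most once")
  expect_error(event_schedule(data.frame(
    name = c("MA1", "MA2"), day = 1, onset = c(0, 100), duration = 300)),
    "overlap")
  expect_error(event_schedule(data.frame(
    name = "MA9", day = 1, onset = 0, duration = 300)), "unknown event")
})

test_that("recording invariants are enforced", {
  m <- matrix(rnorm(32), nrow = 2)
  expect_error(eeg_recording(m, -1), "positive")
  expect_error(eeg_recording(m, 10, c("Fp1", "Fp1")), "unique")
  expect_error(eeg_recording(m, 10, c("Fp1", "Fp2"),
                             data.frame(label = "MA1", onset = 1,
                                        duration = 10)),
               "within")
  rec <- eeg_recording(m, 16, annotations = data.frame(
    label = "MA1", onset = 0, duration = 1))
  expect_s3_class(rec, "eeg_recording")
  expect_identical(rec$channel_labels, c("Fp1", "Fp2"))
  expect_equal(recording_duration(rec), 1)
})

test_that("CSV recordings round-trip exactly, with annotations", {
  set.seed(42)
  rec <- eeg_recording(matrix(rnorm(16 * 1000), nrow = 16), 125,
                       annotations = data.frame(
                         label = c("MA1", "rest"), onset = c(0, 4),
                         duration = c(4, 4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$rate, rec$rate)
  expect_identical(back$data, rec$data)
  expect_equal(back$annotations, rec$annotations)
})

test_that("ragged or headerless CSV input is rejected with a parse error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# rate=125", "Fp1,Fp2", "0.1,0.2", "0.3"), path)
  expect_error(read_recording(path), "ragged|non-numeric")
  writeLines(c("Fp1,Fp2", "0.1,0.2"), path)
  expect_error(read_recording(path), "rate")
})

test_that("EDF recordings round-trip within 16-bit quantization", {
  set.seed(7)
  rec <- eeg_recording(matrix(rnorm(16 * 1000, sd = 30), nrow = 16), 125,
                       annotations = data.frame(label = "MA1", onset = 0,
                                                duration = 8))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$channel_labels, default_montage())
  expect_equal(back$rate, 125)
  for (i in 1:16) {
    step <- diff(range(rec$data[i, ])) / 65535
    expect_lt(max(abs(back$data[i, ] - rec$data[i, ])), step)
  }
  expect_equal(back$annotations, rec$annotations)
  # 2-channel recordings carry 2 signals
  rec2 <- eeg_recording(matrix(sin(1:500), nrow = 2), 125)
  path2 <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec2, path2)
  expect_equal(nrow(read_recording(path2)$data), 2)
})

test_that("corrupt EDF headers are rejected naming the offending field", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(strrep("x", 600)), path)
  expect_error(read_recording(path), "version")
})

test_that("band table partitions 1-50 Hz with the documented edges", {
  tab <- eeg_bands()
  narrow <- tab[tab$name != "raw", ]
  expect_equal(narrow$f_lo[-1], narrow$f_hi[-nrow(narrow)])
  expect_equal(range(narrow$f_lo, narrow$f_hi), c(1, 50))
  expect_error(band_definition("mu"), "unknown band")
  expect_error(band_definition(list(name = "bad", f_lo = 5, f_hi = 3)))
})
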