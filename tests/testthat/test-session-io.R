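test_that("profile and container validation reject out-of-range input", {
  expect_error(subject_profile("s", "man", -1, 1.8, 80), class = "cogscreen_domain_error")
  expect_error(subject_profile("s", "man", 40, 3.1, 80), class = "cogscreen_domain_error")
  expect_error(subject_profile("s", "man", 40, 1.8, 0), class = "cogscreen_domain_error")
  expect_error(touch_trajectory(c(10, 5), 1:2, 1:2), class = "cogscreen_domain_error")
  expect_error(touch_trajectory(numeric(0), numeric(0), numeric(0)),
               class = "cogscreen_domain_error")
  expect_error(graph_layout(data.frame(node_id = c("a", "a"), x_px = 1:2, y_px = 1:2)),
               class = "cogscreen_validation_error")
  expect_error(graph_layout(data.frame(node_id = "a", x_px = 1, y_px = 1),
                            rbind(c("a", "a"))),
               class = "cogscreen_validation_error")
  p <- subject_profile("s", "man", 40, 1.8, 80)
  expect_error(session_record(p, 1, tasks = list(T99 = list())),
               class = "cogscreen_validation_error")
  expect_error(session_record(p, 1, durations = c(T1 = -1)),
               class = "cogscreen_domain_error")
})

test_that("a minimal session round-trips losslessly", {
  p <- subject_profile("subj-1", "woman", 63, 1.66, 59.5, "light", label = 1)
  s <- session_record(p, 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_session(s, f)
  s2 <- read_session(f)
  expect_identical(s2$profile$subject_id, "subj-1")
  expect_identical(s2$profile$label, 1L)
  expect_identical(s2$round_index, 2L)
  expect_length(s2$tasks, 0)
})

test_that("trajectories, layouts and action logs survive serialization exactly", {
  p <- subject_profile("s", "man", 40, 1.8, 80)
  tr <- touch_trajectory(c(0, 16, 31), c(0.5, 100.25, 200.125), c(7, 8.5, 9.0625))
  lay <- graph_layout(data.frame(node_id = c("a", "b"), x_px = c(0, 100),
                                 y_px = c(0, 0), label = c("1", "A")),
                      rbind(c("a", "b")), node_radius_px = 35)
  log <- graph_action_log(list(stroke_action(tr), node_touch_action("b", 50)))
  s <- session_record(p, 1,
                      tasks = list(T4 = list(follow = tr),
                                   T12 = list(log = log, layout = lay)),
                      durations = c(T4 = 12.5, T12 = 30))
  f <- withr::local_tempfile(fileext = ".json")
  write_session(s, f)
  s2 <- read_session(f)
  tr2 <- s2$tasks$T4$follow
  expect_identical(tr2$t_ms, tr$t_ms)
  expect_identical(tr2$x_px, tr$x_px)
  expect_identical(tr2$y_px, tr$y_px)
  lay2 <- s2$tasks$T12$layout
  expect_identical(lay2$nodes$node_id, lay$nodes$node_id)
  expect_identical(lay2$edges, lay$edges)
  log2 <- s2$tasks$T12$log
  expect_identical(log2$actions[[2]]$node_id, "b")
  expect_identical(s2$durations[["T4"]], 12.5)
  # second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".json")
  write_session(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed session JSON produces a field-naming error", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema": "cogscreen-session/1", "profile": {"subject_id": "x"}}', f)
  expect_error(read_session(f), "profile.gender")
  writeLines("{not json", f)
  expect_error(read_session(f), "malformed")
})

test_that("WAV round trips: silence, sine quantization bound, stereo averaging", {
  f <- withr::local_tempfile(fileext = ".wav")
  write_audio(audio_clip(numeric(48000), 48000), f)
  sil <- read_audio(f)
  expect_identical(length(sil), 48000L)
  expect_true(all(sil$samples == 0))
  expect_identical(sil$rate_hz, 48000L)

  t <- seq_len(4800) / 48000
  sine <- audio_clip(0.9 * sin(2 * pi * 440 * t), 48000)
  write_audio(sine, f, bits = 16)
  back <- read_audio(f)
  expect_lt(max(abs(back$samples - sine$samples)), 2^-15)
  write_audio(sine, f, bits = 32)
  expect_equal(read_audio(f)$samples, sine$samples, tolerance = 1e-7)
})

test_that("stereo channels +x and -x average to silence", {
  # hand-build a 2-channel 16-bit file: interleaved L = x, R = -x
  x <- as.integer(round(sin(2 * pi * 100 * seq_len(960) / 48000) * 30000))
  inter <- as.vector(rbind(x, -x))
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(inter) * 2), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 2L), con, 2, endian = "little")
  writeBin(48000L, con, 4, endian = "little")
  writeBin(48000L * 4L, con, 4, endian = "little")
  writeBin(c(4L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(inter) * 2), con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  clip <- read_audio(f)
  expect_identical(length(clip), 960L)
  expect_true(all(abs(clip$samples) < 2^-15))
})

test_that("non-WAV input is rejected", {
  f <- withr::local_tempfile(fileext = ".wav")
  writeLines("definitely not audio", f)
  expect_error(read_audio(f), "unsupported format")
})
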