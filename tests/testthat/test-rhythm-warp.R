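test_that("frame duration ratio follows the sinusoid and its limits", {
  # full depth: trough compresses a frame to 0 ms, peak doubles it
  m1 <- modulator(depth = 1, cycles = 1, phase = 0)
  expect_identical(frame_duration_ratio(m1, 0.75) * 50, 0)
  expect_identical(frame_duration_ratio(m1, 0.25) * 50, 100)
  # zero depth is the identity for any position and phase
  m0 <- modulator(depth = 0, cycles = 2, phase = pi / 4)
  expect_equal(frame_duration_ratio(m0, c(0, 0.3, 0.99)), rep(1, 3))
  # 75% depth at the peak stretches a 50-ms frame to 87.5 ms
  m75 <- modulator(depth = 0.75, cycles = 1, phase = 0)
  expect_equal(frame_duration_ratio(m75, 0.25) * 50, 87.5)
  expect_error(frame_duration_ratio(m75, 1), "t_norm")
  expect_error(frame_duration_ratio(m75, -0.01), "t_norm")
})

test_that("modulator constructor validates its invariants", {
  expect_error(modulator(1.2, 1), "depth")
  expect_error(modulator(0.5, 0), "cycles")
  expect_error(modulator(0.5, 1.5), "cycles")
  expect_equal(modulator(0.5, 1, 2 * pi + 0.3)$phase, 0.3)
  expect_length(modulator_phases(), 8)
  expect_equal(diff(modulator_phases()), rep(pi / 4, 7))
})

test_that("zero-depth schedule is exact identity", {
  sch <- build_frame_schedule(1000, modulator(0, 1, 0), 50)
  expect_equal(sch$n_frames, 20L)
  expect_equal(sch$new_durations_ms, rep(50, 20))
  expect_equal(sch$remainder_ms, 0)
})

test_that("warped schedules conserve total duration on the full parameter grid", {
  for (depth in c(0, 0.25, 0.5, 0.75, 1))
    for (cyc in 1:3)
      for (ph in modulator_phases()) {
        sch <- build_frame_schedule(1000, modulator(depth, cyc, ph), 50)
        expect_lt(abs(sum(sch$new_durations_ms) - 1000), 1e-9)
        expect_true(all(sch$new_durations_ms >= 0))
      }
})

test_that("schedule matches the independent direct-evaluation oracle", {
  sch <- build_frame_schedule(1000, modulator(0.75, 3, pi / 4), 50)
  expect_equal(sch$new_durations_ms, oracle_schedule(1000, 50, 0.75, 3, pi / 4))
  set.seed(11)
  for (i in 1:100) {
    depth <- runif(1)
    cyc <- sample(1:3, 1)
    ph <- runif(1, 0, 2 * pi)
    region <- runif(1, 300, 2000)
    frame <- runif(1, 20, 80)
    sch <- build_frame_schedule(region, modulator(depth, cyc, ph), frame)
    expect_equal(sch$new_durations_ms, oracle_schedule(region, frame, depth, cyc, ph),
                 tolerance = 1e-12)
  }
})

test_that("pre-correction durations stay within the modulator bounds", {
  set.seed(3)
  for (i in 1:25) {
    depth <- runif(1)
    mod <- modulator(depth, sample(1:3, 1), runif(1, 0, 2 * pi))
    n <- 20
    raw <- 50 * frame_duration_ratio(mod, (seq_len(n) - 0.5) / n)
    expect_true(all(raw >= 50 * (1 - depth) - 1e-12))
    expect_true(all(raw <= 50 * (1 + depth) + 1e-12))
  }
})

test_that("sub-frame remainders pass through and short regions error", {
  sch <- build_frame_schedule(1030, modulator(0.75, 1, 0), 50)
  expect_equal(sch$n_frames, 20L)
  expect_equal(sch$remainder_ms, 30)
  expect_lt(abs(sum(sch$new_durations_ms) - 1000), 1e-9)
  expect_error(build_frame_schedule(40, modulator(0.75, 1, 0), 50), "shorter")
})

test_that("warping with an identity schedule is sample-exact passthrough", {
  set.seed(5)
  x <- rnorm(9000)
  sch <- identity_schedule(1000, 50)
  expect_identical(warp_waveform(x, 8000, sch), x)
})

test_that("warped audio conserves duration to within one sample", {
  sr <- 8000
  t <- seq_len(sr) / sr
  x <- sin(2 * pi * 440 * t)
  for (ph in c(0, pi / 4, 5 * pi / 4)) {
    sch <- build_frame_schedule(1000, modulator(0.75, 1, ph), 50)
    y <- warp_waveform(x, sr, sch)
    expect_lte(abs(length(y) - length(x)), 1)
  }
})

test_that("constant frames stay constant under any stretch", {
  x <- rep(0.25, 1600)  # 100 ms at 16 kHz
  sch <- build_frame_schedule(100, modulator(1, 1, pi / 2), 50)
  y <- warp_waveform(x, 16000, sch)
  expect_true(all(abs(y - 0.25) < 1e-12))
})

test_that("warp_waveform rejects bad input", {
  sch <- identity_schedule(1000, 50)
  expect_error(warp_waveform(numeric(0), 8000, sch), "empty")
  expect_error(warp_waveform(rnorm(100), 0, sch), "sample_rate")
  expect_error(warp_waveform(rnorm(100), 8000, sch), "shorter")
})

test_that("WAV files round-trip in both encodings", {
  set.seed(8)
  x <- runif(4000, -0.9, 0.9)
  for (fmt in c("pcm16", "float32")) {
    path <- withr::local_tempfile(fileext = ".wav")
    write_wav(x, path, 16000, fmt)
    got <- read_wav(path)
    expect_equal(got$sample_rate, 16000)
    tol <- if (fmt == "pcm16") 1 / 32767 else 1e-7
    expect_equal(got$samples, x, tolerance = tol)
  }
})

test_that("label tracks parse the tab-separated dialect", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.000000\t1.200000\tearly", "1.200000\t2.861000\tgap",
               "2.861000\t3.211000\tnow"), path)
  lab <- read_labels(path)
  expect_equal(lab$label, c("early", "gap", "now"))
  expect_equal(lab$end_s - lab$start_s, c(1.2, 1.661, 0.35))
})
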