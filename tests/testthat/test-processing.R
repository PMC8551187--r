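fs <- 1000
t20 <- seq(0, 20 - 1 / fs, by = 1 / fs)
interior <- (5 * fs):(15 * fs)

test_that("bandpass passes the SCG band and rejects out-of-band content", {
  y <- bandpass(sin(2 * pi * 20 * t20), 10, 30, fs = fs)
  expect_lt(abs(max(abs(y[interior])) - 1), 0.05)

  y1 <- bandpass(sin(2 * pi * 1 * t20), 10, 30, fs = fs)
  expect_lt(max(abs(y1[interior])), 0.1)

  yc <- bandpass(rep(2.5, length(t20)), 10, 30, fs = fs)
  expect_lt(max(abs(yc[interior])), 1e-6)

  expect_error(bandpass(t20, 30, 10, fs = fs), "band edges")
  expect_error(bandpass(t20, 10, 600, fs = fs), "band edges")
})

test_that("bandpass is zero-phase: symmetric pulses stay symmetric", {
  tt <- seq(-5, 5, by = 1 / fs)
  pulse <- exp(-tt^2 / (2 * 0.05^2))
  y <- bandpass(pulse, 10, 30, fs = fs)
  expect_lt(max(abs(y - rev(y))), 1e-9)
})

test_that("bandpass preserves channel wrappers", {
  ch <- waveform_channel("FBG1", sin(2 * pi * 20 * t20), fs, "nm")
  out <- bandpass(ch, 10, 30)
  expect_s3_class(out, "waveform_channel")
  expect_identical(out$name, "FBG1")
  expect_length(out$samples, length(ch$samples))
})

test_that("hilbert_envelope recovers closed-form amplitude envelopes", {
  expect_equal(hilbert_envelope(numeric(100)), numeric(100))

  env <- hilbert_envelope(sin(2 * pi * 20 * t20))
  expect_lt(max(abs(env[interior] - 1)), 0.02)

  # AM: carrier 20 Hz, modulator 1 + 0.5 sin(2 pi t)
  mod <- 1 + 0.5 * sin(2 * pi * 1 * t20)
  env_am <- hilbert_envelope(mod * sin(2 * pi * 20 * t20))
  expect_lt(max(abs(env_am[interior] - mod[interior])) / max(mod), 0.05)
})

test_that("envelope dominates band-limited signals pointwise", {
  set.seed(201)
  for (i in 1:5) {
    x <- bandpass(rnorm(length(t20)), 10, 30, fs = fs)
    env <- hilbert_envelope(x)
    tol <- 0.05 * max(abs(x[interior]))
    expect_true(all(env[interior] >= abs(x[interior]) - tol))
  }
})

test_that("dominant_frequency finds the strongest in-band component", {
  t15 <- seq(0, 15 - 1 / fs, by = 1 / fs)
  f <- dominant_frequency(sin(2 * pi * 1.2 * t15), fs)
  expect_lt(abs(as.numeric(f) - 1.2), 0.25 + 1e-9)  # one 4-s-segment bin

  mix <- sin(2 * pi * 1 * t15) + 0.2 * sin(2 * pi * 2.5 * t15)
  expect_equal(as.numeric(dominant_frequency(mix, fs)), 1)

  set.seed(202)
  fn <- dominant_frequency(rnorm(length(t15)), fs)
  expect_true(is.finite(as.numeric(fn)))
  expect_true(is.logical(attr(fn, "low_confidence")))

  expect_error(dominant_frequency(numeric(10) + 5, fs = 10, f_min = 0.5,
                                  f_max = 3), "flat|bins")
})

test_that("octave-error correction picks the beat fundamental of a pulse train", {
  t15 <- seq(0, 15 - 1 / fs, by = 1 / fs)
  spikes <- numeric(length(t15))
  spikes[seq(1, length(t15), by = fs)] <- 1  # 1 Hz impulse train
  raw <- as.numeric(dominant_frequency(spikes, fs, f_min = 0.5, f_max = 2))
  fixed <- as.numeric(dominant_frequency(spikes, fs, f_min = 0.5, f_max = 2,
                                         prefer_fundamental = TRUE))
  expect_gt(raw, 1)        # argmax lands on a harmonic
  expect_equal(fixed, 1)   # corrected to the fundamental
})

test_that("detect_peaks implements the normalized adaptive detector", {
  t15 <- seq(0, 15 - 1 / fs, by = 1 / fs)
  env <- 0.5 - 0.5 * cos(2 * pi * 1.2 * t15)  # rectified periodic envelope
  pk <- detect_peaks(env, fs, f_dom = 1.2)
  expect_length(pk$peak_indices, 18)  # floor(15 * 1.2)
  expect_equal(pk$min_distance_samples, round(0.7 * fs / 1.2))

  # scale invariance of min-max normalization
  pk2 <- detect_peaks(5.7 * env, fs, f_dom = 1.2)
  expect_identical(pk2$peak_indices, pk$peak_indices)

  # spacing contract
  expect_true(all(diff(pk$peak_indices) >= pk$min_distance_samples))

  expect_error(detect_peaks(rep(1, 1000), fs, f_dom = 1), "constant")
})

test_that("two equal maxima closer than the refractory window collapse to one", {
  x <- numeric(2000)
  x[500] <- 1
  x[800] <- 1  # 0.3 s later
  pk <- detect_peaks(x, fs, f_dom = 1)  # min distance 700 samples
  expect_identical(pk$peak_indices, 500L)  # earlier tie survives
})

test_that("detector matches the brute-force reference on random signals", {
  set.seed(203)
  for (i in 1:200) {
    n <- sample(150:500, 1)
    sfs <- sample(c(50, 100, 250), 1)
    x <- as.numeric(bandpass(rnorm(n), 0.5, 0.45 * sfs, fs = sfs, order = 2)) +
      0.2 * sin(2 * pi * runif(1, 0.5, 3) * (1:n) / sfs)
    fd <- runif(1, 0.5, 3)
    got <- detect_peaks(x, sfs, f_dom = fd)
    expect_identical(got$peak_indices, as.integer(brute_force_peaks(x, sfs, fd)))
  }
})

test_that("scg_envelope peaks once per beat on clean bursts", {
  cfg <- quiet_config(duration = 15, hr_bpm = 72)
  ev <- generate_event_train(cfg)
  strain <- synthesize_scg_strain(ev, cfg)
  env <- scg_envelope(strain, fs = cfg$fs)
  pk <- detect_peaks(env, cfg$fs, f_range = c(0.5, 2))
  expect_equal(length(pk$peak_indices), length(ev$ao_times))
})
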