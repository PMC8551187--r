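mk_ch <- function(x, nm = "FBG1", fs = 1000) waveform_channel(nm, x, fs, "nm")

test_that("fuse_channels sums exactly four aligned channels", {
  x <- sin(2 * pi * 20 * seq(0, 2, by = 1e-3))
  chans <- lapply(paste0("FBG", 1:4), function(nm) mk_ch(x, nm))
  fused <- fuse_channels(chans)
  expect_identical(fused$name, "FBGsum")
  expect_equal(fused$samples, 4 * x, tolerance = 1e-15)

  expect_error(fuse_channels(chans[1:3]), "exactly 4")
  bad <- chans; bad[[4]] <- mk_ch(x, "FBG4", fs = 500)
  expect_error(fuse_channels(bad), "share")
})

test_that("fusion commutes with linear zero-phase filtering", {
  set.seed(301)
  fs <- 1000
  chans <- lapply(paste0("FBG", 1:4), function(nm) mk_ch(rnorm(4000), nm, fs))
  sum_then_filter <- bandpass(fuse_channels(chans), 10, 30)$samples
  filter_then_sum <- Reduce(`+`, lapply(chans, function(c)
    bandpass(c, 10, 30)$samples))
  expect_lt(max(abs(sum_then_filter - filter_then_sum)), 1e-9)
})

test_that("mean_hr_from_peaks averages instantaneous beat-to-beat rates", {
  mk_peaks <- function(times, fs = 1000) {
    idx <- as.integer(round(times * fs)) + 1L
    structure(list(channel = "FBG1", peak_indices = idx,
                   peak_times = (idx - 1) / fs, fs = fs, f_dom = 1,
                   min_distance_samples = 700, threshold = 0.5),
              class = "peak_set")
  }
  expect_equal(mean_hr_from_peaks(mk_peaks(seq(0.5, 14.5, 1)))$mean_hr, 60)
  expect_equal(mean_hr_from_peaks(mk_peaks(seq(0.25, 14.5, 0.75)))$mean_hr, 80)
  # intervals 1.0 and 0.8 s: mean of 60 and 75 bpm
  expect_equal(mean_hr_from_peaks(mk_peaks(c(1, 2, 2.8)))$mean_hr, 67.5)
  # window filtering and the insufficient-beats contract
  est <- mean_hr_from_peaks(mk_peaks(c(1, 2, 3, 20, 21)), window = c(0, 15))
  expect_equal(est$n_peaks, 3)
  expect_error(mean_hr_from_peaks(mk_peaks(c(1, 20)), window = c(0, 15)),
               "fewer than 2")
})

test_that("ECG reference recovers simulated rates", {
  cfg <- quiet_config(duration = 16, hr_bpm = 60, ecg_noise_sd = 0.005)
  ev <- generate_event_train(cfg)
  ecg <- synthesize_ecg(ev, cfg)
  est <- hr_reference_from_ecg(ecg, fs = cfg$fs)
  expect_equal(est$mean_hr, 60, tolerance = 0.01)

  cfg72 <- quiet_config(duration = 16, hr_bpm = 72, ecg_noise_sd = 0.005,
                        seed = 8)
  ecg72 <- synthesize_ecg(generate_event_train(cfg72), cfg72)
  expect_lt(abs(hr_reference_from_ecg(ecg72, fs = cfg72$fs)$mean_hr - 72), 0.5)

  expect_error(hr_reference_from_ecg(ecg, fs = cfg$fs, window = c(18, 19)),
               "fewer than 2")
})

test_that("mae is the mean absolute discrepancy", {
  expect_equal(mae(c(60, 70), c(60, 70)), 0)
  expect_equal(mae(c(62, 58), c(60, 60)), 2)
  expect_equal(mae(61.5, 60), 1.5)
  expect_equal(mae(c(62, 58), c(60, 60)), mae(c(58, 62), c(60, 60)))
  expect_error(mae(1:3, 1:2), "equal length")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("comparative_report reproduces hand-computed cell MAEs", {
  # full 7-subject x 3-test design: 21 values per (position, channel) cell
  grid <- expand.grid(subject = paste0("S", 1:7), test = paste0("T", 1:3),
                      position = paste0("Position", 1:3),
                      channel = c(paste0("FBG", 1:4), "FBGsum"),
                      stringsAsFactors = FALSE)
  grid$hr_ref_bpm <- 70
  # per-position error patterns: +-1 in Position1, +-2 in Position2, 0 in 3
  err <- ifelse(grid$position == "Position1", 1,
                ifelse(grid$position == "Position2", 2, 0))
  sign <- rep_len(c(1, -1), nrow(grid))
  grid$hr_bpm <- grid$hr_ref_bpm + sign * err
  rep <- comparative_report(grid)
  expect_true(all(rep$by_cell$n == 21))
  expect_equal(rep$by_cell$mae_bpm[rep$by_cell$position == "Position1"],
               rep(1, 5))
  expect_equal(rep$by_cell$mae_bpm[rep$by_cell$position == "Position2"],
               rep(2, 5))
  expect_equal(rep$by_cell$mae_bpm[rep$by_cell$position == "Position3"],
               rep(0, 5))
  expect_true(all(rep$best_position_per_channel$best_position == "Position3"))

  # all-perfect estimates give all-zero MAE
  grid$hr_bpm <- grid$hr_ref_bpm
  expect_true(all(comparative_report(grid)$by_cell$mae_bpm == 0))

  expect_error(comparative_report(grid[0, ]), "no complete")
  expect_error(comparative_report(data.frame(x = 1)), "columns")
})

test_that("HR estimates are invariant to positive channel scaling (fusion identity)", {
  cfg <- quiet_config(duration = 16, hr_bpm = 66, seed = 12)
  ev <- generate_event_train(cfg)
  strain <- synthesize_scg_strain(ev, cfg)
  base <- hr_from_scg(strain, fs = cfg$fs)
  scaled_sum <- hr_from_scg((0.044 + 0.045 + 0.045 + 0.046) * strain,
                            fs = cfg$fs)
  expect_identical(scaled_sum$mean_hr, base$mean_hr)
  expect_identical(scaled_sum$beat_intervals, base$beat_intervals)
})

test_that("estimate_hr handles failed channels gracefully", {
  rec <- simulate_recording(config = quiet_config(seed = 2, duration = 16))
  # dead channel: an all-zero trace has a constant envelope and cannot be
  # normalized for peak detection
  rec$channels$FBG2$samples[] <- 0
  est <- estimate_hr(rec)
  expect_true(is.na(est$hr_bpm[est$channel == "FBG2"]))
  expect_false(anyNA(est$hr_bpm[est$channel %in% c("FBG1", "ECG")]))
})

test_that("simulate_study yields the full factorial with references", {
  df <- simulate_study(n_subjects = 2, n_tests = 1,
                       positions = c("Position1", "Position3"),
                       config = quiet_config(duration = 16), seed = 5)
  expect_equal(nrow(df), 2 * 1 * 2 * 5)
  expect_true(all(c("hr_bpm", "hr_ref_bpm", "hr_true_bpm") %in% names(df)))
  expect_true(all(abs(df$hr_ref_bpm - df$hr_true_bpm) < 1))
})
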