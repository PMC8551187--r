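# Channel fusion, windowed HR estimation, MAE evaluation, comparative
# position and single- vs multi-sensor analyses

#' Sum four FBG channels into the multi-sensor signal
#'
#' Sample-wise sum of the four raw wavelength-shift channels (`FBGsum`).
#' Summing happens before filtering; because every later stage up to the
#' envelope is linear and zero-phase, this commutes with post-filter
#' summation.
#'
#' @param channels List of exactly 4 [waveform_channel()]s with equal `fs`
#'   and length.
#' @return A [waveform_channel()] named `"FBGsum"`.
#' @export
fuse_channels <- function(channels) {
  if (!is.list(channels) || length(channels) != 4L ||
      !all(vapply(channels, inherits, logical(1), "waveform_channel")))
    stopf("`channels` must be a list of exactly 4 waveform_channel objects")
  fss <- vapply(channels, `[[`, numeric(1), "fs")
  lens <- vapply(channels, function(c) length(c$samples), integer(1))
  if (length(unique(fss)) != 1L || length(unique(lens)) != 1L)
    stopf("channels must share sampling rate and length")
  waveform_channel("FBGsum",
                   Reduce(`+`, lapply(channels, `[[`, "samples")),
                   fss[1L], units = channels[[1L]]$units)
}

#' Windowed mean heart rate from detected peaks
#'
#' Beat-to-beat intervals are the successive differences of the peak times
#' falling inside the window; each interval gives an instantaneous rate
#' `60 / IBI` and the estimate is their arithmetic mean (mean of rates, not
#' beats divided by duration).
#'
#' @param peaks A `peak_set` from [detect_peaks()].
#' @param window `c(t_start, t_end)` in seconds (default the first 15 s).
#' @return An object of class `hr_estimate` with `mean_hr` (bpm),
#'   `beat_intervals` (s), `n_peaks`, `window`, `channel`.
#' @export
mean_hr_from_peaks <- function(peaks, window = c(0, 15)) {
  stopifnot(inherits(peaks, "peak_set"))
  tms <- peaks$peak_times
  tms <- tms[tms >= window[1L] & tms <= window[2L]]
  if (length(tms) < 2L)
    stopf("fewer than 2 peaks inside [%g, %g] s", window[1L], window[2L])
  ibi <- diff(tms)
  structure(
    list(channel = peaks$channel, window = window,
         beat_intervals = ibi, mean_hr = mean(60 / ibi),
         n_peaks = length(tms)),
    class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("<hr_estimate> %s: %.2f bpm from %d peaks in [%g, %g] s\n",
              if (nzchar(x$channel)) x$channel else "(unnamed)",
              x$mean_hr, x$n_peaks, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Reference heart rate from the ECG channel
#'
#' Band-passes the ECG 0.5-100 Hz, detects R peaks with the same adaptive
#' detector used for SCG envelopes, and averages the beat-to-beat rates over
#' the window. The dominant-frequency prior is searched in the cardiac
#' fundamental band (`f_range`, default 0.5-2 Hz) with octave-error
#' correction (see [dominant_frequency()]): an R-wave train spreads power
#' evenly across beat-rate harmonics, and the refractory window must track
#' the heart rate itself, not a QRS harmonic.
#'
#' @param ecg A [waveform_channel()] or numeric vector.
#' @param fs Sampling rate, Hz (taken from the channel when omitted).
#' @param window Analysis window, s.
#' @param band ECG band-pass edges, Hz.
#' @param f_range Dominant-frequency search band, Hz.
#' @return An `hr_estimate` for channel `"ECG"`.
#' @export
hr_reference_from_ecg <- function(ecg, fs = NULL, window = c(0, 15),
                                  band = c(0.5, 100), f_range = c(0.5, 2)) {
  fs <- need_fs(ecg, fs)
  filt <- bandpass(ecg, band[1L], band[2L], fs = fs)
  f_dom <- dominant_frequency(filt, fs = fs, f_min = f_range[1L],
                              f_max = f_range[2L], prefer_fundamental = TRUE)
  pk <- detect_peaks(filt, fs = fs, f_dom = f_dom, channel = "ECG")
  mean_hr_from_peaks(pk, window = window)
}

#' Heart rate from one SCG channel
#'
#' Full single-channel chain: [scg_envelope()], adaptive [detect_peaks()]
#' (AO peaks), then [mean_hr_from_peaks()].
#'
#' @inheritParams hr_reference_from_ecg
#' @param x A [waveform_channel()] or numeric vector (raw wavelength shift).
#' @return An `hr_estimate`.
#' @export
hr_from_scg <- function(x, fs = NULL, window = c(0, 15), f_range = c(0.5, 2)) {
  fs <- need_fs(x, fs)
  env <- scg_envelope(x, fs = fs)
  pk <- detect_peaks(env, fs = fs, f_range = f_range,
                     channel = if (inherits(x, "waveform_channel")) x$name else "")
  mean_hr_from_peaks(pk, window = window)
}

#' Estimate HR on every channel of a recording
#'
#' Synchronizes at the trigger edge (when a TRIGGER channel is present),
#' then runs the SCG chain on each FBG channel and on their sum, and the
#' R-peak chain on the ECG. Channels whose detection fails (e.g. fewer than
#' two usable peaks) yield `NA` rather than an error.
#'
#' @param rec An [recording()].
#' @param window Analysis window after synchronization, s.
#' @param sync Synchronize at the trigger first (default `TRUE` when a
#'   TRIGGER channel is present).
#' @param f_range Dominant-frequency search band, Hz.
#' @return A data frame with one row per channel (`FBG1..FBG4`, `FBGsum`,
#'   `ECG`): `channel`, `hr_bpm`, `n_peaks`, plus the recording's `subject`,
#'   `position`, `test` metadata when available, and `hr_true_bpm` from the
#'   embedded ground truth (`NA` otherwise).
#' @export
#' @examples
#' rec <- simulate_recording(config = sim_config(seed = 3, noise_sd = 0))
#' estimate_hr(rec)
estimate_hr <- function(rec, window = c(0, 15), sync = TRUE,
                        f_range = c(0.5, 2)) {
  stopifnot(inherits(rec, "scg_recording"))
  if (sync && !is.null(rec$channels[["TRIGGER"]])) rec <- synchronize(rec)
  fbg_names <- grep("^FBG[0-9]+$", names(rec$channels), value = TRUE)
  chans <- rec$channels[fbg_names]
  if (length(chans) == 4L) chans$FBGsum <- fuse_channels(unname(chans))
  one <- function(f) tryCatch(f, error = function(e) NULL)
  rows <- lapply(names(chans), function(nm) {
    est <- one(hr_from_scg(chans[[nm]], window = window, f_range = f_range))
    data.frame(channel = nm,
               hr_bpm = if (is.null(est)) NA_real_ else est$mean_hr,
               n_peaks = if (is.null(est)) NA_integer_ else est$n_peaks)
  })
  if (!is.null(rec$channels[["ECG"]])) {
    est <- one(hr_reference_from_ecg(rec$channels[["ECG"]], window = window,
                                     f_range = f_range))
    rows <- c(rows, list(data.frame(
      channel = "ECG",
      hr_bpm = if (is.null(est)) NA_real_ else est$mean_hr,
      n_peaks = if (is.null(est)) NA_integer_ else est$n_peaks)))
  }
  out <- do.call(rbind, rows)
  for (k in c("subject", "position", "test"))
    out[[k]] <- if (!is.null(rec$meta[[k]])) as.character(rec$meta[[k]]) else NA_character_
  out$hr_true_bpm <- if (!is.null(rec$truth)) true_mean_hr(rec$truth) else NA_real_
  out
}

#' Mean absolute error between HR estimates and references
#'
#' @param estimates Numeric vector, bpm.
#' @param references Numeric vector of equal length, bpm.
#' @return MAE in bpm.
#' @export
mae <- function(estimates, references) {
  if (length(estimates) == 0L) stopf("empty input")
  if (length(estimates) != length(references))
    stopf("`estimates` and `references` must have equal length")
  mean(abs(estimates - references))
}

#' Simulate the full study grid
#'
#' Subjects x tests x positions factorial of simulated recordings run
#' through the full pipeline. Each subject draws a mean heart rate uniformly
#' from the 60-80.4 bpm (1-1.34 Hz) cardiac band; each recording gets its
#' own deterministic sub-seed.
#'
#' @param n_subjects,n_tests Grid size (defaults 7 and 3).
#' @param positions Character vector of position labels.
#' @param config Base [sim_config()]; `position`, `channel_gains`, `hr_bpm`
#'   and `seed` are overridden per cell.
#' @param array An [array_spec()].
#' @param seed Master seed for subject rates and per-recording sub-seeds.
#' @return Tidy data frame: `subject`, `test`, `position`, `channel`,
#'   `hr_bpm`, `hr_ref_bpm`, `hr_true_bpm`.
#' @export
simulate_study <- function(n_subjects = 7, n_tests = 3,
                           positions = c("Position1", "Position2", "Position3"),
                           config = sim_config(), array = default_array(),
                           seed = 20210) {
  hr_subjects <- local_seed(seed, stats::runif(n_subjects, 60, 80.4))
  rows <- list()
  idx <- 0L
  for (s in seq_len(n_subjects)) for (p in seq_along(positions)) for (tt in seq_len(n_tests)) {
    idx <- idx + 1L
    cfg <- config
    cfg$hr_bpm <- hr_subjects[s]
    cfg$position <- positions[p]
    cfg$channel_gains <- position_gains(positions[p])
    cfg$seed <- as.integer((seed + 7L * idx) %% .Machine$integer.max)
    rec <- simulate_recording(array, cfg,
                              meta = list(subject = sprintf("S%d", s),
                                          test = sprintf("T%d", tt)))
    est <- estimate_hr(rec)
    ref <- est$hr_bpm[est$channel == "ECG"]
    est <- est[est$channel != "ECG", ]
    est$hr_ref_bpm <- ref
    rows[[idx]] <- est
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject", "test", "position", "channel",
          "hr_bpm", "hr_ref_bpm", "hr_true_bpm")]
}

#' Per-position, per-channel MAE report
#'
#' Groups HR estimates by (position, channel), computes the MAE against the
#' ECG reference in each cell and per channel across positions, and flags
#' the best channel per position and the best position per channel. Rows
#' with a missing estimate or reference are dropped; `n` reports the values
#' actually used per cell.
#'
#' @param estimates Data frame with columns `position`, `channel`, `hr_bpm`,
#'   `hr_ref_bpm` (e.g. from [simulate_study()]).
#' @return An object of class `mae_report`: `by_cell` (position, channel,
#'   n, mae_bpm), `by_channel` (channel, n, mae_bpm across positions),
#'   `best_channel_per_position`, `best_position_per_channel`.
#' @export
comparative_report <- function(estimates) {
  need <- c("position", "channel", "hr_bpm", "hr_ref_bpm")
  if (!is.data.frame(estimates) || !all(need %in% names(estimates)))
    stopf("`estimates` must be a data frame with columns %s",
          paste(need, collapse = ", "))
  ok <- stats::complete.cases(estimates[, c("hr_bpm", "hr_ref_bpm")])
  estimates <- estimates[ok, ]
  if (nrow(estimates) == 0L) stopf("no complete estimate/reference pairs")
  err <- abs(estimates$hr_bpm - estimates$hr_ref_bpm)
  by_cell <- stats::aggregate(err,
                              by = list(position = estimates$position,
                                        channel = estimates$channel),
                              FUN = mean)
  names(by_cell)[3L] <- "mae_bpm"
  by_cell$n <- stats::aggregate(err,
                                by = list(estimates$position, estimates$channel),
                                FUN = length)$x
  by_cell <- by_cell[order(by_cell$position, by_cell$channel),
                     c("position", "channel", "n", "mae_bpm")]
  rownames(by_cell) <- NULL
  by_channel <- stats::aggregate(err, by = list(channel = estimates$channel),
                                 FUN = mean)
  names(by_channel)[2L] <- "mae_bpm"
  by_channel$n <- as.vector(table(estimates$channel)[by_channel$channel])
  by_channel <- by_channel[, c("channel", "n", "mae_bpm")]
  best_ch <- do.call(rbind, lapply(split(by_cell, by_cell$position), function(d)
    data.frame(position = d$position[1L],
               best_channel = d$channel[which.min(d$mae_bpm)],
               mae_bpm = min(d$mae_bpm))))
  best_pos <- do.call(rbind, lapply(split(by_cell, by_cell$channel), function(d)
    data.frame(channel = d$channel[1L],
               best_position = d$position[which.min(d$mae_bpm)],
               mae_bpm = min(d$mae_bpm))))
  rownames(best_ch) <- rownames(best_pos) <- NULL
  structure(list(by_cell = by_cell, by_channel = by_channel,
                 best_channel_per_position = best_ch,
                 best_position_per_channel = best_pos),
            class = "mae_report")
}

#' @export
print.mae_report <- function(x, ...) {
  cat("<mae_report>\n  MAE by (position, channel):\n")
  print(x$by_cell, row.names = FALSE)
  cat("  Across positions:\n")
  print(x$by_channel, row.names = FALSE)
  cat("  Best channel per position:\n")
  print(x$best_channel_per_position, row.names = FALSE)
  invisible(x)
}

channel_mae_over_recordings <- function(config, array, n_recordings, seed) {
  errs <- NULL
  for (j in seq_len(n_recordings)) {
    cfg <- config
    cfg$seed <- as.integer((seed + j) %% .Machine$integer.max)
    est <- estimate_hr(simulate_recording(array, cfg))
    ref <- est$hr_bpm[est$channel == "ECG"]
    e <- est[est$channel != "ECG", ]
    errs <- rbind(errs, abs(e$hr_bpm - ref))
    colnames(errs) <- e$channel
  }
  colMeans(errs)
}

#' Single- vs multi-sensor fusion experiment
#'
#' Seeded replications of the single- versus multi-sensor comparison under
#' weak coupling (default: the `Position2` gain preset, where individual
#' channels err regularly). Each replication simulates
#' `n_recordings` independent recordings, computes each channel's MAE
#' against the ECG reference across them, and compares the fused channel's
#' MAE with the best individual channel's MAE.
#'
#' @param n_seeds Number of replications.
#' @param n_recordings Recordings per replication.
#' @param config Base [sim_config()] (default: `Position2` preset).
#' @param array An [array_spec()].
#' @param seed Master seed.
#' @return Data frame per replication: `seed`, `mae_fbgsum_bpm`,
#'   `mae_best_single_bpm`, `fusion_wins` (logical,
#'   `mae_fbgsum <= min_i mae_FBGi`).
#' @export
fusion_benefit_experiment <- function(n_seeds = 100, n_recordings = 5,
                                      config = sim_config(position = "Position2"),
                                      array = default_array(), seed = 1L) {
  rows <- lapply(seq_len(n_seeds), function(k) {
    m <- channel_mae_over_recordings(config, array, n_recordings,
                                     seed = seed + 1000L * k)
    single <- m[c("FBG1", "FBG2", "FBG3", "FBG4")]
    data.frame(seed = k, mae_fbgsum_bpm = unname(m["FBGsum"]),
               mae_best_single_bpm = min(single),
               fusion_wins = unname(m["FBGsum"] <= min(single)))
  })
  do.call(rbind, rows)
}

#' Position-ordering experiment
#'
#' Seeded replications of the position analysis: for each replication and
#' each position preset, `n_recordings` recordings are simulated and the
#' per-position MAE is the mean over the five channels (four FBGs and their
#' sum) of the per-channel MAE. Returns the per-position MAEs and whether
#' the strict ordering Position1 < Position3 < Position2 held.
#'
#' @inheritParams fusion_benefit_experiment
#' @param n_recordings Recordings per position per replication.
#' @return Data frame per replication: `seed`, `mae_position1_bpm`,
#'   `mae_position2_bpm`, `mae_position3_bpm`, `ordered` (logical).
#' @export
position_ordering_experiment <- function(n_seeds = 50, n_recordings = 2,
                                         config = sim_config(),
                                         array = default_array(), seed = 1L) {
  positions <- c("Position1", "Position2", "Position3")
  rows <- lapply(seq_len(n_seeds), function(k) {
    m <- vapply(seq_along(positions), function(p) {
      cfg <- config
      cfg$position <- positions[p]
      cfg$channel_gains <- position_gains(positions[p])
      mean(channel_mae_over_recordings(cfg, array, n_recordings,
                                       seed = seed + 1000L * k + 100L * p))
    }, numeric(1))
    data.frame(seed = k,
               mae_position1_bpm = m[1L], mae_position2_bpm = m[2L],
               mae_position3_bpm = m[3L],
               ordered = m[1L] < m[3L] && m[3L] < m[2L])
  })
  do.call(rbind, rows)
}
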