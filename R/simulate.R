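# Synthetic supine-apnea recording generator with known ground truth

#' Per-position relative coupling gains
#'
#' Documented presets for how strongly chest-wall displacement couples into
#' each grating when the patch is worn in the three standard placements:
#' `Position1` (horizontal over the left sternum, strongest coupling,
#' strongest on FBG1-FBG2), `Position2` (vertical xiphoid-to-umbilicus,
#' weakest overall) and `Position3` (horizontal periumbilical,
#' intermediate).
#'
#' @param position `"Position1"`, `"Position2"` or `"Position3"`.
#' @return Numeric vector of 4 relative gains.
#' @export
position_gains <- function(position) {
  presets <- list(
    Position1 = c(1.00, 0.90, 0.60, 0.50),
    Position2 = c(0.35, 0.30, 0.30, 0.25),
    Position3 = c(0.70, 0.60, 0.50, 0.45))
  g <- presets[[position]]
  if (is.null(g)) stopf("no coupling-gain preset for position '%s'", position)
  g
}

#' Simulation configuration
#'
#' Parameters of the synthetic supine-apnea recording generator. Defaults
#' emulate the study conditions of a ~20 s breath-hold: cardiac rate inside
#' the 1-1.34 Hz band, aortic-opening (AO) locked vibration bursts with
#' energy centered at 20 Hz (inside the 10-30 Hz SCG analysis band), chest
#' displacement mid-range of 0.2-0.5 mm, and picometre-scale interrogator
#' noise.
#'
#' @param duration Recording length, s.
#' @param fs Sampling rate, Hz.
#' @param hr_bpm Mean heart rate, bpm.
#' @param hrv_sd Standard deviation of inter-beat jitter, s.
#' @param r_offset Time of the first R peak, s.
#' @param emd_delay R-to-AO electromechanical (pre-ejection) delay, s.
#' @param burst_freq Vibration-burst center frequency, Hz.
#' @param burst_tau Burst exponential decay constant, s.
#' @param displacement_amp Peak chest displacement per beat, mm.
#' @param disp_to_strain Displacement-to-strain coupling, m\eqn{\epsilon}/mm.
#' @param position Body position label selecting a [position_gains()] preset
#'   when `channel_gains` is `NULL`.
#' @param channel_gains Optional explicit 4-vector of relative channel gains.
#' @param noise_sd Per-channel additive wavelength noise, nm.
#' @param ecg_noise_sd Additive ECG noise, a.u. (unit R amplitude).
#' @param ecg_r_width Width of the triangular R-wave template, s.
#' @param baseline_drift_amp Amplitude of a slow sinusoidal baseline drift,
#'   nm (0 disables).
#' @param baseline_drift_freq Drift frequency, Hz.
#' @param trigger_time Time of the trigger rising edge, s.
#' @param seed Integer RNG seed; identical configs give bit-identical
#'   recordings.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 20, fs = 1000, hr_bpm = 72, hrv_sd = 0.02,
                       r_offset = 0.5, emd_delay = 0.10,
                       burst_freq = 20, burst_tau = 0.05,
                       displacement_amp = 0.35, disp_to_strain = 1,
                       position = "Position1", channel_gains = NULL,
                       noise_sd = 0.01, ecg_noise_sd = 0.01,
                       ecg_r_width = 0.02,
                       baseline_drift_amp = 0, baseline_drift_freq = 0.05,
                       trigger_time = 0.2, seed = 1L) {
  if (!is_number(duration) || duration <= 0) stopf("`duration` must be > 0")
  if (!is_number(fs) || fs <= 0) stopf("`fs` must be > 0")
  if (!is_number(hr_bpm) || hr_bpm <= 0) stopf("`hr_bpm` must be > 0")
  if (!is_number(hrv_sd) || hrv_sd < 0) stopf("`hrv_sd` must be >= 0")
  if (!is_number(trigger_time) || trigger_time < 0 || trigger_time >= duration)
    stopf("`trigger_time` must satisfy 0 <= trigger_time < duration")
  if (!is_number(displacement_amp) || displacement_amp < 0)
    stopf("`displacement_amp` must be >= 0")
  if (is.null(channel_gains)) channel_gains <- position_gains(position)
  if (!is.numeric(channel_gains) || length(channel_gains) != 4L)
    stopf("`channel_gains` must have exactly 4 entries")
  structure(
    list(duration = duration, fs = fs, hr_bpm = hr_bpm, hrv_sd = hrv_sd,
         r_offset = r_offset, emd_delay = emd_delay,
         burst_freq = burst_freq, burst_tau = burst_tau,
         displacement_amp = displacement_amp, disp_to_strain = disp_to_strain,
         position = position, channel_gains = channel_gains,
         noise_sd = noise_sd, ecg_noise_sd = ecg_noise_sd,
         ecg_r_width = ecg_r_width,
         baseline_drift_amp = baseline_drift_amp,
         baseline_drift_freq = baseline_drift_freq,
         trigger_time = trigger_time, seed = as.integer(seed)),
    class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys map one-to-one onto [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stopf("unknown sim_config keys in %s: %s", path, paste(unknown, collapse = ", "))
  do.call(sim_config, y)
}

#' Ground-truth cardiac event train
#'
#' @param r_times Strictly increasing ECG R-peak times, s.
#' @param ao_times Matching aortic-valve-opening times, s (one per R peak,
#'   each `emd_delay` after its R peak).
#' @param emd_delay The R-to-AO delay, s.
#' @return An object of class `cardiac_event_train`.
#' @export
cardiac_event_train <- function(r_times, ao_times, emd_delay) {
  if (length(r_times) != length(ao_times))
    stopf("`r_times` and `ao_times` must have equal length")
  if (length(r_times) > 1L && (any(diff(r_times) <= 0) || any(diff(ao_times) <= 0)))
    stopf("event times must be strictly increasing")
  if (length(r_times) &&
      any(abs(ao_times - r_times - emd_delay) > 1e-9))
    stopf("ao_times must equal r_times + emd_delay")
  structure(list(r_times = as.numeric(r_times), ao_times = as.numeric(ao_times),
                 emd_delay = emd_delay),
            class = "cardiac_event_train")
}

#' Mean heart rate of an event train
#'
#' Arithmetic mean of the instantaneous beat-to-beat rates `60 / IBI`.
#'
#' @param events A [cardiac_event_train()].
#' @return Mean HR in bpm (`NA` with fewer than 2 beats).
#' @export
true_mean_hr <- function(events) {
  stopifnot(inherits(events, "cardiac_event_train"))
  if (length(events$r_times) < 2L) return(NA_real_)
  mean(60 / diff(events$r_times))
}

#' Generate a ground-truth cardiac event train
#'
#' R-peak times start at `r_offset` and advance by `60 / hr_bpm` plus
#' zero-mean Gaussian jitter (sd `hrv_sd`, redrawn if an interval would be
#' non-positive). AO events follow each R peak by `emd_delay`. Beats whose
#' AO would fall beyond `duration` are not generated.
#'
#' @param config A [sim_config()].
#' @param use_seed Seed the RNG from `config$seed` (default). Internal
#'   callers that manage the RNG themselves pass `FALSE`.
#' @return A [cardiac_event_train()].
#' @export
generate_event_train <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (use_seed) return(local_seed(config$seed, generate_event_train(config, FALSE)))
  if (config$r_offset + config$emd_delay > config$duration)
    stopf("no beat fits: r_offset + emd_delay exceeds duration")
  mean_ibi <- 60 / config$hr_bpm
  r <- config$r_offset
  repeat {
    ibi <- mean_ibi + stats::rnorm(1L, 0, config$hrv_sd)
    tries <- 0L
    while (ibi <= 0 && tries < 1000L) {
      ibi <- mean_ibi + stats::rnorm(1L, 0, config$hrv_sd)
      tries <- tries + 1L
    }
    if (ibi <= 0) stopf("could not draw a positive inter-beat interval")
    nxt <- r[length(r)] + ibi
    if (nxt + config$emd_delay > config$duration) break
    r <- c(r, nxt)
  }
  cardiac_event_train(r, r + config$emd_delay, emd_delay = config$emd_delay)
}

#' Synthesize the chest-strain signal from AO events
#'
#' Each aortic valve opening launches an exponentially decaying vibration
#' burst \eqn{A e^{-(t - t_{AO})/\tau} \cos(2\pi f_b (t - t_{AO}))} for
#' \eqn{t \ge t_{AO}}, zero elsewhere; bursts from successive beats
#' superpose. The cosine phase makes `A = displacement_amp * disp_to_strain`
#' the true peak amplitude, attained at burst onset.
#'
#' @param events A [cardiac_event_train()].
#' @param config A [sim_config()].
#' @return Strain signal in m\eqn{\epsilon}, sampled at `config$fs`.
#' @export
synthesize_scg_strain <- function(events, config) {
  stopifnot(inherits(events, "cardiac_event_train"), inherits(config, "sim_config"))
  if (config$burst_freq >= config$fs / 2)
    stopf("burst_freq %g Hz would alias at fs %g Hz", config$burst_freq, config$fs)
  n <- round(config$duration * config$fs)
  s <- numeric(n)
  amp <- config$displacement_amp * config$disp_to_strain
  # truncate each burst once its envelope has decayed to ~3e-4 of the peak
  burst_len <- min(n, ceiling(8 * config$burst_tau * config$fs))
  for (ao in events$ao_times) {
    i0 <- ceiling(ao * config$fs) + 1L  # first sample with t >= ao
    if (i0 > n) next
    i1 <- min(n, i0 + burst_len - 1L)
    tt <- (seq.int(i0, i1) - 1L) / config$fs - ao
    s[i0:i1] <- s[i0:i1] +
      amp * exp(-tt / config$burst_tau) * cos(2 * pi * config$burst_freq * tt)
  }
  s
}

#' Synthesize a reference ECG
#'
#' Unit-amplitude triangular R-wave templates (width `ecg_r_width`) centered
#' at the ground-truth R times over low-amplitude Gaussian noise. A
#' commercial single-lead reference sensor is emulated: the QRS complex
#' dominates all other waves, which are not modelled.
#'
#' @inheritParams generate_event_train
#' @param events A [cardiac_event_train()].
#' @return ECG signal (a.u.) sampled at `config$fs`.
#' @export
synthesize_ecg <- function(events, config, use_seed = TRUE) {
  stopifnot(inherits(events, "cardiac_event_train"), inherits(config, "sim_config"))
  if (use_seed) return(local_seed(config$seed, synthesize_ecg(events, config, FALSE)))
  n <- round(config$duration * config$fs)
  t <- (seq_len(n) - 1L) / config$fs
  x <- stats::rnorm(n, 0, config$ecg_noise_sd)
  half <- config$ecg_r_width / 2
  for (r in events$r_times) {
    k <- which(t >= r - half & t <= r + half)
    if (length(k)) x[k] <- x[k] + pmax(0, 1 - abs(t[k] - r) / half)
  }
  x
}

#' Simulate a full multichannel recording
#'
#' Produces the four FBG wavelength-shift channels (shared strain signal
#' scaled by per-channel coupling gains and each grating's strain
#' sensitivity, plus independent Gaussian noise and optional slow drift), the
#' reference ECG, and a binary trigger stepping from 0 to 1 at
#' `trigger_time`. The ground-truth event train is embedded. Identical
#' configurations (including `seed`) yield bit-identical recordings.
#'
#' @param array An [array_spec()] (default [default_array()]).
#' @param config A [sim_config()].
#' @param meta Extra metadata merged into the recording (e.g. `subject`,
#'   `test`); `position` is always taken from `config`.
#' @return An [recording()].
#' @export
#' @examples
#' rec <- simulate_recording(config = sim_config(duration = 5, seed = 7))
#' rec
simulate_recording <- function(array = default_array(), config = sim_config(),
                               meta = list()) {
  stopifnot(inherits(array, "array_spec"), inherits(config, "sim_config"))
  local_seed(config$seed, {
    events <- generate_event_train(config, use_seed = FALSE)
    strain <- synthesize_scg_strain(events, config)
    n <- length(strain)
    t <- (seq_len(n) - 1L) / config$fs
    drift <- if (config$baseline_drift_amp > 0)
      config$baseline_drift_amp * sin(2 * pi * config$baseline_drift_freq * t)
    else 0
    channels <- list()
    for (i in seq_len(4L)) {
      spec <- array$gratings[[i]]
      shift <- strain_to_shift(spec, config$channel_gains[i] * strain) +
        stats::rnorm(n, 0, config$noise_sd) + drift
      channels[[spec$label]] <- waveform_channel(spec$label, shift,
                                                 config$fs, units = "nm")
    }
    channels$ECG <- waveform_channel("ECG",
                                     synthesize_ecg(events, config, use_seed = FALSE),
                                     config$fs, units = "a.u.")
    channels$TRIGGER <- waveform_channel("TRIGGER",
                                         as.numeric(t >= config$trigger_time),
                                         config$fs, units = "binary")
    meta$position <- config$position
    recording(channels, meta = meta, truth = events)
  })
}
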