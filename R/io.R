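# Multichannel recording container, CSV dialect, trigger synchronization

#' A uniformly sampled waveform channel
#'
#' @param name Channel name (e.g. `"FBG1"`, `"ECG"`, `"TRIGGER"`).
#' @param samples Numeric sample vector (non-empty).
#' @param fs Sampling rate in Hz (> 0).
#' @param units One of `"nm"`, `"a.u."`, `"binary"`.
#' @return An object of class `waveform_channel`.
#' @export
waveform_channel <- function(name, samples, fs, units = "a.u.") {
  if (!is.character(name) || length(name) != 1L)
    stopf("`name` must be a single string")
  if (!is.numeric(samples) || length(samples) == 0L)
    stopf("`samples` must be a non-empty numeric vector")
  if (!is_number(fs) || fs <= 0) stopf("`fs` must be a positive number (Hz)")
  units <- match.arg(units, c("nm", "a.u.", "binary"))
  structure(list(name = name, samples = as.numeric(samples),
                 fs = fs, units = units),
            class = "waveform_channel")
}

#' @export
print.waveform_channel <- function(x, ...) {
  cat(sprintf("<waveform_channel> %s: %d samples @ %g Hz (%s)\n",
              x$name, length(x$samples), x$fs, x$units))
  invisible(x)
}

channel_times <- function(ch) (seq_along(ch$samples) - 1L) / ch$fs

#' A multichannel SCG recording
#'
#' Bundles simultaneously acquired channels (four FBG wavelength-shift
#' traces, a reference ECG, and a binary synchronization trigger) with
#' session metadata and, for simulated data, the ground-truth cardiac event
#' train.
#'
#' @param channels Named list of [waveform_channel()]s sharing `fs` and
#'   length.
#' @param meta List of metadata: typically `subject`, `position`
#'   (`"Position1"`..`"Position3"`), `test` (`"T1"`..`"T3"`).
#' @param truth Optional `cardiac_event_train` ground truth.
#' @return An object of class `scg_recording`.
#' @export
recording <- function(channels, meta = list(), truth = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      !all(vapply(channels, inherits, logical(1), "waveform_channel")))
    stopf("`channels` must be a non-empty list of waveform_channel objects")
  if (is.null(names(channels)) || any(names(channels) == ""))
    names(channels) <- vapply(channels, `[[`, character(1), "name")
  fss <- vapply(channels, `[[`, numeric(1), "fs")
  lens <- vapply(channels, function(c) length(c$samples), integer(1))
  if (length(unique(fss)) != 1L) stopf("all channels must share the sampling rate")
  if (length(unique(lens)) != 1L) stopf("all channels must share the sample count")
  if (!is.null(truth) && !inherits(truth, "cardiac_event_train"))
    stopf("`truth` must be NULL or a cardiac_event_train")
  structure(list(channels = channels, meta = meta, truth = truth),
            class = "scg_recording")
}

#' @export
print.scg_recording <- function(x, ...) {
  ch1 <- x$channels[[1L]]
  cat(sprintf("<scg_recording> %d channels (%s), %.3g s @ %g Hz\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              length(ch1$samples) / ch1$fs, ch1$fs))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  if (!is.null(x$truth))
    cat(sprintf("  truth: %d beats\n", length(x$truth$r_times)))
  invisible(x)
}

recording_fs <- function(rec) rec$channels[[1L]]$fs
recording_len <- function(rec) length(rec$channels[[1L]]$samples)

#' Write a recording to the package CSV dialect
#'
#' Plain-text format: `#`-prefixed header lines carrying the sampling rate,
#' metadata, channel units and (if present) the ground-truth event times;
#' then one CSV column per channel, one row per sample. Samples are printed
#' at full double precision (`%.17g`), so a write/read round trip is
#' lossless.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "scg_recording"))
  hdr <- c("# scghr_recording v1",
           sprintf("# fs: %.17g", recording_fs(rec)))
  for (k in names(rec$meta))
    hdr <- c(hdr, sprintf("# %s: %s", k, format(rec$meta[[k]])))
  hdr <- c(hdr, sprintf("# units: %s",
                        paste(names(rec$channels),
                              vapply(rec$channels, `[[`, character(1), "units"),
                              sep = "=", collapse = ",")))
  if (!is.null(rec$truth)) {
    hdr <- c(hdr,
             sprintf("# truth_r_times: %s",
                     paste(sprintf("%.17g", rec$truth$r_times), collapse = " ")),
             sprintf("# truth_ao_times: %s",
                     paste(sprintf("%.17g", rec$truth$ao_times), collapse = " ")),
             sprintf("# truth_emd_delay: %.17g", rec$truth$emd_delay))
  }
  mat <- vapply(rec$channels, function(ch) sprintf("%.17g", ch$samples),
                character(recording_len(rec)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(rec$channels), collapse = ","), con)
  writeLines(do.call(paste, c(asplit(mat, 2L), list(sep = ","))), con)
  invisible(path)
}

#' Read a recording from the package CSV dialect
#'
#' Inverse of [write_recording()]. The `fs` header is mandatory; channels not
#' listed in the `units` header are preserved with units `"a.u."`.
#'
#' @param path File path.
#' @return An [recording()].
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1L] - 1L else length(lines)
  hdr <- lines[seq_len(n_hdr)]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) kv[[trimws(m[2L])]] <- trimws(m[3L])
  }
  if (is.null(kv$fs)) stopf("recording file lacks the mandatory `# fs:` header")
  fs <- as.numeric(kv$fs)
  if (!is_number(fs) || fs <= 0) stopf("invalid fs header: %s", kv$fs)
  body <- lines[-seq_len(n_hdr)]
  if (length(body) < 2L) stopf("recording file has no data rows")
  df <- utils::read.csv(text = body, header = TRUE, check.names = FALSE,
                        colClasses = "numeric")
  units <- list()
  if (!is.null(kv$units)) {
    for (u in strsplit(kv$units, ",")[[1L]]) {
      p <- strsplit(u, "=", fixed = TRUE)[[1L]]
      if (length(p) == 2L) units[[p[1L]]] <- p[2L]
    }
  }
  channels <- lapply(names(df), function(nm)
    waveform_channel(nm, df[[nm]], fs,
                     units = if (!is.null(units[[nm]])) units[[nm]] else "a.u."))
  names(channels) <- names(df)
  truth <- NULL
  if (!is.null(kv$truth_r_times)) {
    r <- as.numeric(strsplit(kv$truth_r_times, "\\s+")[[1L]])
    ao <- as.numeric(strsplit(kv$truth_ao_times, "\\s+")[[1L]])
    truth <- cardiac_event_train(r, ao,
                                 emd_delay = as.numeric(kv$truth_emd_delay))
  }
  meta_keys <- setdiff(names(kv), c("fs", "units", "truth_r_times",
                                    "truth_ao_times", "truth_emd_delay"))
  recording(channels, meta = kv[meta_keys], truth = truth)
}

trigger_edge_index <- function(x) {
  # binary trigger contract: rising edge = first sample > 0.5 after one <= 0.5
  if (x[1L] > 0.5) return(1L)
  idx <- which(x[-1L] > 0.5 & x[-length(x)] <= 0.5)
  if (length(idx) == 0L) return(NA_integer_)
  idx[1L] + 1L
}

#' Synchronize a recording at its trigger edge
#'
#' Crops every channel so that the first rising edge (0 to 1 transition) of
#' the TRIGGER channel becomes t = 0, mirroring the push-button
#' synchronization of the optical and ECG acquisition chains at the start of
#' the apnea stage. Ground-truth event times, when present, are shifted
#' accordingly (beats before the trigger are dropped). Idempotent.
#'
#' @param rec An [recording()] containing a `TRIGGER` channel.
#' @return The cropped recording.
#' @export
synchronize <- function(rec) {
  stopifnot(inherits(rec, "scg_recording"))
  trig <- rec$channels[["TRIGGER"]]
  if (is.null(trig)) stopf("cannot synchronize: no TRIGGER channel")
  edge <- trigger_edge_index(trig$samples)
  if (is.na(edge)) stopf("cannot synchronize: TRIGGER has no rising edge")
  if (edge == 1L) return(rec)
  fs <- recording_fs(rec)
  channels <- lapply(rec$channels, function(ch) {
    waveform_channel(ch$name, ch$samples[edge:length(ch$samples)], ch$fs, ch$units)
  })
  truth <- rec$truth
  if (!is.null(truth)) {
    t0 <- (edge - 1L) / fs
    keep <- truth$r_times - t0 >= 0
    truth <- if (any(keep))
      cardiac_event_train(truth$r_times[keep] - t0, truth$ao_times[keep] - t0,
                          emd_delay = truth$emd_delay)
    else NULL
  }
  recording(channels, meta = rec$meta, truth = truth)
}
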