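#' Notch-filter line noise and harmonics
#'
#' Zero-phase Butterworth band-stop filtering of every channel at the power
#' line frequency and its harmonics (default stopbands 57-63, 117-123 and
#' 177-183 Hz). Stopbands above the Nyquist frequency are an error.
#'
#' @param raw A [raw_recording()].
#' @param stopbands List of `c(lo, hi)` stopbands in Hz.
#' @param order Butterworth prototype order per stopband.
#' @return The filtered [raw_recording()].
#' @export
notch_filter <- function(raw,
                         stopbands = list(c(57, 63), c(117, 123), c(177, 183)),
                         order = 2) {
  stopifnot(inherits(raw, "raw_recording"))
  nyq <- raw$fs / 2
  hi <- max(vapply(stopbands, max, 0))
  if (raw$fs <= 2 * hi) {
    stop(sprintf("stopband edge %g Hz at or above Nyquist (%g Hz)", hi, nyq))
  }
  sig <- raw$signal
  for (sb in stopbands) {
    flt <- signal::butter(order, sb / nyq, type = "stop")
    for (ch in seq_len(nrow(sig))) {
      sig[ch, ] <- signal::filtfilt(flt, sig[ch, ])
    }
  }
  out <- raw
  out$signal <- sig
  out
}

#' Resample a recording
#'
#' Anti-aliased downsampling to `fs_target`: each channel is low-pass
#' filtered (zero-phase Butterworth at 90% of the target Nyquist) and
#' linearly interpolated onto the new sample grid. Upsampling requests are an
#' error; `fs_target == fs` is the identity.
#'
#' @param raw A [raw_recording()].
#' @param fs_target Target sampling rate in Hz (default 1000).
#' @return The resampled [raw_recording()]; duration preserved within one
#'   sample.
#' @export
resample_recording <- function(raw, fs_target = 1000) {
  stopifnot(inherits(raw, "raw_recording"))
  if (fs_target > raw$fs) stop("upsampling is not supported")
  if (fs_target == raw$fs) return(raw)
  n <- ncol(raw$signal)
  t_old <- (seq_len(n) - 1L) / raw$fs
  n_new <- round(n * fs_target / raw$fs)
  t_new <- (seq_len(n_new) - 1L) / fs_target
  lp <- signal::butter(8, 0.9 * (fs_target / 2) / (raw$fs / 2), type = "low")
  sig <- matrix(0, nrow(raw$signal), n_new,
                dimnames = list(rownames(raw$signal), NULL))
  for (ch in seq_len(nrow(raw$signal))) {
    filt <- signal::filtfilt(lp, raw$signal[ch, ])
    sig[ch, ] <- approx(t_old, filt, xout = t_new, rule = 2)$y
  }
  out <- raw
  out$signal <- sig
  out$fs <- fs_target
  out
}

#' Automatic channel quality assessment
#'
#' A channel is rejected if its variance exceeds `var_factor` times (or is
#' below 1/`var_factor` of) the mean variance across channels, or if its
#' jump count (samples where the absolute first difference exceeds
#' `jump_uv` microvolts) exceeds `jump_factor` times the mean jump count.
#'
#' @param raw A [raw_recording()] (at least two channels).
#' @param var_factor Variance ratio threshold (default 5).
#' @param jump_uv Jump amplitude threshold in microvolts (default 100).
#' @param jump_factor Jump count ratio threshold (default 3).
#' @return A `qc_report` data frame: per channel `channel`, `variance`,
#'   `n_jumps`, `rejected`, `reason` (`variance_high`, `variance_low`,
#'   `spiky`, or `""`).
#' @export
detect_bad_channels <- function(raw, var_factor = 5, jump_uv = 100,
                                jump_factor = 3) {
  stopifnot(inherits(raw, "raw_recording"))
  if (nrow(raw$signal) < 2L) {
    stop("channel QC needs at least two channels as a reference population")
  }
  v <- apply(raw$signal, 1, var)
  jumps <- apply(raw$signal, 1, function(x) sum(abs(diff(x)) > jump_uv))
  v_mean <- mean(v)
  j_mean <- mean(jumps)
  reason <- rep("", length(v))
  reason[v > var_factor * v_mean] <- "variance_high"
  reason[v < v_mean / var_factor] <- "variance_low"
  reason[reason == "" & j_mean > 0 & jumps > jump_factor * j_mean] <- "spiky"
  structure(
    data.frame(channel = rownames(raw$signal), variance = v, n_jumps = jumps,
               rejected = reason != "", reason = reason,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("qc_report", "data.frame")
  )
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over the retained ("good") channels
#' from every channel. Bad channels never influence the average but are
#' still re-referenced themselves.
#'
#' @param raw A [raw_recording()].
#' @param good Logical vector (or channel-name vector) of retained channels;
#'   default all.
#' @return The re-referenced [raw_recording()].
#' @export
rereference_common_average <- function(raw, good = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  n_ch <- nrow(raw$signal)
  if (is.null(good)) good <- rep(TRUE, n_ch)
  if (is.character(good)) good <- rownames(raw$signal) %in% good
  if (sum(good) < 2L) stop("common-average reference needs >= 2 good channels")
  avg <- colMeans(raw$signal[good, , drop = FALSE])
  out <- raw
  out$signal <- sweep(raw$signal, 2, avg)
  out$reference <- "common_average"
  out
}

#' Epoch a recording and baseline-correct
#'
#' Extracts, for each event, the `window` (ms, half-open `[start, end)` at
#' sample resolution, time 0 = stimulus onset) and subtracts the per-trial,
#' per-channel mean over the `baseline` window. Events whose window falls
#' outside the recording are dropped (recorded in the `dropped` attribute).
#'
#' @param raw A [raw_recording()].
#' @param design A [make_task_design()] event table (onsets in seconds).
#' @param window Epoch window in ms, default `c(-200, 700)`.
#' @param baseline Baseline window in ms, default `c(-200, 0)`.
#' @return An [ecog_epochs()].
#' @export
epoch_and_baseline <- function(raw, design, window = c(-200, 700),
                               baseline = c(-200, 0)) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$fs
  step_ms <- 1000 / fs
  times <- seq(window[1], window[2] - step_ms, by = step_ms)
  n_t <- length(times)
  n_ch <- nrow(raw$signal)
  onset_samp <- round(design$onset * fs) + 1L
  first <- onset_samp + round(window[1] / step_ms)
  keep <- first >= 1L & (first + n_t - 1L) <= ncol(raw$signal)
  dropped <- which(!keep)
  arr <- array(0, c(sum(keep), n_ch, n_t))
  bl <- window_idx_halfopen(times, baseline)
  ki <- 0L
  for (i in which(keep)) {
    ki <- ki + 1L
    seg <- raw$signal[, first[i]:(first[i] + n_t - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg[, bl, drop = FALSE])
    arr[ki, , ] <- seg
  }
  ep <- ecog_epochs(arr, times = times, fs = fs,
                    categories = design$trial_type[keep],
                    sites = rownames(raw$signal))
  attr(ep, "dropped") <- dropped
  ep
}

#' Flag artifact epochs by amplitude
#'
#' A trial is flagged if any sample of any retained channel exceeds
#' `threshold_uv` microvolts in absolute value (on the baseline-corrected
#' signal). Flagged trials are excluded by downstream stages.
#'
#' @param epochs An [ecog_epochs()].
#' @param threshold_uv Spike amplitude threshold (> 0), default 100.
#' @param channels Optional subset of channels (names or indices) to scan.
#' @return The epochs with the `artifact` flag updated.
#' @export
reject_artifact_epochs <- function(epochs, threshold_uv = 100, channels = NULL) {
  stopifnot(inherits(epochs, "ecog_epochs"))
  if (threshold_uv <= 0) stop("threshold must be positive")
  ch <- seq_len(dim(epochs$data)[2])
  if (!is.null(channels)) {
    ch <- if (is.character(channels)) match(channels, epochs$sites) else channels
  }
  mx <- apply(abs(epochs$data[, ch, , drop = FALSE]), 1, max)
  epochs$artifact <- epochs$artifact | (mx > threshold_uv)
  epochs
}

#' Full preprocessing chain
#'
#' Applies the stages in their canonical order: downsample, notch filter,
#' channel quality control, common-average re-reference (good channels
#' only), epoch + baseline correction, artifact rejection, band power
#' extraction. Bad channels are dropped from the epoched output.
#'
#' @param raw A [raw_recording()].
#' @param design Event table.
#' @param fs_target Target sampling rate (Hz).
#' @param band Band limits in Hz for [band_power()].
#' @param freq_step Wavelet frequency step in Hz.
#' @param window,baseline_epoch Epoch and baseline-correction windows (ms).
#' @param artifact_uv Artifact amplitude threshold (microvolts).
#' @param ... Further arguments passed to [band_power()].
#' @return A [bp_epochs()]; the QC report is attached as attribute `qc`.
#' @export
preprocess_recording <- function(raw, design, fs_target = 1000,
                                 band = c(70, 177), freq_step = 1,
                                 window = c(-200, 700),
                                 baseline_epoch = c(-200, 0),
                                 artifact_uv = 100, ...) {
  raw <- resample_recording(raw, fs_target)
  raw <- notch_filter(raw)
  qc <- detect_bad_channels(raw)
  good <- !qc$rejected
  raw <- rereference_common_average(raw, good)
  raw$signal <- raw$signal[good, , drop = FALSE]
  if (!is.null(raw$layout)) raw$layout <- raw$layout[good, , drop = FALSE]
  ep <- epoch_and_baseline(raw, design, window = window,
                           baseline = baseline_epoch)
  ep <- reject_artifact_epochs(ep, artifact_uv)
  bp <- band_power(ep, band = band, freq_step = freq_step, ...)
  bp$layout <- raw$layout
  attr(bp, "qc") <- qc
  bp
}
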