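#' Simulate a raw multichannel ECoG recording with planted effects
#'
#' Generates a raw-like recording for a task design: each channel carries
#' 1/f-like background noise (an autoregressive process with spectral
#' exponent near -2), a continuous high-gamma "floor" (band-limited noise in
#' 70-170 Hz) and an optional 60 Hz line-noise component. Sites named in
#' `effects` respond to their preferred categories with amplitude-modulated
#' high-gamma bursts: the floor is multiplied, from `latency_ms` after each
#' preferred-category onset, by a trapezoidal envelope whose plateau gain
#' corresponds to the planted dB amplitude.
#'
#' @param design A [make_task_design()] event table.
#' @param layout An [electrode_layout()]; one channel per site.
#' @param effects List of [planted_effect()]s; all site labels must exist in
#'   the layout.
#' @param fs Sampling rate in Hz.
#' @param noise List with elements `pink_sd` (microvolt SD of the 1/f
#'   background), `ar` (AR(1) coefficient), `hg_sd` (SD of the high-gamma
#'   floor) and `line_amp` (amplitude of the 60 Hz component, 0 disables).
#' @param pad_s Seconds of recording appended after the last event.
#' @param seed Integer seed; the recording is a pure function of
#'   (arguments, seed).
#' @return A [raw_recording()].
#' @export
simulate_raw <- function(design, layout, effects = list(), fs = 1000,
                         noise = list(), pad_s = 2, seed = 1) {
  noise <- modifyList(list(pink_sd = 8, ar = 0.97, hg_sd = 1.5, line_amp = 0),
                      noise)
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  eff_sites <- vapply(effects, `[[`, "", "site")
  unknown <- setdiff(eff_sites, layout$name)
  if (length(unknown)) {
    stop("planted effect site(s) not in layout: ", paste(unknown, collapse = ", "))
  }
  n_ch <- nrow(layout)
  n_samp <- ceiling((max(design$onset + design$duration) + pad_s) * fs)

  bp <- signal::butter(4, c(70, 170) / (fs / 2), type = "pass")
  sig <- with_seed(seed, {
    out <- matrix(0, n_ch, n_samp)
    t_axis <- (seq_len(n_samp) - 1L) / fs
    for (ch in seq_len(n_ch)) {
      pink <- as.numeric(stats::filter(rnorm(n_samp), noise$ar, method = "recursive"))
      pink <- pink / sd(pink) * noise$pink_sd
      hg <- signal::filtfilt(bp, rnorm(n_samp))
      hg <- hg / sd(hg) * noise$hg_sd
      gain <- rep(1, n_samp)
      idx <- which(eff_sites == layout$name[ch])
      for (k in idx) {
        e <- effects[[k]]
        gmax <- 10^(e$amplitude_db / 20)
        ons <- design$onset[design$trial_type %in% e$categories]
        for (o in ons) {
          env <- response_envelope(n_samp, fs, o + e$latency_ms / 1000,
                                   e$duration_ms / 1000, e$rise_ms / 1000)
          gain <- pmax(gain, 1 + (gmax - 1) * env)
        }
      }
      line <- if (noise$line_amp > 0) {
        noise$line_amp * sin(2 * pi * 60 * t_axis + runif(1, 0, 2 * pi))
      } else 0
      out[ch, ] <- pink + hg * gain + line
    }
    out
  })
  raw_recording(sig, fs = fs, layout = layout, reference = "none")
}

# trapezoidal 0..1 envelope starting at `onset_s`, rising over `rise_s`,
# sustained for `dur_s`, falling over `rise_s`; returned at sample resolution
response_envelope <- function(n_samp, fs, onset_s, dur_s, rise_s) {
  t <- (seq_len(n_samp) - 1L) / fs - onset_s
  up <- pmin(pmax(t / rise_s, 0), 1)
  down <- pmin(pmax((dur_s + rise_s - t) / rise_s, 0), 1)
  pmin(up, down)
}

#' Simulate band-power epochs directly
#'
#' A fast generator that emulates the output of the preprocessing stage:
#' trials x sites x time arrays of baseline-rescaled high-frequency broadband
#' power in dB. Background is temporally smoothed Gaussian noise of SD
#' `noise_sd_db`; sites named in `effects` additionally carry a trapezoidal
#' dB response to their preferred categories. Used to drive selectivity,
#' decoding and latency analyses at desk scale; the full raw-signal path is
#' exercised by [simulate_raw()] plus the preprocessing stage.
#'
#' @inheritParams simulate_raw
#' @param times Time axis in ms relative to onset.
#' @param noise_sd_db SD of the background noise in dB after smoothing.
#' @param smooth_ms Width (FWHM, ms) of the Gaussian smoothing applied to
#'   produce the smoothed `power` component.
#' @return A [bp_epochs()] whose trials follow `design` (response blocks
#'   included, carrying no planted response).
#' @export
simulate_band_power <- function(design, layout, effects = list(),
                                times = -200:699, fs = 1000,
                                noise_sd_db = 1, smooth_ms = 50, seed = 1) {
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  eff_sites <- vapply(effects, `[[`, "", "site")
  unknown <- setdiff(eff_sites, layout$name)
  if (length(unknown)) {
    stop("planted effect site(s) not in layout: ", paste(unknown, collapse = ", "))
  }
  n_tr <- nrow(design)
  n_site <- nrow(layout)
  n_t <- length(times)
  sd_noise <- max(noise_sd_db, 1e-12)

  raw <- with_seed(seed, {
    arr <- array(0, c(n_tr, n_site, n_t))
    ker_sd <- 20 / 2.355 * fs / 1000  # 20 ms FWHM pre-smoothing of the noise
    for (s in seq_len(n_site)) {
      nz <- matrix(rnorm(n_tr * n_t), n_t, n_tr)
      nz <- gauss_smooth_mat(nz, ker_sd)
      nz <- nz / mean(apply(nz, 2, sd)) * sd_noise
      arr[, s, ] <- t(nz)
    }
    arr
  })
  for (k in seq_along(effects)) {
    e <- effects[[k]]
    s <- match(e$site, layout$name)
    tr <- which(design$trial_type %in% e$categories)
    t_rel <- times - e$latency_ms
    up <- pmin(pmax(t_rel / e$rise_ms, 0), 1)
    down <- pmin(pmax((e$duration_ms + e$rise_ms - t_rel) / e$rise_ms, 0), 1)
    shape <- e$amplitude_db * pmin(up, down)
    raw[tr, s, ] <- sweep(raw[tr, s, , drop = FALSE], 3, shape, `+`)
  }
  smoothed <- raw
  sd_samp <- smooth_ms / 2.355 * fs / 1000
  if (sd_samp > 0) {
    for (s in seq_len(n_site)) {
      m <- matrix(raw[, s, ], n_tr, n_t)
      smoothed[, s, ] <- t(gauss_smooth_mat(t(m), sd_samp))
    }
  }
  bp_epochs(smoothed, raw, times = times, fs = fs,
            categories = design$trial_type, sites = layout$name,
            band = "HFB", layout = layout)
}

#' Terminal amplitude of the injected ramp
#'
#' The injected signal's effective amplitude for condition-A trials is
#' `x_a + snr_in * sd_b`, where `sd_b` is the standard deviation over time of
#' the trial-averaged condition-B trace. This is the calibration used by the
#' semi-simulation that validates onset detection.
#'
#' @param x_a Pre-injection amplitude of condition-A trials.
#' @param snr_in Target signal-to-noise ratio (dimensionless).
#' @param sd_b `sd` over time of the mean condition-B trace.
#' @return Effective amplitude (same units as `x_a`).
#' @export
ramp_effective_amplitude <- function(x_a, snr_in, sd_b) {
  x_a + snr_in * sd_b
}

#' Inject a calibrated ramp into condition-A trials
#'
#' Adds, within `window`, a ramp to every condition-A trial. The ramp rises
#' linearly from zero with slope `slope` (in units of the terminal amplitude
#' per window length) and plateaus at the terminal amplitude
#' `snr_in * sd(colMeans(b))` until the end of the window; condition-B trials
#' are untouched. With `snr_in = 0` the trials are returned unchanged.
#'
#' @param a Trials x time matrix of condition-A trials.
#' @param b Trials x time matrix of condition-B (reference) trials sharing
#'   the same time axis.
#' @param times Time axis in ms.
#' @param snr_in Target signal-to-noise ratio.
#' @param slope Ramp slope, terminal-amplitude units per window length.
#' @param window Ramp window in ms, default \[0, 500\].
#' @return Modified `a`, with attributes `sd_b` (the scaling SD) and
#'   `terminal_amplitude` (the injected increment's plateau value).
#' @export
inject_ramp <- function(a, b, times, snr_in, slope = 3, window = c(0, 500)) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(b) == 0L) stop("empty reference (condition-B) trial set")
  if (ncol(a) != length(times) || ncol(b) != length(times)) {
    stop("trial sets must share the time axis")
  }
  if (window[1] < min(times) || window[2] > max(times) + 1) {
    stop("ramp window must lie inside the epoch")
  }
  sd_b <- sd(colMeans(b))
  inc <- snr_in * sd_b
  w_len <- window[2] - window[1]
  frac <- pmin(pmax((times - window[1]) / w_len * slope, 0), 1)
  frac[times < window[1] | times > window[2]] <- 0
  out <- a + rep(inc * frac, each = nrow(a))
  attr(out, "sd_b") <- sd_b
  attr(out, "terminal_amplitude") <- inc
  out
}

#' Peak-normalize trials
#'
#' Scales each trial (row) to unit maximum amplitude. Trials whose maximum
#' within the peak-search window is not strictly positive cannot be
#' normalized; they are flagged and excluded from the returned matrix.
#'
#' @param trials Trials x time matrix.
#' @param times Time axis in ms (required when `peak_window` is given).
#' @param peak_window Restrict the peak search to this ms window
#'   (default: whole trace).
#' @return List with `trials` (normalized, excluded rows dropped) and
#'   `excluded` (logical flag per input trial).
#' @export
normalize_peak <- function(trials, times = NULL, peak_window = NULL) {
  trials <- as.matrix(trials)
  cols <- if (is.null(peak_window)) seq_len(ncol(trials)) else {
    stopifnot(!is.null(times))
    window_idx(times, peak_window)
  }
  peaks <- apply(trials[, cols, drop = FALSE], 1, max)
  excluded <- !(peaks > 0)
  out <- trials[!excluded, , drop = FALSE] / peaks[!excluded]
  list(trials = out, excluded = excluded)
}
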