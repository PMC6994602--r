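#' Frequency bands
#'
#' The six analysis bands: theta 4-7, alpha 8-12, beta1 13-29, beta2 30-39,
#' gamma 40-69 and high-frequency broadband (HFB) 70-177 Hz. Wavelet
#' decomposition uses seven cycles at HFB frequencies (>= 70 Hz) and five
#' cycles below.
#'
#' @return Named list of `c(lo, hi)` band limits in Hz.
#' @export
band_specs <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta1 = c(13, 29),
       beta2 = c(30, 39), gamma = c(40, 69), HFB = c(70, 177))
}

#' Wavelet frequency grid for a band
#'
#' Frequencies from `band[1]` to `band[2]` in steps of `freq_step`, skipping
#' any frequency inside a notch stopband (these bins were removed from the
#' signal by the notch filter and carry no power).
#'
#' @param band `c(lo, hi)` in Hz.
#' @param freq_step Step in Hz (default 1).
#' @param exclude List of `c(lo, hi)` stopbands to avoid.
#' @return Numeric vector of frequencies.
#' @export
band_frequencies <- function(band, freq_step = 1,
                             exclude = list(c(57, 63), c(117, 123), c(177, 183))) {
  freqs <- seq(band[1], band[2], by = freq_step)
  for (sb in exclude) freqs <- freqs[freqs < sb[1] | freqs > sb[2]]
  if (!length(freqs)) stop("band lies entirely inside excluded frequencies")
  freqs
}

# complex Morlet wavelet at `freq` Hz, unit energy, odd symmetric support
morlet_wavelet <- function(freq, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * freq)
  h <- ceiling(3.5 * sigma_t * fs)
  t <- (-h:h) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * freq * t)
  w / sqrt(sum(Mod(w)^2))
}

# Gaussian smoothing of each column of a time x n matrix, reflection padding.
# For traces shorter than the kernel support, the support is truncated.
gauss_smooth_mat <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  x <- as.matrix(x)
  n <- nrow(x)
  h <- min(ceiling(3 * sd_samples), n)
  k <- exp(-(-h:h)^2 / (2 * sd_samples^2))
  k <- k / sum(k)
  padded <- rbind(x[h:1, , drop = FALSE], x, x[n:(n - h + 1L), , drop = FALSE])
  out <- stats::filter(padded, k, sides = 2)
  out <- out[(h + 1):(h + n), , drop = FALSE]
  matrix(as.numeric(out), n, ncol(x))
}

#' Morlet-wavelet band power in dB
#'
#' Time-frequency decomposition of artifact-free epochs with complex Morlet
#' wavelets on the band's frequency grid (seven cycles at >= 70 Hz, five
#' below; notch-band frequencies skipped). Per frequency bin, power (squared
#' coefficient magnitude) is log-rescaled by subtracting the mean log-power
#' over the baseline window of that trial and channel, converted to dB, then
#' averaged over the band's bins and Gaussian-smoothed in time. Before
#' smoothing, the baseline-window mean of every trial and channel is exactly
#' 0 dB by construction.
#'
#' @param epochs An [ecog_epochs()]; flagged artifact trials are dropped.
#' @param band `c(lo, hi)` in Hz (must lie below Nyquist).
#' @param freq_step Wavelet frequency step in Hz (default 1).
#' @param n_cycles Wavelet cycles; default 7 for bands starting at or above
#'   70 Hz, 5 otherwise.
#' @param exclude Notch stopbands whose frequencies are skipped.
#' @param baseline Baseline window in ms, half-open `[lo, hi)`, default
#'   `c(-100, 0)`.
#' @param smooth_ms Gaussian smoothing width (FWHM) in ms, default 50.
#' @param band_name Label stored on the result.
#' @param zmax Optional post-rescale rejection: trials whose |dB| z-score
#'   against the trial population exceeds `zmax` are dropped (off by
#'   default; used by the semi-simulation path).
#' @return A [bp_epochs()].
#' @export
band_power <- function(epochs, band = c(70, 177), freq_step = 1,
                       n_cycles = NULL,
                       exclude = list(c(57, 63), c(117, 123), c(177, 183)),
                       baseline = c(-100, 0), smooth_ms = 50,
                       band_name = NULL, zmax = NULL) {
  stopifnot(inherits(epochs, "ecog_epochs"))
  if (band[2] >= epochs$fs / 2) stop("band must lie below the Nyquist frequency")
  freqs <- band_frequencies(band, freq_step, exclude)
  if (is.null(n_cycles)) n_cycles <- if (band[1] >= 70) 7 else 5
  if (is.null(band_name)) {
    known <- band_specs()
    hit <- which(vapply(known, function(b) all(b == band), TRUE))
    band_name <- if (length(hit)) names(known)[hit[1]] else
      sprintf("%g-%gHz", band[1], band[2])
  }

  keep <- !epochs$artifact
  dat <- epochs$data[keep, , , drop = FALSE]
  n_tr <- dim(dat)[1]; n_ch <- dim(dat)[2]; n_t <- dim(dat)[3]
  times <- epochs$times
  bl <- window_idx_halfopen(times, baseline)

  wavs <- lapply(freqs, morlet_wavelet, fs = epochs$fs, n_cycles = n_cycles)
  max_len <- max(vapply(wavs, length, 0L))
  nfft <- stats::nextn(n_t + max_len - 1L, 2)

  out_raw <- array(0, c(n_tr, n_ch, n_t))
  for (ch in seq_len(n_ch)) {
    X <- matrix(0, nfft, n_tr)
    X[seq_len(n_t), ] <- t(matrix(dat[, ch, ], n_tr, n_t))
    FX <- mvfft(X)
    acc <- matrix(0, n_t, n_tr)
    for (k in seq_along(wavs)) {
      w <- wavs[[k]]
      L <- length(w)
      W <- fft(c(w, rep(0, nfft - L)))
      conv <- mvfft(FX * W, inverse = TRUE) / nfft
      mid <- ((L - 1L) / 2 + 1L):((L - 1L) / 2 + n_t)
      pow <- Mod(conv[mid, , drop = FALSE])^2
      lp <- log10(pow + 1e-300)
      lp <- sweep(lp, 2, colMeans(lp[bl, , drop = FALSE]))
      acc <- acc + lp
    }
    out_raw[, ch, ] <- t(10 * acc / length(wavs))
  }

  sd_samp <- smooth_ms / 2.355 * epochs$fs / 1000
  out_sm <- out_raw
  if (sd_samp > 0) {
    for (ch in seq_len(n_ch)) {
      m <- matrix(out_raw[, ch, ], n_tr, n_t)
      out_sm[, ch, ] <- t(gauss_smooth_mat(t(m), sd_samp))
    }
  }
  bp <- bp_epochs(out_sm, out_raw, times = times, fs = epochs$fs,
                  categories = epochs$categories[keep],
                  sites = epochs$sites, band = band_name)
  if (!is.null(zmax)) {
    z <- apply(bp$power, 1, function(tr) max(abs(tr)))
    zz <- (z - mean(z)) / sd(z)
    keep2 <- zz <= zmax
    bp$power <- bp$power[keep2, , , drop = FALSE]
    bp$power_raw <- bp$power_raw[keep2, , , drop = FALSE]
    bp$categories <- bp$categories[keep2]
  }
  attr(bp, "frequencies") <- freqs
  bp
}
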