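#' Raw multichannel recording container
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate, Hz.
#' @param layout An [electrode_layout()] with one row per channel (optional).
#' @param reference Free-text note on the referencing state.
#' @return A list of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, layout = NULL, reference = "none") {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (!all(is.finite(signal))) stop("signal must be finite")
  if (!is.null(layout) && nrow(layout) != nrow(signal)) {
    stop("layout must have one row per channel")
  }
  if (is.null(rownames(signal))) {
    rownames(signal) <- if (!is.null(layout)) layout$name else
      sprintf("ch%02d", seq_len(nrow(signal)))
  }
  structure(list(signal = signal, fs = fs, layout = layout,
                 reference = reference),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %.2f Hz (%.1f s), reference: %s\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, x$reference))
  invisible(x)
}

#' Epoched voltage container
#'
#' Trials x channels x time array of baseline-corrected voltage, with the time
#' axis in milliseconds relative to stimulus onset.
#'
#' @param data trials x channels x time numeric array (microvolts).
#' @param times Time axis in ms relative to onset (length = dim 3).
#' @param fs Sampling rate, Hz.
#' @param categories Per-trial stimulus category (length = dim 1).
#' @param sites Channel labels (length = dim 2).
#' @param artifact Logical per-trial artifact flag.
#' @return A list of class `ecog_epochs`.
#' @export
ecog_epochs <- function(data, times, fs, categories, sites = NULL,
                        artifact = NULL) {
  stopifnot(length(dim(data)) == 3L,
            length(times) == dim(data)[3],
            length(categories) == dim(data)[1])
  if (is.null(sites)) sites <- sprintf("ch%02d", seq_len(dim(data)[2]))
  if (is.null(artifact)) artifact <- rep(FALSE, dim(data)[1])
  structure(list(data = data, times = times, fs = fs,
                 categories = as.character(categories), sites = sites,
                 artifact = artifact),
            class = "ecog_epochs")
}

#' @export
print.ecog_epochs <- function(x, ...) {
  cat(sprintf("<ecog_epochs> %d trials x %d channels x %d samples, [%d, %d] ms, %d flagged\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), sum(x$artifact)))
  invisible(x)
}

#' Band-power epochs container
#'
#' Trials x channels x time log-rescaled band power in dB relative to the
#' per-trial baseline window. `power` holds the Gaussian-smoothed signal used
#' by selectivity and decoding analyses; `power_raw` the unsmoothed signal
#' required by response-onset-latency estimation.
#'
#' @param power,power_raw trials x channels x time arrays, dB.
#' @param times Time axis, ms relative to onset.
#' @param fs Sampling rate, Hz.
#' @param categories Per-trial stimulus category.
#' @param sites Channel labels.
#' @param band Band name (e.g. `"HFB"`).
#' @param layout Optional [electrode_layout()] matching `sites`.
#' @return A list of class `bp_epochs`.
#' @export
bp_epochs <- function(power, power_raw, times, fs, categories, sites = NULL,
                      band = "HFB", layout = NULL) {
  stopifnot(length(dim(power)) == 3L,
            identical(dim(power), dim(power_raw)),
            length(times) == dim(power)[3],
            length(categories) == dim(power)[1])
  if (is.null(sites)) sites <- sprintf("ch%02d", seq_len(dim(power)[2]))
  structure(list(power = power, power_raw = power_raw, times = times, fs = fs,
                 categories = as.character(categories), sites = sites,
                 band = band, layout = layout),
            class = "bp_epochs")
}

#' @export
print.bp_epochs <- function(x, ...) {
  cat(sprintf("<bp_epochs> band %s: %d trials x %d sites x %d samples, [%d, %d] ms\n",
              x$band, dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

# index helper: closed analysis window [lo, hi] on a ms time axis
window_idx <- function(times, window) {
  which(times >= window[1] & times <= window[2])
}

# half-open window [lo, hi) used for baseline/epoch extraction
window_idx_halfopen <- function(times, window) {
  which(times >= window[1] & times < window[2])
}
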