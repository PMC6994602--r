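#' Response onset latency parameters
#'
#' Parameters of the trial-level onset detector: a sliding window of
#' `bin_width_ms` bins advancing by `bin_step_ms` (28 ms overlap at the
#' defaults), a detection threshold of baseline mean plus `threshold_sd`
#' baseline standard deviations (baseline statistics averaged across
#' trials; see `baseline_stat`), and a required run of `n_consecutive`
#' suprathreshold bins. Bins are half-open `[t, t + width)`, aligned to
#' stimulus onset.
#'
#' @param bin_width_ms Bin width in ms (default 30).
#' @param bin_step_ms Bin step in ms (default 2, i.e. 28 ms overlap).
#' @param n_consecutive Required consecutive suprathreshold bins (default 25).
#' @param baseline Baseline window in ms, default `c(-200, 0)`.
#' @param threshold_sd Threshold in baseline SDs above the baseline mean.
#' @param min_detect_frac Minimum fraction of trials with a detected onset
#'   for a site estimate to be valid (default 0.5).
#' @param baseline_stat How the shared threshold is estimated:
#'   `"trial_mean"` (default) averages each trial's baseline mean and SD
#'   across trials, keeping the threshold at single-trial noise scale;
#'   `"average_trace"` takes mean and SD over time of the trial-averaged
#'   baseline trace (this SD shrinks with the trial count, making the
#'   detector fire on noise runs for well-averaged sites).
#' @param search Post-onset search region for the first bin, ms.
#' @param peak_window Window for the per-trial peak normalization, ms.
#' @param normalize Peak-normalize each trial before detection.
#' @return A list of class `rol_params`.
#' @export
rol_params <- function(bin_width_ms = 30, bin_step_ms = 2, n_consecutive = 25,
                       baseline = c(-200, 0), threshold_sd = 1,
                       min_detect_frac = 0.5, search = c(0, 500),
                       peak_window = c(0, 600), normalize = TRUE,
                       baseline_stat = c("trial_mean", "average_trace",
                                         "per_trial")) {
  stopifnot(bin_width_ms > 0, bin_step_ms > 0, n_consecutive >= 1)
  structure(list(bin_width_ms = bin_width_ms, bin_step_ms = bin_step_ms,
                 n_consecutive = n_consecutive, baseline = baseline,
                 threshold_sd = threshold_sd,
                 min_detect_frac = min_detect_frac, search = search,
                 peak_window = peak_window, normalize = normalize,
                 baseline_stat = match.arg(baseline_stat)),
            class = "rol_params")
}

#' Trial-level response onset latency
#'
#' Detects the onset of a sustained band-power response in one trial: bin
#' means are computed over half-open `[t, t + width)` bins starting at the
#' beginning of the search region and advancing by the bin step; the onset
#' is the start time of the first bin of the earliest run of at least
#' `n_consecutive` bins whose means all strictly exceed the threshold.
#' Returns `NA` (undetected) when no such run exists. The input must be the
#' unsmoothed band-power trace.
#'
#' @param trace Numeric vector, one trial's unsmoothed band power.
#' @param times Time axis in ms.
#' @param params An [rol_params()].
#' @param threshold Detection threshold; when `NULL`, computed from the
#'   trace's own baseline window (mean + `threshold_sd` x SD over time).
#' @return Onset time in ms, or `NA` if undetected.
#' @export
rol_trial <- function(trace, times, params = rol_params(), threshold = NULL) {
  if (is.null(threshold)) {
    bl <- trace[window_idx_halfopen(times, params$baseline)]
    threshold <- mean(bl) + params$threshold_sd * sd(bl)
  }
  starts <- seq(params$search[1], max(times) - params$bin_width_ms + 1,
                by = params$bin_step_ms)
  if (!length(starts)) return(NA_real_)
  dt <- diff(times)
  if (all(dt == dt[1]) && params$bin_width_ms %% dt[1] == 0 &&
      all((starts - times[1]) %% dt[1] == 0)) {
    # regular grid: bin means from cumulative sums
    w <- as.integer(params$bin_width_ms / dt[1])
    i0 <- as.integer(round((starts - times[1]) / dt[1])) + 1L
    cs <- c(0, cumsum(trace))
    means <- (cs[i0 + w] - cs[i0]) / w
  } else {
    means <- vapply(starts, function(s) {
      mean(trace[times >= s & times < s + params$bin_width_ms])
    }, 0)
  }
  above <- means > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= params$n_consecutive)
  if (!length(hit)) return(NA_real_)
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  starts[first]
}

#' Site-level response onset latency
#'
#' Estimates the onset latency of one site from its per-trial unsmoothed
#' band-power traces: each trial is peak-normalized, a shared threshold is
#' computed from the baseline statistics averaged across trials (see
#' `baseline_stat` in [rol_params()]), onsets are detected per trial with
#' [rol_trial()], and the site estimate is the median over detected trials.
#' The estimate is invalid when onsets were detected in fewer than
#' `min_detect_frac` of the trials.
#'
#' @param trials Trials x time matrix of unsmoothed band power.
#' @param times Time axis in ms.
#' @param params An [rol_params()].
#' @return A list of class `rol_estimate`: `onsets` (per trial, ms or NA),
#'   `median_ms`, `detection_fraction`, `valid`, `n_trials`.
#' @export
rol_site <- function(trials, times, params = rol_params()) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 1L) stop("at least one trial is required")
  n_in <- nrow(trials)
  keep <- rep(TRUE, n_in)
  if (params$normalize) {
    np <- normalize_peak(trials, times, params$peak_window)
    keep <- !np$excluded
    trials <- np$trials
  }
  onsets <- rep(NA_real_, n_in)
  if (nrow(trials) > 0) {
    bi <- window_idx_halfopen(times, params$baseline)
    threshold <- switch(params$baseline_stat,
      trial_mean = {
        bl <- trials[, bi, drop = FALSE]
        mean(rowMeans(bl)) + params$threshold_sd * mean(apply(bl, 1, sd))
      },
      average_trace = {
        bl <- colMeans(trials)[bi]
        mean(bl) + params$threshold_sd * sd(bl)
      },
      per_trial = NULL)
    onsets[keep] <- apply(trials, 1, rol_trial, times = times,
                          params = params, threshold = threshold)
  }
  detected <- onsets[!is.na(onsets)]
  frac <- length(detected) / n_in
  structure(list(onsets = onsets,
                 median_ms = if (length(detected)) median(detected) else NA_real_,
                 detection_fraction = frac,
                 valid = frac >= params$min_detect_frac,
                 n_trials = n_in),
            class = "rol_estimate")
}

#' @export
print.rol_estimate <- function(x, ...) {
  cat(sprintf("<rol_estimate> median %s ms, detected %d/%d trials (%s)\n",
              format(x$median_ms), sum(!is.na(x$onsets)), x$n_trials,
              if (x$valid) "valid" else "invalid"))
  invisible(x)
}

#' Posterior-anterior gradient analysis
#'
#' Spearman correlations of onset latency and of selectivity against the
#' MNI y coordinate over valid sites, plus region means for the posterior
#' (y < -45), middle (-45 <= y <= -35) and anterior (y > -35) divisions.
#' In `reference = "best_site"` mode, ROL and y are taken relative to each
#' subject's most human-face-selective site (within a subject this
#' subtracts a constant, leaving ranks unchanged).
#'
#' @param rol Per-site median onset latency (ms; NA for invalid sites).
#' @param selectivity Per-site selectivity score (dB).
#' @param y Per-site MNI y coordinate (mm).
#' @param subject Per-site subject identifier (required for the referenced
#'   variant).
#' @param reference `"none"` or `"best_site"`.
#' @return A list of class `gradient_result`: `rol_vs_y` and
#'   `selectivity_vs_y` (each rho, p, n), `region_means` data frame, and
#'   `variant`.
#' @export
gradient_analysis <- function(rol, selectivity, y, subject = NULL,
                              reference = c("none", "best_site")) {
  reference <- match.arg(reference)
  ok <- !is.na(rol) & !is.na(y)
  if (sum(ok) < 5) stop("at least 5 valid sites are required")
  rol <- rol[ok]; sel <- selectivity[ok]; yy <- y[ok]
  subject <- if (is.null(subject)) rep("s1", sum(ok)) else subject[ok]
  region <- cut(yy, c(-Inf, -45, -35, Inf),
                labels = c("posterior", "middle", "anterior"), right = TRUE)
  region_means <- data.frame(
    region = levels(region),
    n = as.integer(table(region)),
    rol_ms = as.numeric(tapply(rol, region, mean)),
    selectivity_db = as.numeric(tapply(sel, region, mean)))
  if (reference == "best_site") {
    for (s in unique(subject)) {
      ix <- which(subject == s)
      bi <- ix[which.max(sel[ix])]
      rol[ix] <- rol[ix] - rol[bi]
      yy[ix] <- yy[ix] - yy[bi]
    }
  }
  ct_rol <- suppressWarnings(cor.test(rol, yy, method = "spearman",
                                      exact = FALSE))
  ct_sel <- suppressWarnings(cor.test(sel, yy, method = "spearman",
                                      exact = FALSE))
  structure(list(
    rol_vs_y = list(rho = unname(ct_rol$estimate), p = ct_rol$p.value,
                    n = length(rol)),
    selectivity_vs_y = list(rho = unname(ct_sel$estimate), p = ct_sel$p.value,
                            n = length(sel)),
    region_means = region_means,
    variant = reference), class = "gradient_result")
}

#' Match face-selective to task-active sites by y coordinate
#'
#' Greedy nearest-neighbour matching of each face-selective site to the
#' task-active site closest in MNI y (pairs farther than `tolerance_mm`
#' are discarded; one task-active site may serve several face sites),
#' followed by a paired Wilcoxon signed-rank test on the onset latencies of
#' the matched pairs.
#'
#' @param face_sites,task_sites Data frames with columns `site`, `y` and
#'   `rol` (valid latencies only).
#' @param tolerance_mm Maximum |y| distance for a match, default 2.
#' @return List with `pairs` (data frame: face site, task site, y values,
#'   latencies, `dy`), `n_face`, `n_task_unique`, and `test` (the Wilcoxon
#'   result, or NULL when no pairs matched).
#' @export
match_sites <- function(face_sites, task_sites, tolerance_mm = 2) {
  stopifnot(all(c("site", "y", "rol") %in% names(face_sites)),
            all(c("site", "y", "rol") %in% names(task_sites)))
  rows <- lapply(seq_len(nrow(face_sites)), function(i) {
    j <- which.min(abs(task_sites$y - face_sites$y[i]))
    dy <- abs(task_sites$y[j] - face_sites$y[i])
    if (dy > tolerance_mm) return(NULL)
    data.frame(face_site = face_sites$site[i], task_site = task_sites$site[j],
               face_y = face_sites$y[i], task_y = task_sites$y[j],
               face_rol = face_sites$rol[i], task_rol = task_sites$rol[j],
               dy = dy, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  test <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    if (all(pairs$face_rol == pairs$task_rol)) {
      # signed-rank statistic is degenerate with no non-zero differences
      test <- list(statistic = c(V = 0), p.value = 1,
                   method = "Wilcoxon signed rank test (degenerate: all differences zero)")
    } else {
      test <- suppressWarnings(
        wilcox.test(pairs$face_rol, pairs$task_rol, paired = TRUE,
                    exact = FALSE))
    }
  }
  list(pairs = pairs,
       n_face = if (is.null(pairs)) 0L else nrow(pairs),
       n_task_unique = if (is.null(pairs)) 0L else
         length(unique(pairs$task_site)),
       test = test)
}
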