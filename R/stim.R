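#' One-tailed two-proportion z test
#'
#' Classical pooled-variance z test for the difference of two population
#' proportions, used for region x outcome counts of electrical-stimulation
#' effects (e.g. the fraction of stimulated sites inducing face distortion
#' in the posterior versus mid fusiform gyrus):
#' `z = (k1/n1 - k2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (k1 + k2)/(n1 + n2)`; the one-tailed p-value is the upper tail of
#' the standard normal. No continuity correction by default (enable with
#' `correct = TRUE`).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param correct Apply the Yates continuity correction.
#' @return List with `z`, `p` (one-tailed, upper), `p1`, `p2`, `pooled`.
#' @examples
#' two_proportion_z_one_tailed(6, 17, 0, 7)$z   # 1.815
#' two_proportion_z_one_tailed(3, 14, 0, 14)$z  # 1.833
#' @export
two_proportion_z_one_tailed <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    stop("pooled proportion is 0 or 1: the z statistic is undefined")
  }
  num <- k1 / n1 - k2 / n2
  if (correct) num <- sign(num) * max(abs(num) - (1 / n1 + 1 / n2) / 2, 0)
  z <- num / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p = pnorm(z, lower.tail = FALSE),
       p1 = k1 / n1, p2 = k2 / n2, pooled = pooled)
}

#' Charge deposited per stimulation trial
#'
#' The charge per trial in microcoulombs, computed as the product of pulse
#' width (ms), current (mA), frequency (Hz) and duration (s) of the
#' stimulation train.
#'
#' @param pulse_width_ms Pulse width in milliseconds (e.g. 0.2).
#' @param current_ma Current in milliamperes (clinical range 3-8).
#' @param frequency_hz Train frequency in Hz (typically 50).
#' @param duration_s Train duration in seconds (1-3).
#' @return Charge in microcoulombs.
#' @examples
#' charge_per_trial(0.2, 3, 50, 1)  # 30
#' @export
charge_per_trial <- function(pulse_width_ms, current_ma, frequency_hz,
                             duration_s) {
  stopifnot(pulse_width_ms >= 0, current_ma >= 0, frequency_hz >= 0,
            duration_s >= 0)
  pulse_width_ms * current_ma * frequency_hz * duration_s
}

#' Region x outcome stimulation comparisons
#'
#' Runs the one-tailed two-proportion z test for each row pair of a counts
#' table (columns `label`, `k1`, `n1`, `k2`, `n2`, where group 1 is the
#' posterior and group 2 the mid fusiform region).
#'
#' @param counts Data frame of counts, one comparison per row.
#' @return The table with `z` and `p` columns appended.
#' @export
stim_outcome_tests <- function(counts) {
  stopifnot(all(c("k1", "n1", "k2", "n2") %in% names(counts)))
  res <- lapply(seq_len(nrow(counts)), function(i) {
    two_proportion_z_one_tailed(counts$k1[i], counts$n1[i],
                                counts$k2[i], counts$n2[i])
  })
  counts$z <- vapply(res, `[[`, 0, "z")
  counts$p <- vapply(res, `[[`, 0, "p")
  counts
}
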