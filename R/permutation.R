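#' Paired permutation test
#'
#' Tests the mean of paired differences against zero. The null distribution
#' is built by random sign flips of the per-trial differences; the p-value
#' uses the `(k + 1) / (n_perm + 1)` estimator, so the smallest attainable
#' p is `1 / (n_perm + 1)` and p never equals zero.
#'
#' @param x,y Equal-length per-trial values (matched pairs).
#' @param n_perm Number of permutations (>= 1000 recommended; the reference
#'   analysis uses 50,000).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param seed Optional seed for the permutation stream.
#' @return A `perm_test` list: `statistic` (mean difference), `p`, `n_perm`,
#'   `paired`, `alternative`.
#' @export
permutation_test_paired <- function(x, y, n_perm = 50000,
                                    alternative = c("two.sided", "greater", "less"),
                                    seed = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  n <- length(d)
  obs <- mean(d)
  null <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    as.numeric(signs %*% d) / n
  })
  p <- perm_p(obs, null, alternative)
  structure(list(statistic = obs, p = p, n_perm = n_perm, paired = TRUE,
                 alternative = alternative),
            class = "perm_test")
}

#' Unpaired permutation test
#'
#' Tests the difference of two group means; the null distribution is built
#' by shuffling group labels over the pooled observations.
#'
#' @param a,b Non-empty numeric vectors of trial values.
#' @inheritParams permutation_test_paired
#' @return A `perm_test` list; `statistic` is `mean(a) - mean(b)`.
#' @export
permutation_test_unpaired <- function(a, b, n_perm = 10000,
                                      alternative = c("two.sided", "greater", "less"),
                                      seed = NULL) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  z <- c(a, b)
  na <- length(a); n <- length(z)
  tot <- sum(z)
  obs <- mean(a) - mean(b)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sa <- sum(z[sample.int(n, na)])
      sa / na - (tot - sa) / (n - na)
    }, 0)
  })
  p <- perm_p(obs, null, alternative)
  structure(list(statistic = obs, p = p, n_perm = n_perm, paired = FALSE,
                 alternative = alternative),
            class = "perm_test")
}

perm_p <- function(obs, null, alternative) {
  # count ties at floating-point resolution as exceedances
  tol <- 1e-8 * (1 + abs(obs))
  k <- switch(alternative,
              two.sided = sum(abs(null) >= abs(obs) - tol),
              greater = sum(null >= obs - tol),
              less = sum(null <= obs + tol))
  (1 + k) / (length(null) + 1)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s, %s: statistic = %.4g, p = %.4g (%d permutations)\n",
              if (x$paired) "paired" else "unpaired", x$alternative,
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up false discovery rate control: returns the rejection mask at level
#' `q` (a thin wrapper over [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param q FDR level, default 0.05.
#' @return Logical rejection mask, monotone in `p`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH") <= q
}
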